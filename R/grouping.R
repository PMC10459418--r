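#' Similar-class grouping from a cross-validated confusion matrix
#'
#' The grouping algorithm scans the validation CVCM of the stage-one
#' classifier for weak classes and their confusion partners, and assembles
#' the similarity-group (SG) map that routes stage-two training and
#' inference:
#'
#' 1. flag every class whose true-positive count is at or below the
#'    threshold ("red" classes);
#' 2. for each red class, collect the classes its images were misclassified
#'    into at or above the false-negative threshold ("yellow" partners,
#'    read from the red class's row);
#' 3. within each coarse package class, merge each red class with its
#'    same-package yellow partners into one similar-drug (SD) list;
#' 4. SD lists with at least two members become SG1..SGN, ordered
#'    lexicographically by package class;
#' 5. every remaining class falls into the residual group SG(N+1).
#'
#' Yellow partners in a different package class are excluded (each SD list
#' spans a single package class) and reported; a red class left without any
#' same-package partner dissolves into the residual with a warning.
#'
#' @name grouping
NULL

#' Grouping thresholds
#'
#' The defaults mirror a validation CVCM with per-class support 50 (5 folds
#' of 10 validation images): a class is flagged when its true-positive
#' count is at most 48, and a confusion partner counts when at least one
#' image was misrouted to it. `tp_fraction`, when supplied, switches to a
#' relative threshold (`TP <= tp_fraction * row support`) for datasets
#' whose validation support differs from 50.
#'
#' @param tp_threshold Absolute true-positive threshold (default 48).
#' @param fn_threshold Minimum row-cell count for a confusion partner
#'   (default 1).
#' @param support Expected per-class row sum of the CVCM (default 50).
#' @param tp_fraction Optional relative threshold; overrides
#'   `tp_threshold` when non-`NULL` (0.96 reproduces 48 of 50).
#' @param scan_columns Also scan the red class's column (its false-positive
#'   sources) for partners; off by default, matching the row-only reading
#'   of the algorithm.
#' @param connected_components Split each package's SD list into confusion
#'   graph components instead of taking the per-package union; off by
#'   default.
#' @return A list of class `grouping_params`.
#' @export
grouping_params <- function(tp_threshold = 48L, fn_threshold = 1L,
                            support = 50L, tp_fraction = NULL,
                            scan_columns = FALSE,
                            connected_components = FALSE) {
  stopifnot(fn_threshold >= 1, tp_threshold >= 0, tp_threshold <= support)
  if (!is.null(tp_fraction)) stopifnot(tp_fraction > 0, tp_fraction <= 1)
  structure(
    list(
      tp_threshold = as.integer(tp_threshold),
      fn_threshold = as.integer(fn_threshold),
      support = as.integer(support),
      tp_fraction = tp_fraction,
      scan_columns = isTRUE(scan_columns),
      connected_components = isTRUE(connected_components)
    ),
    class = "grouping_params"
  )
}

new_sg_map <- function(groups, residual, params = NULL, provenance = NULL) {
  structure(
    list(groups = groups, residual = residual, params = params,
      provenance = provenance),
    class = "sg_map"
  )
}

#' Build the similarity-group map from a validation CVCM
#'
#' Runs the grouping algorithm (see [grouping]) on a cross-validated
#' confusion matrix and a fine-to-package label map.
#'
#' @param cvcm The validation `confusion_matrix` (never the testing one).
#' @param package_of A [label_map()] from fine label to package class,
#'   covering every CVCM label.
#' @param params A [grouping_params()] object.
#' @return An `sg_map`: `groups` is a list of SD lists (each with
#'   `package_class` and sorted `members`), `residual` the sorted remaining
#'   labels, plus the thresholds and a digest of the source CVCM. Groups
#'   and residual always partition the CVCM label set.
#' @export
find_similar_groups <- function(cvcm, package_of,
                                params = grouping_params()) {
  stopifnot(inherits(params, "grouping_params"))
  package_of <- as_label_map(package_of)
  m <- unclass(cvcm)
  labs <- cm_labels(cvcm)
  if (length(labs) == 0) stop("empty confusion matrix")
  missing <- setdiff(labs, names(package_of))
  if (length(missing)) {
    stop("label(s) missing from the package map: ",
      paste(missing, collapse = ", "))
  }
  pkg <- unname(unclass(package_of)[labs])

  tp <- diag(m)
  threshold <- if (is.null(params$tp_fraction)) {
    rep(params$tp_threshold, length(labs))
  } else {
    params$tp_fraction * rowSums(m)
  }
  red <- labs[tp <= threshold]

  yellow_of <- stats::setNames(vector("list", length(red)), red)
  for (r in red) {
    i <- match(r, labs)
    row_part <- labs[m[i, ] >= params$fn_threshold & seq_along(labs) != i]
    partners <- row_part
    if (params$scan_columns) {
      col_part <- labs[m[, i] >= params$fn_threshold & seq_along(labs) != i]
      partners <- union(partners, col_part)
    }
    cross <- partners[pkg[match(partners, labs)] != pkg[i]]
    if (length(cross)) {
      message("red class ", r, ": cross-package partner(s) excluded: ",
        paste(cross, collapse = ", "))
    }
    yellow_of[[r]] <- setdiff(partners, cross)
  }

  sd_lists <- list()
  red_pkgs <- sort(unique(pkg[match(red, labs)]))
  for (p in red_pkgs) {
    reds_p <- red[pkg[match(red, labs)] == p]
    if (params$connected_components) {
      comps <- confusion_components(reds_p, yellow_of)
    } else {
      comps <- list(sort(unique(c(reds_p,
        unlist(yellow_of[reds_p], use.names = FALSE)))))
    }
    for (members in comps) {
      if (length(members) < 2) {
        warning("red class ", paste(members, collapse = ", "), " (package ",
          p, ") has no same-package partner; dissolved into the residual")
        next
      }
      sd_lists[[length(sd_lists) + 1L]] <- list(
        package_class = p, members = sort(members))
    }
  }
  # lexicographic order by package class (then first member, for the
  # connected-components mode where one package can yield several lists)
  if (length(sd_lists)) {
    ord <- order(
      vapply(sd_lists, `[[`, character(1), "package_class"),
      vapply(sd_lists, function(g) g$members[1], character(1))
    )
    sd_lists <- sd_lists[ord]
  }
  grouped <- unlist(lapply(sd_lists, `[[`, "members"), use.names = FALSE)
  residual <- sort(setdiff(labs, grouped))
  sg <- new_sg_map(sd_lists, residual, params,
    provenance = list(cvcm_digest = rlang::hash(unclass(cvcm))))
  validate_sg_map(sg, labs)
  sg
}

confusion_components <- function(reds, yellow_of) {
  nodes <- sort(unique(c(reds, unlist(yellow_of[reds], use.names = FALSE))))
  if (!length(nodes)) return(list())
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (r in reds) {
    for (y in yellow_of[[r]]) {
      a <- comp[[r]]; b <- comp[[y]]
      if (a != b) comp[comp == b] <- a
    }
  }
  lapply(unique(comp), function(k) sort(names(comp)[comp == k]))
}

validate_sg_map <- function(sg, labels) {
  all_members <- c(unlist(lapply(sg$groups, `[[`, "members"),
    use.names = FALSE), sg$residual)
  if (anyDuplicated(all_members)) {
    stop("SG map is not a partition: duplicated label(s) ",
      paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  if (!setequal(all_members, labels)) {
    stop("SG map is not a partition of the label set")
  }
  invisible(sg)
}

#' Number of similarity groups (excluding the residual)
#' @param sg_map An `sg_map`.
#' @return Integer count of SD lists.
#' @export
n_groups <- function(sg_map) length(sg_map$groups)

#' Route a label to its similarity group
#'
#' Returns the 1-based index of the SD list containing each label, or
#' `n_groups(sg_map) + 1` for residual members. Unknown labels are an
#' error.
#'
#' @param label Character vector of fine labels.
#' @param sg_map An `sg_map`.
#' @return Integer vector of group indices.
#' @export
assign_group <- function(label, sg_map) {
  label <- as.character(label)
  idx <- stats::setNames(
    rep(length(sg_map$groups) + 1L, length(sg_map$residual)),
    sg_map$residual)
  for (g in seq_along(sg_map$groups)) {
    mem <- sg_map$groups[[g]]$members
    idx[mem] <- g
  }
  unknown <- setdiff(label, names(idx))
  if (length(unknown)) {
    stop("label(s) not in the SG map: ", paste(unknown, collapse = ", "))
  }
  unname(idx[label])
}

#' Fine-label-to-group label map
#'
#' Convenience wrapper turning an `sg_map` into a [label_map()] whose
#' coarse labels are `SG1..SGN` and `SG<N+1>` for the residual, suitable
#' for [project_cm()] (group-level evaluation).
#'
#' @param sg_map An `sg_map`.
#' @return A `label_map`.
#' @export
group_label_map <- function(sg_map) {
  fine <- character(0)
  coarse <- character(0)
  for (g in seq_along(sg_map$groups)) {
    mem <- sg_map$groups[[g]]$members
    fine <- c(fine, mem)
    coarse <- c(coarse, rep(sprintf("SG%d", g), length(mem)))
  }
  fine <- c(fine, sg_map$residual)
  coarse <- c(coarse, rep(sprintf("SG%d", length(sg_map$groups) + 1L),
    length(sg_map$residual)))
  label_map(fine, coarse)
}

#' @export
print.sg_map <- function(x, ...) {
  cat(sprintf("<sg_map> %d similarity group(s) + residual of %d\n",
    length(x$groups), length(x$residual)))
  for (g in seq_along(x$groups)) {
    cat(sprintf("  SG%d [%s]: %s\n", g, x$groups[[g]]$package_class,
      paste(x$groups[[g]]$members, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an SG map
#'
#' @param x An `sg_map`.
#' @param ... Unused.
#' @return Tibble with columns label, group (integer index), group_id
#'   (`SG1`..), package_class (`NA` for residual rows).
#' @export
tidy.sg_map <- function(x, ...) {
  rows <- purrr::imap(x$groups, function(g, i) {
    tibble::tibble(label = g$members, group = as.integer(i),
      group_id = sprintf("SG%d", i), package_class = g$package_class)
  })
  res <- tibble::tibble(label = x$residual,
    group = length(x$groups) + 1L,
    group_id = sprintf("SG%d", length(x$groups) + 1L),
    package_class = NA_character_)
  dplyr::bind_rows(c(rows, list(res)))
}

#' Serialize SG maps as JSON
#'
#' Writes groups (package class + members), residual, thresholds and the
#' source CVCM digest; this file is the routing contract consumed by the
#' two-stage pipeline.
#'
#' @param sg_map An `sg_map`.
#' @param path File path.
#' @return `read_sg_map` returns an `sg_map`; `write_sg_map` returns
#'   `path` invisibly.
#' @export
write_sg_map <- function(sg_map, path) {
  payload <- list(
    groups = lapply(sg_map$groups, function(g) {
      list(package_class = g$package_class, members = as.list(g$members))
    }),
    residual = as.list(sg_map$residual),
    params = sg_map$params[c("tp_threshold", "fn_threshold", "support")],
    provenance = sg_map$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sg_map
#' @export
read_sg_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  groups <- lapply(x$groups, function(g) {
    list(package_class = g$package_class,
      members = as.character(unlist(g$members, use.names = FALSE)))
  })
  new_sg_map(groups, as.character(unlist(x$residual, use.names = FALSE)),
    params = x$params, provenance = x$provenance)
}
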