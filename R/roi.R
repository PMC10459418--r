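#' Region-of-interest crop machinery
#'
#' Each similarity group gets a centered square crop whose side is chosen
#' from a halving pyramid built on the full frame: sides
#' `N, N/2, N/4, N/8` (floored), all centered at `(floor(N/2), floor(N/2))`
#' in 0-based coordinates. Cropping magnifies the central imprint region
#' relative to the frame once the crop is resized to the classifier input
#' side, which is what makes the stage-two models discriminative within a
#' group. The residual group keeps the full frame.
#'
#' @name roi
NULL

#' Halving pyramid of candidate crop sides
#'
#' @param n Base side in pixels (the full frame).
#' @param levels Number of pyramid levels (default 4).
#' @return Integer vector `floor(n / 2^k)` for `k = 0 .. levels - 1`; e.g.
#'   a 2992-pixel frame yields 2992, 1496, 748, 374.
#' @export
pyramid_sizes <- function(n, levels = 4L) {
  stopifnot(length(n) == 1, length(levels) == 1, levels >= 1)
  if (n < 2^(levels - 1)) {
    stop("base side ", n, " too small for ", levels, " halving levels")
  }
  as.integer(floor(n / 2^(seq_len(levels) - 1)))
}

#' Centered square crop
#'
#' Extracts the `r` x `r` window whose rows and columns span the 0-based
#' half-open range `[c - floor(r/2), c - floor(r/2) + r)` with
#' `c = (floor(H/2), floor(W/2))`. Pixel values are copied, never
#' resampled, and crops beyond the frame are an error (no padding).
#'
#' @param img Numeric matrix (H x W).
#' @param r Window side in pixels; must not exceed `min(H, W)`.
#' @return An `r` x `r` numeric matrix.
#' @export
center_crop <- function(img, r) {
  stopifnot(is.matrix(img), length(r) == 1, r >= 1)
  h <- nrow(img)
  w <- ncol(img)
  if (r > min(h, w)) {
    stop("crop side ", r, " exceeds image extent ", h, "x", w)
  }
  r0 <- floor(h / 2) - floor(r / 2)  # 0-based first row
  c0 <- floor(w / 2) - floor(r / 2)
  r0 <- max(0, min(r0, h - r))
  c0 <- max(0, min(c0, w - r))
  img[(r0 + 1):(r0 + r), (c0 + 1):(c0 + r), drop = FALSE]
}

#' Per-group crop specification
#'
#' Maps each similarity-group index to its chosen window side; the residual
#' group maps to the identity (full frame), recorded as `NA`.
#'
#' @param sides Integer vector of window sides, one per similarity group
#'   (ordered SG1..SGN).
#' @param base_side Side of the full frame the pyramid was built on.
#' @param levels Pyramid levels the sides were drawn from.
#' @return A `crop_spec` tibble with columns `group` and `side` (the
#'   residual row has `side = NA`).
#' @export
crop_spec <- function(sides, base_side, levels = 4L) {
  sides <- as.integer(sides)
  if (any(!is.na(sides) & sides > base_side)) {
    stop("crop side exceeds the base side")
  }
  out <- tibble::tibble(
    group = seq_len(length(sides) + 1L),
    side = c(sides, NA_integer_)
  )
  structure(out, class = c("crop_spec", class(out)),
    base_side = as.integer(base_side), levels = as.integer(levels))
}

#' Look up the crop side for a group
#'
#' @param spec A [crop_spec()].
#' @param group Group index (residual = last index).
#' @return Integer side, or `NA` for the identity (full-frame) crop.
#' @export
crop_side <- function(spec, group) {
  i <- match(group, spec$group)
  if (anyNA(i)) stop("group ", paste(group[is.na(i)], collapse = ", "),
    " not covered by the crop spec")
  spec$side[i]
}

#' Apply a group's crop to an image
#'
#' `NA` (residual) is the identity; otherwise a centered crop.
#'
#' @param img Numeric matrix.
#' @param side Integer side or `NA`.
#' @return Cropped (or untouched) matrix.
#' @export
apply_crop <- function(img, side) {
  if (is.na(side)) img else center_crop(img, side)
}

#' Choose the optimal crop side for a similarity group
#'
#' The expert-in-the-loop step: from the pyramid candidates, pick the
#' window that best exposes the group's discriminative region.
#'
#' * `selector = "manual"`: the configured side for this group is returned
#'   (the stand-in for an experienced pharmacist's choice); a missing entry
#'   is an error.
#' * `selector = "auto"`: for each candidate, the group's training and
#'   validation images are cropped, a quick proxy classifier is fitted, and
#'   the side with the highest validation accuracy wins; ties go to the
#'   larger side. Deterministic given `seed`.
#'
#' @param group Group index (or any id present in `manual_config`).
#' @param candidates Integer vector of candidate sides, largest first.
#' @param selector `"manual"` or `"auto"`.
#' @param manual_config Named vector/list of sides keyed by group id
#'   (required for manual).
#' @param train_images,train_labels,val_images,val_labels Group-restricted
#'   data (required for auto): lists of image matrices plus label vectors.
#' @param config A [train_config()] for the proxy classifier (auto only).
#' @param verbose Log per-candidate scores.
#' @return The chosen side (integer), with attribute `scores` (named
#'   per-candidate validation accuracies) in auto mode.
#' @export
select_optimal_crop <- function(group, candidates,
                                selector = c("manual", "auto"),
                                manual_config = NULL,
                                train_images = NULL, train_labels = NULL,
                                val_images = NULL, val_labels = NULL,
                                config = NULL, verbose = FALSE) {
  selector <- match.arg(selector)
  stopifnot(length(candidates) >= 1)
  candidates <- as.integer(candidates)

  if (selector == "manual") {
    key <- as.character(group)
    if (is.null(manual_config) || is.null(manual_config[[key]])) {
      stop("no manual crop configured for group ", key)
    }
    return(as.integer(manual_config[[key]]))
  }

  if (length(candidates) == 1L) return(candidates)
  if (length(unique(train_labels)) < 2) {
    stop("auto crop selection needs at least 2 classes in the group")
  }
  if (is.null(config)) config <- train_config()
  scores <- vapply(candidates, function(side) {
    tr <- lapply(train_images, center_crop, r = side)
    va <- lapply(val_images, center_crop, r = side)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, side)
    fit <- train_classifier(tr, train_labels, va, val_labels, cfg)
    max(fit$curves$val_acc)
  }, numeric(1))
  names(scores) <- as.character(candidates)
  # highest score wins; ties go to the larger side (candidates are
  # scanned largest-first so which.max already prefers it)
  ord <- order(candidates, decreasing = TRUE)
  best <- ord[which.max(scores[ord])]
  if (verbose) {
    message("group ", group, " crop scores: ",
      paste(sprintf("%s=%.3f", names(scores), scores), collapse = " "),
      " -> ", candidates[best])
  }
  structure(candidates[best], scores = scores)
}

#' Serialize crop specs as JSON
#'
#' @param spec A [crop_spec()].
#' @param path File path.
#' @return `read_crop_spec` returns a `crop_spec`; `write_crop_spec`
#'   returns `path` invisibly.
#' @export
write_crop_spec <- function(spec, path) {
  payload <- list(
    base_side = attr(spec, "base_side"),
    levels = attr(spec, "levels"),
    groups = lapply(seq_len(nrow(spec)), function(i) {
      list(group = spec$group[i],
        side = if (is.na(spec$side[i])) NULL else spec$side[i])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_crop_spec
#' @export
read_crop_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  sides <- vapply(x$groups, function(g) {
    if (is.null(g$side) || length(g$side) == 0) NA_integer_ else
      as.integer(g$side)
  }, integer(1))
  crop_spec(sides[-length(sides)], base_side = x$base_side,
    levels = x$levels)
}
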