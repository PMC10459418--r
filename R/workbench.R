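#' Manifests and run plumbing
#'
#' A manifest is the dataset inventory: one row per image with its path
#' (or in-memory id), fine label (`drug`), coarse label (`package`), split
#' (`trainval` or `test`), cross-validation fold (validation block index,
#' `NA` for test rows) and pose id. TSV on disk, tibble in memory.
#'
#' @name workbench
NULL

manifest_columns <- c("image_id", "path", "drug", "package", "split",
  "fold", "pose")

#' Read and validate a manifest TSV
#'
#' Enforces the column contract, unique paths/ids, a consistent
#' drug-to-package mapping, and known split values.
#'
#' @param path Manifest TSV path.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(
      image_id = readr::col_character(), path = readr::col_character(),
      drug = readr::col_character(), package = readr::col_character(),
      split = readr::col_character(), fold = readr::col_integer(),
      pose = readr::col_integer()
    ))
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(manifest$image_id)) {
    stop("duplicate image_id in manifest")
  }
  paths <- manifest$path[!is.na(manifest$path)]
  if (anyDuplicated(paths)) stop("duplicate path in manifest")
  bad_split <- setdiff(unique(manifest$split), c("trainval", "test"))
  if (length(bad_split)) {
    stop("unknown split value(s): ", paste(bad_split, collapse = ", "))
  }
  multi <- manifest |>
    dplyr::distinct(.data$drug, .data$package) |>
    dplyr::count(.data$drug) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    stop("drug(s) listed under more than one package: ",
      paste(multi$drug, collapse = ", "))
  }
  tibble::as_tibble(manifest)
}

#' Load manifest images from disk
#'
#' Reads every image referenced by the manifest's `path` column (ASCII
#' PGM) into a named list keyed by `image_id`.
#'
#' @param manifest A manifest tibble with non-`NA` paths.
#' @return Named list of image matrices.
#' @export
load_images <- function(manifest) {
  if (anyNA(manifest$path)) stop("manifest has rows without a path")
  imgs <- lapply(manifest$path, read_pgm)
  names(imgs) <- manifest$image_id
  imgs
}

#' Run configuration with a stable digest
#'
#' Bundles the seed, training configuration, grouping thresholds and crop
#' candidates that fully determine a run; `digest` is a stable hash so
#' artifacts can record their provenance.
#'
#' @param seed Master seed.
#' @param train A [train_config()].
#' @param grouping A [grouping_params()].
#' @param crop_candidates Integer vector of candidate crop sides, or
#'   `NULL` to derive the halving pyramid from the frame side.
#' @param manual_crops Optional named list: group id to side (the expert
#'   crop map; takes precedence over the automated selector).
#' @return A list of class `run_config` with a `digest` field.
#' @export
run_config <- function(seed = 1L, train = train_config(seed = seed),
                       grouping = grouping_params(),
                       crop_candidates = NULL, manual_crops = NULL) {
  cfg <- list(seed = as.integer(seed), train = train, grouping = grouping,
    crop_candidates = crop_candidates, manual_crops = manual_crops)
  cfg$digest <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Render a human-readable run summary
#'
#' Reads the artifacts of a completed run directory (validation/testing
#' CVCMs, SG map, crop spec, per-level metric reports) and renders a
#' deterministic text summary. Missing artifacts are an error listing
#' them.
#'
#' @param run_dir Directory holding `cvcm_val.tsv`, `cvcm_test.tsv`,
#'   `sg_map.json`, `crop_spec.json` and `metrics_<level>.json` files.
#' @return Character vector of report lines (invisibly printed).
#' @export
render_report <- function(run_dir) {
  needed <- c("cvcm_val.tsv", "cvcm_test.tsv", "sg_map.json",
    "crop_spec.json", "metrics_drug.json", "metrics_package.json",
    "metrics_group.json")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing)) {
    stop("incomplete run; missing artifact(s): ",
      paste(missing, collapse = ", "))
  }
  sg <- read_sg_map(file.path(run_dir, "sg_map.json"))
  cspec <- read_crop_spec(file.path(run_dir, "crop_spec.json"))
  lines <- c("== two-stage classification run ==", "")
  lines <- c(lines, sprintf("similarity groups: %d (+ residual of %d)",
    length(sg$groups), length(sg$residual)))
  for (g in seq_along(sg$groups)) {
    lines <- c(lines, sprintf("  SG%d [%s] crop %s: %s", g,
      sg$groups[[g]]$package_class,
      ifelse(is.na(cspec$side[g]), "full", cspec$side[g]),
      paste(sg$groups[[g]]$members, collapse = ", ")))
  }
  lines <- c(lines, "")
  for (level in c("drug", "package", "group")) {
    rep <- read_metrics(file.path(run_dir,
      sprintf("metrics_%s.json", level)))
    lines <- c(lines, sprintf(
      "%-8s accuracy %.4f | macro R %.4f P %.4f F1 %.4f",
      level, rep$accuracy, rep$macro_recall, rep$macro_precision,
      rep$macro_f1))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
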