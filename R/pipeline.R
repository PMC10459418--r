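#' The two-stage pipeline
#'
#' Orchestration of the full method: stage-one k-fold cross-validation
#' producing the validation and testing CVCMs, similarity-group
#' construction from the validation CVCM, per-group optimal-crop
#' selection, per-group stage-two training on cropped images, two-stage
#' inference, and multi-level evaluation (fine, package and group level).
#'
#' @name pipeline
NULL

split_pool <- function(manifest, seed, n_val_frac = NULL) {
  # deterministic 40/10-style re-split of each class's train+val pool,
  # used for the deployment stage-one model and the stage-two models
  pool <- manifest[manifest$split == "trainval", ]
  val_rows <- character(0)
  for (cls in sort(unique(pool$drug))) {
    ids <- pool$image_id[pool$drug == cls]
    n_val <- max(1L, round(length(ids) / 5))
    withr::with_seed(derive_seed(seed, 701L, match(cls,
      sort(unique(pool$drug)))), {
      val_rows <- c(val_rows, sample(ids, n_val))
    })
  }
  list(train = setdiff(pool$image_id, val_rows), val = val_rows)
}

#' Run stage-one cross-validation
#'
#' Trains one model per fold on that fold's train/validation split (the
#' other folds' pool images train, the fold's block validates), evaluates
#' each fold model on its validation block and on the fixed per-class test
#' block, and aggregates the per-fold confusion matrices into the
#' validation CVCM (per-class support = pool size) and the testing CVCM
#' (per-class support = test block x folds). Also trains the deployment
#' stage-one model ("Model 0") on a seeded re-split of the full pool.
#'
#' @param manifest A validated manifest with `trainval`/`test` splits and
#'   fold assignments.
#' @param images Named list of image matrices keyed by `image_id`.
#' @param config A [train_config()].
#' @param final_model Train the deployment model on the full pool
#'   (default `TRUE`).
#' @return A `stage1_result`: per-fold models, `model0`, `cvcm_val`,
#'   `cvcm_test`, and the label set.
#' @export
run_stage1 <- function(manifest, images, config = train_config(),
                       final_model = TRUE) {
  manifest <- validate_manifest(manifest)
  labels <- sort(unique(manifest$drug))
  pool <- manifest[manifest$split == "trainval", ]
  test <- manifest[manifest$split == "test", ]
  if (nrow(test) == 0) stop("manifest has no test split")
  folds <- sort(unique(pool$fold))
  if (length(folds) < 2 || anyNA(folds)) {
    stop("trainval rows must carry fold assignments")
  }
  per_class_folds <- tapply(pool$fold, pool$drug,
    function(f) length(unique(f)))
  if (any(per_class_folds < length(folds))) {
    stop("class(es) with insufficient train+val images for the fold plan: ",
      paste(names(per_class_folds)[per_class_folds < length(folds)],
        collapse = ", "))
  }

  get_images <- function(ids) images[ids]
  fold_models <- list()
  cms_val <- list()
  cms_test <- list()
  for (f in folds) {
    tr <- pool[pool$fold != f, ]
    va <- pool[pool$fold == f, ]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 601L, f)
    fit <- train_classifier(get_images(tr$image_id), tr$drug,
      get_images(va$image_id), va$drug, cfg)
    fold_models[[f]] <- fit
    pred_va <- predict(fit, get_images(va$image_id))
    cms_val[[f]] <- build_cm(va$drug, pred_va$.pred_label, labels)
    pred_te <- predict(fit, get_images(test$image_id))
    cms_test[[f]] <- build_cm(test$drug, pred_te$.pred_label, labels)
  }

  model0 <- NULL
  if (final_model) {
    sp <- split_pool(manifest, config$seed)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 600L)
    tr_rows <- pool[pool$image_id %in% sp$train, ]
    va_rows <- pool[pool$image_id %in% sp$val, ]
    model0 <- train_classifier(get_images(tr_rows$image_id), tr_rows$drug,
      get_images(va_rows$image_id), va_rows$drug, cfg)
  }

  structure(
    list(
      fold_models = fold_models, model0 = model0,
      cvcm_val = aggregate_folds(cms_val),
      cvcm_test = aggregate_folds(cms_test),
      labels = labels
    ),
    class = "stage1_result"
  )
}

#' @export
print.stage1_result <- function(x, ...) {
  acc_val <- macro_metrics(x$cvcm_val)$accuracy
  acc_test <- macro_metrics(x$cvcm_test)$accuracy
  cat(sprintf(
    "<stage1_result> %d folds over %d classes | CVCM accuracy val %.4f, test %.4f\n",
    length(x$fold_models), length(x$labels), acc_val, acc_test))
  invisible(x)
}

#' Build the SG map from a stage-one result
#'
#' Runs the grouping algorithm on the *validation* CVCM (never the testing
#' one) and records provenance.
#'
#' @param stage1 A `stage1_result`.
#' @param package_of A [label_map()] from fine label to package class.
#' @param params A [grouping_params()].
#' @return An `sg_map`.
#' @export
build_sg_map <- function(stage1, package_of, params = grouping_params()) {
  find_similar_groups(stage1$cvcm_val, package_of, params)
}

#' Choose crop sides for every similarity group
#'
#' For each SD list, picks a window side from the pyramid candidates —
#' from the expert crop map where one is configured, otherwise with the
#' automated proxy selector — and records the identity (full frame) for
#' the residual group.
#'
#' @param dataset A `synth_dataset` (or list with `manifest` + `images`).
#' @param sg_map An `sg_map`.
#' @param candidates Candidate sides (default: the 4-level halving pyramid
#'   of the frame side).
#' @param manual_crops Optional named list, group index to side; groups
#'   with an entry skip the automated selector.
#' @param config [train_config()] for the proxy classifier.
#' @return A [crop_spec()].
#' @export
select_crops <- function(dataset, sg_map, candidates = NULL,
                         manual_crops = NULL, config = train_config()) {
  manifest <- dataset$manifest
  images <- dataset$images
  base_side <- nrow(images[[1]])
  if (is.null(candidates)) candidates <- pyramid_sizes(base_side, 4L)
  sides <- integer(length(sg_map$groups))
  sp <- split_pool(manifest, config$seed)
  for (g in seq_along(sg_map$groups)) {
    key <- as.character(g)
    if (!is.null(manual_crops) && !is.null(manual_crops[[key]])) {
      sides[g] <- select_optimal_crop(g, candidates, "manual",
        manual_config = manual_crops)
      next
    }
    members <- sg_map$groups[[g]]$members
    tr_rows <- manifest[manifest$image_id %in% sp$train &
      manifest$drug %in% members, ]
    va_rows <- manifest[manifest$image_id %in% sp$val &
      manifest$drug %in% members, ]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 801L, g)
    sides[g] <- select_optimal_crop(g, candidates, "auto",
      train_images = images[tr_rows$image_id], train_labels = tr_rows$drug,
      val_images = images[va_rows$image_id], val_labels = va_rows$drug,
      config = cfg)
  }
  crop_spec(sides, base_side = base_side, levels = length(candidates))
}

#' Train the stage-two models
#'
#' For each similarity group (and the residual), restricts the manifest to
#' the group's member classes, applies the group's crop side to every
#' image, and trains a dedicated classifier over exactly those labels. The
#' residual group trains at full frame. A group with a single class is an
#' error.
#'
#' @param manifest A validated manifest.
#' @param images Named list of image matrices.
#' @param sg_map An `sg_map`.
#' @param cspec A [crop_spec()] covering every group plus the residual.
#' @param config A [train_config()].
#' @return Named list of `tsidl_model`s, one per group index
#'   (`"1" .. "<N+1>"`).
#' @export
train_stage2 <- function(manifest, images, sg_map, cspec,
                         config = train_config()) {
  manifest <- validate_manifest(manifest)
  n_g <- length(sg_map$groups)
  sp <- split_pool(manifest, config$seed)
  models <- list()
  for (g in seq_len(n_g + 1L)) {
    members <- if (g <= n_g) sg_map$groups[[g]]$members else sg_map$residual
    if (length(members) < 2) {
      stop("group ", g, " has fewer than 2 classes")
    }
    side <- crop_side(cspec, g)
    tr_rows <- manifest[manifest$image_id %in% sp$train &
      manifest$drug %in% members, ]
    va_rows <- manifest[manifest$image_id %in% sp$val &
      manifest$drug %in% members, ]
    crop_list <- function(ids) lapply(images[ids], apply_crop, side = side)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 901L, g)
    models[[as.character(g)]] <- train_classifier(
      crop_list(tr_rows$image_id), tr_rows$drug,
      crop_list(va_rows$image_id), va_rows$drug, cfg)
  }
  models
}

#' Assemble a deployable two-stage bundle
#'
#' Validates that every similarity group (and the residual) has a
#' stage-two model whose label set matches its members exactly.
#'
#' @param model0 The deployment stage-one `tsidl_model`.
#' @param sg_map An `sg_map`.
#' @param cspec A [crop_spec()].
#' @param stage2_models Named list from [train_stage2()].
#' @return A `tsidl_bundle`.
#' @export
tsidl_bundle <- function(model0, sg_map, cspec, stage2_models) {
  n_g <- length(sg_map$groups)
  for (g in seq_len(n_g + 1L)) {
    key <- as.character(g)
    if (is.null(stage2_models[[key]])) {
      stop("no stage-two model for group ", key)
    }
    members <- if (g <= n_g) sg_map$groups[[g]]$members else sg_map$residual
    if (!setequal(stage2_models[[key]]$labels, members)) {
      stop("stage-two model ", key,
        " label set does not match the group members")
    }
  }
  structure(
    list(model0 = model0, sg_map = sg_map, crop_spec = cspec,
      stage2 = stage2_models),
    class = "tsidl_bundle"
  )
}

#' @export
print.tsidl_bundle <- function(x, ...) {
  cat(sprintf(
    "<tsidl_bundle> stage-1 over %d classes; %d similarity group(s) + residual\n",
    length(x$model0$labels), length(x$sg_map$groups)))
  invisible(x)
}

#' Two-stage inference
#'
#' For every image: the stage-one model predicts a fine label, the label
#' routes to a similarity group through the SG map, the group's crop is
#' applied, and the group's stage-two model produces the final label. The
#' final label always belongs to the routed group's label set, so a
#' stage-one routing error (true class outside the routed group) is
#' irrecoverable by construction. All intermediate outputs are returned
#' for audit.
#'
#' @param images Named list of image matrices.
#' @param bundle A [tsidl_bundle()].
#' @return Tibble with `image_id`, `stage1_label`, `stage1_score`,
#'   `group`, `final_label`, `final_score` in the input order.
#' @export
infer_two_stage <- function(images, bundle) {
  if (length(images) == 0) {
    return(tibble::tibble(image_id = character(0),
      stage1_label = character(0), stage1_score = numeric(0),
      group = integer(0), final_label = character(0),
      final_score = numeric(0)))
  }
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  p1 <- predict(bundle$model0, images)
  score_cols <- paste0(".pred_", bundle$model0$labels)
  s1_scores <- do.call(cbind, lapply(score_cols, function(cl) p1[[cl]]))
  stage1_label <- p1$.pred_label
  stage1_score <- apply(s1_scores, 1, max)
  group <- assign_group(stage1_label, bundle$sg_map)

  final_label <- character(length(images))
  final_score <- numeric(length(images))
  for (g in unique(group)) {
    sel <- which(group == g)
    side <- crop_side(bundle$crop_spec, g)
    cropped <- lapply(images[sel], apply_crop, side = side)
    m2 <- bundle$stage2[[as.character(g)]]
    p2 <- predict(m2, cropped)
    final_label[sel] <- p2$.pred_label
    sc <- do.call(cbind,
      lapply(paste0(".pred_", m2$labels), function(cl) p2[[cl]]))
    final_score[sel] <- apply(sc, 1, max)
  }
  tibble::tibble(image_id = ids, stage1_label = stage1_label,
    stage1_score = stage1_score, group = as.integer(group),
    final_label = final_label, final_score = final_score)
}

#' Evaluate a bundle on the test split
#'
#' Builds the fine-level confusion matrix from two-stage predictions on
#' the manifest's test rows, projects it to the package and group levels,
#' and computes macro metrics at each level.
#'
#' @param bundle A [tsidl_bundle()].
#' @param manifest A validated manifest with a test split.
#' @param images Named list of image matrices.
#' @param package_of [label_map()] from fine label to package class.
#' @return A `tsidl_eval`: per-level `metrics` and confusion matrices,
#'   plus the prediction table.
#' @export
evaluate_tsidl <- function(bundle, manifest, images, package_of) {
  manifest <- validate_manifest(manifest)
  test <- manifest[manifest$split == "test", ]
  if (nrow(test) == 0) stop("manifest has no test split")
  preds <- infer_two_stage(images[test$image_id], bundle)
  labels <- sort(unique(manifest$drug))
  cm_fine <- build_cm(test$drug, preds$final_label, labels)
  cm_package <- project_cm(cm_fine, package_of)
  cm_group <- project_cm(cm_fine, group_label_map(bundle$sg_map))
  structure(
    list(
      metrics = list(
        drug = macro_metrics(cm_fine),
        package = macro_metrics(cm_package),
        group = macro_metrics(cm_group)
      ),
      cms = list(drug = cm_fine, package = cm_package, group = cm_group),
      predictions = dplyr::bind_cols(
        test[, c("image_id", "drug", "package")], preds[, -1])
    ),
    class = "tsidl_eval"
  )
}

#' @export
print.tsidl_eval <- function(x, ...) {
  for (level in names(x$metrics)) {
    m <- x$metrics[[level]]
    cat(sprintf("%-8s accuracy %.4f | macro R %.4f P %.4f F1 %.4f\n",
      level, m$accuracy, m$macro_recall, m$macro_precision, m$macro_f1))
  }
  invisible(x)
}

#' @rdname tidy.metrics_report
#' @export
glance.tsidl_eval <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$metrics), function(level) {
    dplyr::bind_cols(tibble::tibble(level = level),
      glance(x$metrics[[level]]))
  }))
}

#' Run the full benchmark end to end
#'
#' Generates (or accepts) a synthetic dataset, runs stage-one
#' cross-validation, builds the SG map, selects crops, trains stage-two
#' models, evaluates the two-stage system on the test split, and records
#' the stage-one-only baseline (the deployment model's full-frame test
#' accuracy) for comparison. Optionally retrains every similarity group's
#' stage-two model without its crop to quantify the crop's effect.
#'
#' @param params [synth_params()] for the generator (ignored when
#'   `dataset` is supplied).
#' @param config [train_config()] used for all models.
#' @param grouping [grouping_params()] for the SG map.
#' @param dataset Optional pre-generated `synth_dataset`.
#' @param manual_crops Optional expert crop map (group index to side).
#' @param compare_nocrop Also train per-group no-crop models and report
#'   per-group test accuracy with and without the crop.
#' @return A list with the dataset, stage-one result, SG map, crop spec,
#'   stage-two models, bundle, `eval` (a `tsidl_eval`), `stage1_accuracy`
#'   (baseline), `tsidl_accuracy`, and optionally `crop_effect` (tibble of
#'   per-group accuracies with/without crop).
#' @export
run_benchmark <- function(params = benchmark_params(),
                          config = train_config(input_side = 40L,
                            learning_rate = 0.05, max_epochs = 80L,
                            hidden_units = 128L, seed = params$seed),
                          grouping = grouping_params(),
                          dataset = NULL, manual_crops = NULL,
                          compare_nocrop = FALSE) {
  if (is.null(dataset)) dataset <- generate_dataset(params)
  manifest <- dataset$manifest
  images <- dataset$images
  pkg_map <- package_map(dataset$params)

  stage1 <- run_stage1(manifest, images, config)
  sg_map <- build_sg_map(stage1, pkg_map, grouping)
  cspec <- select_crops(dataset, sg_map, manual_crops = manual_crops,
    config = config)
  stage2 <- train_stage2(manifest, images, sg_map, cspec, config)
  bundle <- tsidl_bundle(stage1$model0, sg_map, cspec, stage2)
  eval <- evaluate_tsidl(bundle, manifest, images, pkg_map)

  test <- manifest[manifest$split == "test", ]
  p1 <- predict(stage1$model0, images[test$image_id])
  stage1_accuracy <- mean(p1$.pred_label == test$drug)

  out <- list(dataset = dataset, stage1 = stage1, sg_map = sg_map,
    crop_spec = cspec, stage2 = stage2, bundle = bundle, eval = eval,
    stage1_accuracy = stage1_accuracy,
    tsidl_accuracy = eval$metrics$drug$accuracy)

  if (compare_nocrop && length(sg_map$groups) > 0) {
    no_crop <- crop_spec(rep(NA_integer_, length(sg_map$groups)),
      base_side = attr(cspec, "base_side"))
    stage2_nc <- train_stage2(manifest, images, sg_map, no_crop, config)
    rows <- lapply(seq_along(sg_map$groups), function(g) {
      members <- sg_map$groups[[g]]$members
      te <- test[test$drug %in% members, ]
      acc_of <- function(model, side) {
        imgs <- lapply(images[te$image_id], apply_crop, side = side)
        mean(predict(model, imgs)$.pred_label == te$drug)
      }
      tibble::tibble(
        group = g,
        n_test = nrow(te),
        crop_side = crop_side(cspec, g),
        acc_crop = acc_of(stage2[[as.character(g)]], crop_side(cspec, g)),
        acc_nocrop = acc_of(stage2_nc[[as.character(g)]], NA_integer_)
      )
    })
    out$crop_effect <- dplyr::bind_rows(rows)
  }
  out
}
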