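#' Synthetic planted-similarity image benchmark
#'
#' The generator renders a fully synthetic analogue of a multi-pose
#' packaged-drug photo collection, so every stage of the two-stage
#' pipeline is testable with no external data. Each class gets
#' `rotations * tilts` grayscale images (default 8 in-plane rotations of
#' 45 degrees times a 3 x 3 grid of -20/0/+20 degree tilt/pitch
#' directions, i.e. 72 poses) of a package-type silhouette shared by its
#' package class. Classes assigned to a *planted similarity group* share
#' all coarse appearance features (silhouette, base tone, label blocks)
#' and differ only in a small, low-contrast, class-unique imprint glyph at
#' the image center — the planted analogue of near-identical pills whose
#' only discriminative signal is the imprint. Unplanted classes carry
#' class-unique label blocks and are easy to tell apart. Pose is realised
#' as an in-plane rotation (with up to 2 degrees of jitter) composed with
#' cosine foreshortening for the tilt, plus illumination gain jitter and
#' pixel noise. Output is pixel-identical for identical seeds.
#'
#' @name synthetic
NULL

#' Generator parameters
#'
#' Defaults state a desk-scale world of 3 package classes x 4 classes each
#' with two planted groups (three classes of package 1; two classes of
#' package 2), the 72-pose capture grid, and a 40/10/22 per-class
#' train/validation/test split (scaled proportionally if the pose count
#' changes) with the 50-image train+validation pool divided into 5
#' cross-validation folds.
#'
#' @param n_packages Number of package classes.
#' @param classes_per_package Fine classes per package.
#' @param planted_groups List of `list(package =, classes =)` entries:
#'   index of the package and indices (within the package) of the classes
#'   forming one planted similarity group. Each group needs >= 2 classes;
#'   groups within a package must be disjoint.
#' @param image_side Rendered frame side in pixels (default 256; 64 is the
#'   usual desk-scale benchmark setting).
#' @param rotations In-plane rotation steps (default 8, i.e. 45 degrees).
#' @param tilts Camera directions, 1-9, taken from the 3 x 3 grid of
#'   -20/0/+20 degree tilt/pitch pairs (default 9).
#' @param imprint_side Side of the central imprint glyph in pixels; must
#'   be below `image_side / 4` so the glyph sits inside the smallest
#'   pyramid crop.
#' @param imprint_contrast Peak-to-peak intensity contrast of the imprint,
#'   in (0, 1] (default 0.15 — low, so the imprint is hard to read at full
#'   frame).
#' @param noise_sd Per-pixel Gaussian noise SD (default 0.05).
#' @param illum_sd SD of the per-image multiplicative illumination gain
#'   (default 0.08).
#' @param split Per-class image counts for train/val/test at 72 poses
#'   (default 40/10/22); rescaled proportionally for other pose counts.
#' @param n_folds Cross-validation folds over the train+val pool
#'   (default 5).
#' @param seed Master RNG seed.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_packages = 3L, classes_per_package = 4L,
                         planted_groups = list(
                           list(package = 1L, classes = 1:3),
                           list(package = 2L, classes = 1:2)
                         ),
                         image_side = 256L, rotations = 8L, tilts = 9L,
                         imprint_side = NULL, imprint_contrast = 0.15,
                         noise_sd = 0.05, illum_sd = 0.08,
                         split = c(train = 40L, val = 10L, test = 22L),
                         n_folds = 5L, seed = 1L) {
  if (is.null(imprint_side)) imprint_side <- floor(image_side / 5)
  stopifnot(n_packages >= 1, classes_per_package >= 1,
    rotations >= 1, tilts >= 1, tilts <= 9,
    imprint_contrast > 0, imprint_contrast <= 1,
    noise_sd >= 0, illum_sd >= 0, n_folds >= 2)
  if (imprint_side >= image_side / 4) {
    stop("imprint_side must be below image_side / 4 so the imprint fits ",
      "the smallest pyramid crop")
  }
  for (g in planted_groups) {
    if (length(g$classes) < 2) {
      stop("planted group of size 1 (package ", g$package, ")")
    }
    stopifnot(g$package >= 1, g$package <= n_packages,
      all(g$classes >= 1), all(g$classes <= classes_per_package))
  }
  for (p in unique(vapply(planted_groups, `[[`, integer(1), "package"))) {
    cls <- unlist(lapply(
      Filter(function(g) g$package == p, planted_groups), `[[`, "classes"))
    if (anyDuplicated(cls)) {
      stop("planted groups overlap within package ", p)
    }
  }
  structure(
    list(
      n_packages = as.integer(n_packages),
      classes_per_package = as.integer(classes_per_package),
      planted_groups = planted_groups,
      image_side = as.integer(image_side),
      rotations = as.integer(rotations), tilts = as.integer(tilts),
      imprint_side = as.integer(imprint_side),
      imprint_contrast = imprint_contrast,
      noise_sd = noise_sd, illum_sd = illum_sd,
      split = split, n_folds = as.integer(n_folds),
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

#' Desk-scale benchmark parameters
#'
#' The standard planted benchmark: 3 packages x 4 classes, two planted
#' groups, 64-pixel frames, 12-pixel imprints at contrast 0.15.
#'
#' @param seed Master RNG seed.
#' @return A [synth_params()] object.
#' @export
benchmark_params <- function(seed = 1L) {
  synth_params(image_side = 64L, imprint_side = 12L, seed = seed)
}

drug_labels <- function(params) {
  unlist(lapply(seq_len(params$n_packages), function(p) {
    sprintf("P%02d_D%02d", p, seq_len(params$classes_per_package))
  }))
}

package_label <- function(p) sprintf("P%02d", p)

#' Fine-to-package label map of a synthetic world
#'
#' @param params A [synth_params()] object.
#' @return A [label_map()] from drug label to package label.
#' @export
package_map <- function(params) {
  fine <- drug_labels(params)
  label_map(fine, substr(fine, 1, 3))
}

#' Ground-truth SG map of the planted groups
#'
#' Echoes the configured planted groups as an `sg_map` (ordered
#' lexicographically by package class) whose residual holds every
#' unplanted class — the reference that grouping-recovery tests compare
#' against.
#'
#' @param params A [synth_params()] object.
#' @return An `sg_map` partitioning the class set.
#' @export
planted_truth <- function(params) {
  groups <- lapply(params$planted_groups, function(g) {
    list(
      package_class = package_label(g$package),
      members = sort(sprintf("P%02d_D%02d", g$package, g$classes))
    )
  })
  ord <- order(vapply(groups, `[[`, character(1), "package_class"),
    vapply(groups, function(g) g$members[1], character(1)))
  groups <- groups[ord]
  residual <- sort(setdiff(drug_labels(params),
    unlist(lapply(groups, `[[`, "members"))))
  sg <- new_sg_map(groups, residual, provenance = list(source = "planted"))
  validate_sg_map(sg, drug_labels(params))
  sg
}

# appearance of one class before pose/noise: package silhouette + coarse
# label blocks (shared within a planted group) + class-unique central
# imprint glyph
render_canvas <- function(params, p, d) {
  s <- params$image_side
  canvas_key <- group_key(params, p, d)
  bg <- 0.12
  img <- matrix(bg, s, s)

  # package silhouette: shape + base tone shared by the whole package
  withr::with_seed(derive_seed(params$seed, 101L, p), {
    base <- stats::runif(1, 0.40, 0.70)
    shape <- (p - 1) %% 3
  })
  ctr <- (s - 1) / 2
  rad <- 0.44 * s
  yy <- matrix(rep(seq_len(s) - 1 - ctr, s), s, s)
  xx <- t(yy)
  mask <- switch(shape + 1,
    yy^2 + xx^2 <= rad^2,                    # disc
    pmax(abs(yy), abs(xx)) <= rad * 0.92,    # square
    abs(yy) + abs(xx) <= rad * 1.25          # diamond
  )
  img[mask] <- base

  # coarse appearance: identical for every member of a planted group,
  # class-unique otherwise. High-contrast quantized label blocks in an
  # annulus of 8 compass slots plus an oriented stripe, so classes with
  # different appearance keys are unambiguous while same-group classes
  # are pixel-identical outside the imprint window.
  withr::with_seed(canvas_key, {
    palette <- seq(0.05, 0.95, length.out = 7)
    slots <- sample(8, 4)
    tones <- sample(palette, 4, replace = TRUE)
    half <- round(stats::runif(4, 0.07, 0.11) * s)
    stripe_dir <- sample(c(0, 45, 90, 135), 1)
    stripe_tone <- sample(palette, 1)
  })
  for (b in 1:4) {
    ang <- (slots[b] - 1) * pi / 4
    oy <- round(ctr + sin(ang) * 0.30 * s)
    ox <- round(ctr + cos(ang) * 0.30 * s)
    y0 <- max(1, oy - half[b]); y1 <- min(s, oy + half[b])
    x0 <- max(1, ox - half[b]); x1 <- min(s, ox + half[b])
    img[y0:y1, x0:x1] <- tones[b]
  }
  # stripe through the annulus, clear of the central imprint window
  th <- stripe_dir * pi / 180
  dist_line <- abs(-sin(th) * xx + cos(th) * yy)
  along <- abs(cos(th) * xx + sin(th) * yy)
  stripe <- dist_line <= 0.045 * s & along >= 0.17 * s & along <= 0.42 * s
  img[stripe] <- stripe_tone

  # class-unique central imprint at low contrast: a 7x7 glyph upsampled
  # to imprint_side by nearest neighbour
  withr::with_seed(derive_seed(params$seed, 301L, p, d), {
    glyph <- matrix(stats::runif(49) > 0.5, 7, 7)
  })
  gs <- params$imprint_side
  up <- glyph[ceiling(seq_len(gs) * 7 / gs), ceiling(seq_len(gs) * 7 / gs)]
  y0 <- floor(s / 2) - floor(gs / 2) + 1
  x0 <- y0
  patch <- img[y0:(y0 + gs - 1), x0:(x0 + gs - 1)]
  img[y0:(y0 + gs - 1), x0:(x0 + gs - 1)] <-
    patch + params$imprint_contrast * (up - 0.5)
  pmin(pmax(img, 0), 1)
}

# seed key for the coarse appearance: shared within a planted group,
# otherwise class-specific
group_key <- function(params, p, d) {
  for (gi in seq_along(params$planted_groups)) {
    g <- params$planted_groups[[gi]]
    if (g$package == p && d %in% g$classes) {
      return(derive_seed(params$seed, 201L, p, 1000L + gi))
    }
  }
  derive_seed(params$seed, 201L, p, d)
}

tilt_grid <- function() {
  g <- expand.grid(tilt = c(-20, 0, 20), pitch = c(-20, 0, 20))
  g[order(abs(g$tilt) + abs(g$pitch)), ]  # frontal pose first
}

render_pose <- function(canvas, params, p, d, pose) {
  rot_idx <- (pose - 1) %% params$rotations
  tilt_idx <- (pose - 1) %/% params$rotations + 1
  tg <- tilt_grid()[seq_len(params$tilts), ]
  withr::with_seed(derive_seed(params$seed, 401L, p, d, pose), {
    angle <- 45 * rot_idx + stats::runif(1, -2, 2)
    m <- pose_matrix(angle, tg$tilt[tilt_idx], tg$pitch[tilt_idx])
    img <- warp_affine(canvas, m, fill = 0.12)
    gain <- 1 + stats::rnorm(1, 0, params$illum_sd)
    img <- img * gain +
      matrix(stats::rnorm(length(img), 0, params$noise_sd), nrow(img))
  })
  pmin(pmax(img, 0), 1)
}

#' Generate the synthetic dataset
#'
#' Renders `rotations * tilts` images per class and assembles the
#' manifest: per class, the train/val counts form a train+validation pool
#' split into `n_folds` disjoint validation blocks, and the remaining
#' images are a fixed test block that never enters cross-validation.
#' Identical seeds give pixel-identical images and identical manifests.
#'
#' @param params A [synth_params()] object.
#' @param dir Optional directory; when given, images are written as ASCII
#'   PGM under `dir/images/`, the manifest as TSV and the parameters as a
#'   JSON sidecar, and the manifest's `path` column is filled.
#' @param render Set `FALSE` to skip rendering and return the manifest
#'   only (count-level checks at large class counts).
#' @return A `synth_dataset`: list with `manifest` (tibble: image_id,
#'   path, drug, package, split, fold, pose), `images` (named list of
#'   matrices, or `NULL` when `render = FALSE`) and `params`.
#' @export
generate_dataset <- function(params, dir = NULL, render = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  n_img <- params$rotations * params$tilts
  frac <- params$split / sum(params$split)
  n_test <- round(frac[["test"]] * n_img)
  n_val <- round(frac[["val"]] * n_img)
  n_train <- n_img - n_test - n_val
  pool_n <- n_train + n_val
  if (pool_n < params$n_folds) {
    stop("train+val pool smaller than the fold count")
  }

  rows <- list()
  images <- if (render) list() else NULL
  for (p in seq_len(params$n_packages)) {
    for (d in seq_len(params$classes_per_package)) {
      drug <- sprintf("P%02d_D%02d", p, d)
      ids <- sprintf("%s_p%03d", drug, seq_len(n_img))
      withr::with_seed(derive_seed(params$seed, 501L, p, d), {
        perm <- sample.int(n_img)
        fold_of_pool <- sample(rep(seq_len(params$n_folds),
          length.out = pool_n))
      })
      split <- rep("test", n_img)
      split[perm[seq_len(pool_n)]] <- "trainval"
      fold <- rep(NA_integer_, n_img)
      fold[perm[seq_len(pool_n)]] <- fold_of_pool
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_id = ids, path = NA_character_, drug = drug,
        package = package_label(p), split = split, fold = fold,
        pose = seq_len(n_img)
      )
      if (render) {
        canvas <- render_canvas(params, p, d)
        for (k in seq_len(n_img)) {
          images[[ids[k]]] <- render_pose(canvas, params, p, d, k)
        }
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)

  if (!is.null(dir)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- file.path(img_dir, paste0(manifest$image_id, ".pgm"))
    if (render) {
      purrr::walk2(manifest$image_id, manifest$path,
        function(id, path) write_pgm(images[[id]], path))
    }
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    jsonlite::write_json(
      params[setdiff(names(params), "planted_groups")],
      file.path(dir, "params.json"), auto_unbox = TRUE)
  }

  structure(list(manifest = manifest, images = images, params = params),
    class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d classes x %d poses = %d images (%s)\n",
    length(unique(x$manifest$drug)),
    x$params$rotations * x$params$tilts, nrow(x$manifest),
    if (is.null(x$images)) "manifest only" else "rendered"))
  invisible(x)
}

#' Mean absolute pixel distance between two classes' clean canvases
#'
#' Diagnostic for the planted-similarity mechanism: the distance between
#' two same-group classes is small at full frame (their coarse appearance
#' is identical) and grows once both canvases are centre-cropped to the
#' imprint region and resized to a common side — cropping is what makes
#' the imprint visible to a classifier.
#'
#' @param params A [synth_params()] object.
#' @param drug_a,drug_b Drug labels.
#' @param crop Optional centre-crop side applied before comparison.
#' @param resize_to Common side both views are resized to (default 32).
#' @return Mean absolute intensity difference.
#' @export
class_distance <- function(params, drug_a, drug_b, crop = NULL,
                           resize_to = 32L) {
  parse <- function(lbl) {
    as.integer(c(substr(lbl, 2, 3), substr(lbl, 6, 7)))
  }
  a <- parse(drug_a); b <- parse(drug_b)
  ca <- render_canvas(params, a[1], a[2])
  cb <- render_canvas(params, b[1], b[2])
  if (!is.null(crop)) {
    ca <- center_crop(ca, crop)
    cb <- center_crop(cb, crop)
  }
  mean(abs(resize_bilinear(ca, resize_to) - resize_bilinear(cb, resize_to)))
}
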