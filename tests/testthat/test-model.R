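test_that("sscnn_spec builds the 8-layer architecture with a sized head", {
  sp <- sscnn_spec(108)
  expect_equal(nrow(sp), 12)  # input + 5 conv + 3 pool + 3 dense
  expect_equal(sum(sp$kind == "conv"), 5)
  expect_equal(sum(sp$kind == "dense"), 3)
  last <- sp[nrow(sp), ]
  expect_equal(last$out_units, 108L)
  expect_equal(last$activation, "softmax")
  expect_equal(sp$out_units[sp$name == "Fc6"], 4096L)

  # only the head changes with the class count
  sp4 <- sscnn_spec(4)
  expect_equal(sp4$out_units[nrow(sp4)], 4L)
  for (col in names(sp)) {
    expect_identical(sp[[col]][-nrow(sp)], sp4[[col]][-nrow(sp4)])
  }

  expect_error(sscnn_spec(1), ">= 2")
})

test_that("infer_shapes reproduces the architecture table sides", {
  shp <- infer_shapes(sscnn_spec(108))
  spatial <- shp$side[shp$kind %in% c("conv", "maxpool")]
  expect_equal(spatial, c(55L, 27L, 27L, 13L, 13L, 13L, 13L, 6L))
  expect_equal(shp$side[shp$name == "Conv1"], 55L)
  expect_equal(shp$side[shp$name == "Pool5"], 6L)
})

test_that("1x1/stride-1 layers preserve the side; collapse is an error", {
  sp <- sscnn_spec(3, input_side = 32L)
  keep <- sp[sp$kind == "input", ]
  one <- dplyr::bind_rows(keep,
    tibble::tibble(name = "c", kind = "conv", maps = 8L, kernel = 1L,
      stride = 1L, padding = 0L, activation = "relu",
      out_units = NA_integer_))
  attr(one, "input_side") <- 32L
  expect_equal(infer_shapes(one)$side[2], 32L)

  tiny <- dplyr::bind_rows(keep,
    tibble::tibble(name = "huge", kind = "conv", maps = 8L, kernel = 64L,
      stride = 1L, padding = 0L, activation = "relu",
      out_units = NA_integer_))
  attr(tiny, "input_side") <- 32L
  expect_error(infer_shapes(tiny), "huge")
})

solid_images <- function(value, n, side = 16, noise = 0.02, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    matrix(value, side, side) + matrix(rnorm(side^2, 0, noise), side, side)
  }))
}

test_that("a separable two-class toy reaches perfect validation accuracy", {
  tr <- c(solid_images(0.2, 10, seed = 1), solid_images(0.8, 10, seed = 2))
  va <- c(solid_images(0.2, 4, seed = 3), solid_images(0.8, 4, seed = 4))
  fit <- train_classifier(tr, rep(c("dark", "light"), each = 10),
    va, rep(c("dark", "light"), each = 4),
    quick_config(seed = 11, epochs = 5))
  expect_equal(max(fit$curves$val_acc), 1)
  expect_lte(fit$best_epoch, 5)
  # converged toy model reproduces its own training labels
  preds <- predict(fit, tr)
  expect_equal(preds$.pred_label, rep(c("dark", "light"), each = 10))
})

test_that("training is deterministic given the seed", {
  tr <- c(solid_images(0.3, 8, seed = 5), solid_images(0.7, 8, seed = 6))
  va <- c(solid_images(0.3, 3, seed = 7), solid_images(0.7, 3, seed = 8))
  labs_tr <- rep(c("a", "b"), each = 8)
  labs_va <- rep(c("a", "b"), each = 3)
  f1 <- train_classifier(tr, labs_tr, va, labs_va, quick_config(seed = 42))
  f2 <- train_classifier(tr, labs_tr, va, labs_va, quick_config(seed = 42))
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$best_epoch, f2$best_epoch)
  expect_identical(f1$w2, f2$w2)
  f3 <- train_classifier(tr, labs_tr, va, labs_va, quick_config(seed = 43))
  expect_false(identical(f3$w2, f1$w2))
})

test_that("the checkpoint is never worse than any recorded epoch", {
  tr <- c(solid_images(0.35, 8, seed = 9), solid_images(0.65, 8, seed = 10))
  va <- c(solid_images(0.35, 4, seed = 11), solid_images(0.65, 4, seed = 12))
  fit <- train_classifier(tr, rep(c("a", "b"), each = 8),
    va, rep(c("a", "b"), each = 4), quick_config(seed = 3, epochs = 8))
  best <- fit$curves$val_acc[fit$best_epoch]
  expect_true(all(fit$curves$val_acc <= best))
  # earliest epoch attaining the maximum wins ties
  expect_equal(fit$best_epoch, min(which(fit$curves$val_acc == best)))
})

test_that("prediction contract: scores sum to 1, empty batch allowed", {
  tr <- c(solid_images(0.2, 6, seed = 13), solid_images(0.8, 6, seed = 14))
  va <- c(solid_images(0.2, 2, seed = 15), solid_images(0.8, 2, seed = 16))
  fit <- train_classifier(tr, rep(c("a", "b"), each = 6),
    va, rep(c("a", "b"), each = 2), quick_config(seed = 1, epochs = 3))
  p <- predict(fit, va)
  expect_equal(p$.pred_a + p$.pred_b, rep(1, 4), tolerance = 1e-6)
  empty <- predict(fit, list())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c(".pred_label", ".pred_a", ".pred_b"))
})

test_that("train_classifier validates its inputs", {
  imgs <- solid_images(0.5, 4)
  expect_error(train_classifier(list(), character(0), imgs, rep("a", 4)),
    "non-empty")
  expect_error(train_classifier(imgs, rep("a", 4), imgs, rep("a", 4)),
    "single class")
  tr <- c(solid_images(0.2, 4), solid_images(0.8, 4, seed = 2))
  expect_error(train_classifier(tr, rep(c("a", "b"), each = 4),
    imgs, rep("z", 4)), "z")
})

test_that("model checkpoints round-trip through the directory format", {
  tr <- c(solid_images(0.2, 6, seed = 21), solid_images(0.8, 6, seed = 22))
  va <- c(solid_images(0.2, 2, seed = 23), solid_images(0.8, 2, seed = 24))
  fit <- train_classifier(tr, rep(c("a", "b"), each = 6),
    va, rep(c("a", "b"), each = 2), quick_config(seed = 2, epochs = 3))
  dir <- withr::local_tempdir()
  write_model(fit, dir)
  back <- read_model(dir)
  expect_equal(back$labels, fit$labels)
  expect_equal(back$best_epoch, fit$best_epoch)
  expect_equal(back$w2, fit$w2, tolerance = 1e-12)
  expect_equal(predict(back, va)$.pred_label, predict(fit, va)$.pred_label)
})

test_that("tidy/glance/autoplot work on fitted models", {
  tr <- c(solid_images(0.2, 5, seed = 31), solid_images(0.8, 5, seed = 32))
  va <- c(solid_images(0.2, 2, seed = 33), solid_images(0.8, 2, seed = 34))
  fit <- train_classifier(tr, rep(c("a", "b"), each = 5),
    va, rep(c("a", "b"), each = 2), quick_config(seed = 9, epochs = 4))
  expect_named(tidy(fit),
    c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  expect_equal(nrow(tidy(fit)), 4)
  expect_s3_class(autoplot(fit), "ggplot")
  g <- glance(fit)
  expect_equal(g$n_classes, 2)
})
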