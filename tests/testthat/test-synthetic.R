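test_that("parameter validation catches degenerate worlds", {
  expect_error(synth_params(planted_groups = list(
    list(package = 1L, classes = 1L))), "size 1")
  expect_error(synth_params(image_side = 64, imprint_side = 20),
    "image_side / 4")
  expect_error(synth_params(planted_groups = list(
    list(package = 1L, classes = 1:2),
    list(package = 1L, classes = 2:3))), "overlap")
})

test_that("default pose grid yields 72 images per class with 40/10/22 splits", {
  p <- synth_params(n_packages = 1L, classes_per_package = 2L,
    planted_groups = list(list(package = 1L, classes = 1:2)),
    image_side = 64L, imprint_side = 12L)
  ds <- generate_dataset(p, render = FALSE)
  counts <- table(ds$manifest$drug)
  expect_true(all(counts == 72))
  per_split <- table(ds$manifest$drug, ds$manifest$split)
  expect_true(all(per_split[, "trainval"] == 50))
  expect_true(all(per_split[, "test"] == 22))
  # the pool divides into 5 validation blocks of 10 per class
  pool <- ds$manifest[ds$manifest$split == "trainval", ]
  blocks <- table(pool$drug, pool$fold)
  expect_true(all(blocks == 10))
  expect_true(all(is.na(ds$manifest$fold[ds$manifest$split == "test"])))
})

test_that("generation is deterministic and seed-sensitive", {
  p <- tiny_params(seed = 7)
  a <- generate_dataset(p)
  b <- generate_dataset(tiny_params(seed = 7))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$images, b$images)
  c <- generate_dataset(tiny_params(seed = 8))
  expect_false(identical(a$images[[1]], c$images[[1]]))
})

test_that("planted_truth echoes the configured groups as a partition", {
  p <- benchmark_params()
  sg <- planted_truth(p)
  expect_equal(n_groups(sg), 2)
  expect_equal(sg$groups[[1]]$members, c("P01_D01", "P01_D02", "P01_D03"))
  expect_equal(sg$groups[[2]]$members, c("P02_D01", "P02_D02"))
  all_members <- c(unlist(lapply(sg$groups, `[[`, "members")), sg$residual)
  expect_setequal(all_members, unique(generate_dataset(p,
    render = FALSE)$manifest$drug))

  none <- synth_params(planted_groups = list(), image_side = 64,
    imprint_side = 12)
  expect_equal(n_groups(planted_truth(none)), 0)
  expect_equal(length(planted_truth(none)$residual), 12)
})

test_that("same-group classes are near-identical at full frame but differ
           under the central crop", {
  p <- benchmark_params(seed = 2)
  full <- class_distance(p, "P01_D01", "P01_D02")
  cropped <- class_distance(p, "P01_D01", "P01_D02",
    crop = p$image_side / 4)
  expect_lt(full, cropped)
  # and unplanted classes are far apart already at full frame
  expect_gt(class_distance(p, "P03_D01", "P03_D02"), 5 * full)
})

test_that("images land in [0,1] with the expected geometry", {
  p <- tiny_params()
  ds <- generate_dataset(p)
  img <- ds$images[[1]]
  expect_equal(dim(img), c(48L, 48L))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(length(ds$images), nrow(ds$manifest))
})

test_that("writing a dataset produces a readable manifest and PGM images", {
  p <- tiny_params()
  dir <- withr::local_tempdir()
  ds <- generate_dataset(p, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "params.json")))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), nrow(ds$manifest))
  imgs <- load_images(man[1:3, ])
  expect_equal(dim(imgs[[1]]), dim(ds$images[[man$image_id[1]]]))
  expect_equal(imgs[[1]], ds$images[[man$image_id[1]]],
    tolerance = 1 / 255)
})
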