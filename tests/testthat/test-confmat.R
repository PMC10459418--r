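test_that("build_cm tallies truth/prediction pairs", {
  cm <- build_cm(c("A", "A", "B"), c("A", "B", "B"))
  expect_s3_class(cm, "confusion_matrix")
  expect_identical(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 1L), 2, 2,
    dimnames = list(truth = c("A", "B"), prediction = c("A", "B"))))

  # a perfect predictor gives a diagonal matrix
  lab <- sample(LETTERS[1:4], 60, replace = TRUE)
  cm2 <- build_cm(lab, lab)
  expect_true(all(unclass(cm2)[upper.tri(cm2) | lower.tri(cm2)] == 0))
  expect_equal(sum(diag(unclass(cm2))), 60)

  expect_error(build_cm(c("A", "Z"), c("A", "A"), labels = c("A", "B")),
    "Z")
  expect_error(build_cm("A", c("A", "B")), "equal length")
})

test_that("build_cm matches a naive double-loop tally on random pairs", {
  withr::with_seed(42, {
    labs <- sprintf("L%d", 1:6)
    truth <- sample(labs, 500, replace = TRUE)
    pred <- sample(labs, 500, replace = TRUE)
  })
  cm <- unclass(build_cm(truth, pred, labs))
  naive <- matrix(0L, 6, 6, dimnames = list(labs, labs))
  for (k in seq_along(truth)) {
    naive[truth[k], pred[k]] <- naive[truth[k], pred[k]] + 1L
  }
  expect_equal(unname(cm[, ]), unname(naive))
})

test_that("aggregate_folds sums matrices and is order-invariant", {
  eye <- confusion_matrix(diag(1, 2), c("A", "B"))
  agg <- aggregate_folds(rep(list(eye), 5))
  expect_equal(unname(diag(unclass(agg))), c(5, 5))

  withr::with_seed(7, cms <- replicate(5, random_cm(4), simplify = FALSE))
  agg1 <- aggregate_folds(cms)
  agg2 <- aggregate_folds(rev(cms))
  expect_identical(agg1, agg2)
  expect_equal(sum(unclass(agg1)),
    sum(vapply(cms, function(x) sum(unclass(x)), numeric(1))))
  # independent elementwise recomputation
  expect_equal(unclass(agg1)[2, 3],
    sum(vapply(cms, function(x) unclass(x)[2, 3], numeric(1))))

  other <- confusion_matrix(diag(1, 2), c("A", "C"))
  expect_error(aggregate_folds(list(eye, other)), "B.*C|C.*B")
})

test_that("macro_metrics matches hand-computed and degenerate cases", {
  expect_error(macro_metrics(confusion_matrix(matrix(0L, 2, 2),
    c("A", "B"))), "empty")

  perfect <- confusion_matrix(diag(5L, 3), c("a", "b", "c"))
  m <- macro_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)

  cm <- confusion_matrix(matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE),
    c("a", "b"))
  m <- macro_metrics(cm)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$macro_recall, (0.8 + 0.9) / 2)
  expect_equal(m$macro_precision, (8 / 9 + 9 / 11) / 2)
  expect_equal(m$macro_f1,
    2 * m$macro_precision * m$macro_recall /
      (m$macro_precision + m$macro_recall))

  # class never predicted: precision contributes 0, with a warning
  degen <- confusion_matrix(matrix(c(5, 0, 5, 0), 2, 2, byrow = TRUE),
    c("a", "b"))
  expect_warning(md <- macro_metrics(degen), "never-predicted")
  expect_equal(md$macro_precision, 0.25)
})

test_that("macro_metrics agrees with the brute-force oracle on random CMs", {
  withr::with_seed(99, {
    for (k in 1:200) {
      r <- sample(2:12, 1)
      cm <- random_cm(r)
      if (sum(unclass(cm)) == 0) next
      got <- suppressWarnings(macro_metrics(cm))
      want <- oracle_macro(unclass(cm))
      expect_equal(got$macro_recall, want$macro_recall, tolerance = 1e-12)
      expect_equal(got$macro_precision, want$macro_precision,
        tolerance = 1e-12)
      expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
      expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    }
  })
})

test_that("per-class identities hold: TP/FN/FP sums recover the total", {
  withr::with_seed(5, cm <- random_cm(6))
  m <- unclass(cm)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  expect_equal(sum(tp + fn), sum(m))
  expect_equal(sum(tp + fp), sum(m))
})

test_that("project_cm regroups cells and conserves the total", {
  withr::with_seed(11, cm <- random_cm(4))
  labs <- rownames(unclass(cm))
  ident <- label_map(labs, labs)
  expect_equal(unname(unclass(project_cm(cm, ident))[, ]),
    unname(unclass(cm)[, ]))

  map <- label_map(labs, c("X", "X", "Y", "Y"))
  coarse <- project_cm(cm, map)
  expect_equal(sum(unclass(coarse)), sum(unclass(cm)))
  # cell-by-cell regrouping oracle
  m <- unclass(cm)
  expect_equal(unclass(coarse)["X", "Y"], sum(m[1:2, 3:4]))
  # within-coarse confusion lands on the coarse diagonal
  expect_equal(unclass(coarse)["X", "X"], sum(m[1:2, 1:2]))

  expect_error(project_cm(cm, label_map(labs[-1], c("X", "Y", "Y"))),
    "unmapped")
})

test_that("coarse accuracy is never below fine accuracy", {
  withr::with_seed(21, {
    for (k in 1:25) {
      cm <- random_cm(6)
      if (sum(unclass(cm)) == 0) next
      map <- label_map(rownames(unclass(cm)),
        sample(c("U", "V", "W"), 6, replace = TRUE))
      fine <- suppressWarnings(macro_metrics(cm))$accuracy
      coarse <- suppressWarnings(macro_metrics(project_cm(cm, map)))$accuracy
      expect_gte(coarse, fine)
    }
  })
})

test_that("CM TSV and metrics JSON round-trips are exact", {
  withr::with_seed(3, cm <- random_cm(5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cm(cm, path)
  expect_identical(read_cm(path), cm)

  rep <- suppressWarnings(macro_metrics(cm))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep, jpath)
  back <- read_metrics(jpath)
  expect_equal(back$macro_f1, rep$macro_f1)
  expect_equal(back$per_class$recall, rep$per_class$recall)

  # fixed key names in the serialization contract
  keys <- names(jsonlite::read_json(jpath))
  expect_setequal(keys, c("macro_recall", "macro_precision", "macro_f1",
    "accuracy", "per_class"))
})

test_that("tidy/glance methods return well-formed tibbles", {
  cm <- build_cm(c("A", "A", "B"), c("A", "B", "B"))
  td <- tidy(cm)
  expect_named(td, c("truth", "prediction", "n"))
  expect_equal(sum(td$n), 3)
  g <- glance(macro_metrics(cm))
  expect_equal(nrow(g), 1)
  expect_true(all(c("accuracy", "macro_f1") %in% names(g)))
})
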