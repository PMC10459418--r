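make_cvcm <- function(rows, labels) {
  confusion_matrix(matrix(rows, length(labels), length(labels),
    byrow = TRUE), labels)
}

test_that("default thresholds mirror the stated protocol", {
  p <- grouping_params()
  expect_equal(p$tp_threshold, 48L)
  expect_equal(p$fn_threshold, 1L)
  expect_equal(p$support, 50L)
})

test_that("a perfect diagonal CVCM yields a single residual group", {
  labs <- sprintf("D%d", 1:5)
  cvcm <- confusion_matrix(diag(50L, 5), labs)
  pkg <- label_map(labs, rep("AMP", 5))
  sg <- find_similar_groups(cvcm, pkg)
  expect_equal(n_groups(sg), 0)
  expect_equal(sg$residual, labs)
})

test_that("manual trace: one red class pulls its same-package partner", {
  labs <- c("A", "B", "C")
  # A: 47 TP with 3 into B; B and C clean
  cvcm <- make_cvcm(c(47, 3, 0, 0, 50, 0, 0, 0, 49), labs)
  pkg <- label_map(labs, c("AMP", "AMP", "AMP"))
  sg <- find_similar_groups(cvcm, pkg)
  expect_equal(n_groups(sg), 1)
  expect_equal(sg$groups[[1]]$members, c("A", "B"))
  expect_equal(sg$groups[[1]]$package_class, "AMP")
  expect_equal(sg$residual, "C")
  expect_equal(assign_group(c("A", "B", "C"), sg), c(1L, 1L, 2L))
})

test_that("cross-package partners are excluded and singletons dissolve", {
  labs <- c("A", "D", "E")
  # A (package X) misroutes only into D (package Y): no same-package
  # partner, so A's list dissolves into the residual with a warning
  cvcm <- make_cvcm(c(46, 4, 0, 0, 50, 0, 0, 0, 50), labs)
  pkg <- label_map(labs, c("X", "Y", "Y"))
  expect_warning(
    sg <- suppressMessages(find_similar_groups(cvcm, pkg)),
    "dissolved")
  expect_equal(n_groups(sg), 0)
  expect_setequal(sg$residual, labs)
})

test_that("grouping matches the brute-force oracle on random CVCMs", {
  withr::with_seed(1234, {
    for (k in 1:200) {
      r <- sample(3:10, 1)
      labs <- sprintf("D%02d", seq_len(r))
      pkgs <- sample(c("AMP", "BOT", "CCB"), r, replace = TRUE)
      # mostly-diagonal CVCM with support 50 and occasional confusions
      m <- matrix(0L, r, r)
      for (i in seq_len(r)) {
        errs <- sample(0:4, 1)
        diag_v <- 50 - errs
        m[i, i] <- diag_v
        if (errs > 0) {
          dest <- sample(setdiff(seq_len(r), i), min(errs, r - 1),
            replace = FALSE)
          for (d in dest) m[i, d] <- m[i, d] + 1L
          m[i, i] <- 50 - sum(m[i, -i])
        }
      }
      cvcm <- confusion_matrix(m, labs)
      pkg_of <- stats::setNames(pkgs, labs)
      got <- suppressMessages(suppressWarnings(
        find_similar_groups(cvcm, label_map(labs, pkgs))))
      want <- oracle_groups(m, labs, pkg_of)
      expect_equal(length(got$groups), length(want$groups))
      for (g in seq_along(got$groups)) {
        expect_equal(got$groups[[g]]$members, want$groups[[g]])
        expect_equal(got$groups[[g]]$package_class,
          names(want$groups)[g])
      }
      expect_equal(got$residual, want$residual)
      # partition property on every call
      all_members <- c(unlist(lapply(got$groups, `[[`, "members")),
        got$residual)
      expect_setequal(all_members, labs)
      expect_equal(anyDuplicated(all_members), 0L)
    }
  })
})

test_that("threshold monotonicity: more permissive thresholds grow sets", {
  withr::with_seed(77, {
    labs <- sprintf("D%d", 1:6)
    m <- matrix(0L, 6, 6)
    diag(m) <- c(50, 48, 45, 50, 47, 49)
    m[2, 3] <- 2; m[3, 2] <- 3; m[3, 4] <- 2; m[5, 6] <- 3; m[6, 5] <- 1
    cvcm <- confusion_matrix(m, labs)
    pkg <- label_map(labs, rep("P", 6))
    red_at <- function(thr) {
      sg <- suppressMessages(suppressWarnings(find_similar_groups(
        cvcm, pkg, grouping_params(tp_threshold = thr))))
      unlist(lapply(sg$groups, `[[`, "members"))
    }
    grouped_46 <- red_at(46)
    grouped_48 <- red_at(48)
    expect_true(all(grouped_46 %in% grouped_48))
  })
})

test_that("grouping is deterministic including group order", {
  withr::with_seed(31, cvcm <- {
    m <- diag(47L, 6)
    m[1, 2] <- 3; m[3, 4] <- 3; m[5, 6] <- 3
    m[2, 1] <- 3; m[4, 3] <- 3; m[6, 5] <- 3
    confusion_matrix(m, sprintf("D%d", 1:6))
  })
  pkg <- label_map(sprintf("D%d", 1:6), c("B", "B", "A", "A", "C", "C"))
  a <- find_similar_groups(cvcm, pkg)
  b <- find_similar_groups(cvcm, pkg)
  expect_identical(a$groups, b$groups)
  # lexicographic package order: A before B before C
  expect_equal(vapply(a$groups, `[[`, character(1), "package_class"),
    c("A", "B", "C"))
})

test_that("relative threshold mode scales with row support", {
  labs <- c("A", "B", "C")
  # support 100 per class; 96/100 with 4 into B is red at fraction 0.96
  cvcm <- make_cvcm(c(96, 4, 0, 0, 100, 0, 0, 0, 100), labs)
  pkg <- label_map(labs, rep("P", 3))
  sg_abs <- find_similar_groups(cvcm, pkg)   # 96 > 48: nothing is red
  expect_equal(n_groups(sg_abs), 0)
  sg_rel <- find_similar_groups(cvcm, pkg,
    grouping_params(tp_fraction = 0.96, support = 100))
  expect_equal(n_groups(sg_rel), 1)
  expect_equal(sg_rel$groups[[1]]$members, c("A", "B"))
})

test_that("assign_group errors on unknown labels and routes residual", {
  labs <- sprintf("D%d", 1:4)
  cvcm <- confusion_matrix(diag(50L, 4), labs)
  sg <- find_similar_groups(cvcm, label_map(labs, rep("P", 4)))
  expect_equal(assign_group("D2", sg), 1L)  # residual index N+1 = 1
  expect_error(assign_group("nope", sg), "nope")
})

test_that("SG map JSON round-trip preserves the routing contract", {
  labs <- c("A", "B", "C", "D")
  cvcm <- make_cvcm(c(40, 10, 0, 0, 8, 42, 0, 0, 0, 0, 50, 0,
    0, 0, 0, 50), labs)
  sg <- find_similar_groups(cvcm, label_map(labs, c("P", "P", "Q", "Q")))
  path <- withr::local_tempfile(fileext = ".json")
  write_sg_map(sg, path)
  back <- read_sg_map(path)
  expect_equal(back$groups, sg$groups)
  expect_equal(back$residual, sg$residual)
  expect_equal(assign_group(labs, back), assign_group(labs, sg))
})
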