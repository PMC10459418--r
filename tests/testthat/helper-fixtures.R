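# Shared fixtures: tiny training configs and a cached desk-scale dataset.

# quick MLP config for unit tests (not the benchmark config)
quick_config <- function(seed = 1L, epochs = 10L) {
  train_config(input_side = 16L, learning_rate = 0.1, max_epochs = epochs,
    hidden_units = 16L, seed = seed)
}

# the benchmark training config used by the acceptance suite
bench_config <- function(seed = 1L) {
  train_config(input_side = 40L, learning_rate = 0.05, max_epochs = 80L,
    hidden_units = 128L, seed = seed)
}

# small 2-package world for fast pipeline tests: 2 x 3 classes, one
# planted pair, 48-px frames, 24 poses (split scales to 13/4/7)
tiny_params <- function(seed = 1L) {
  synth_params(
    n_packages = 2L, classes_per_package = 3L,
    planted_groups = list(list(package = 1L, classes = 1:2)),
    image_side = 48L, rotations = 8L, tilts = 3L, imprint_side = 10L,
    seed = seed
  )
}

# cache one rendered benchmark dataset per session (used by several files)
bench_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(benchmark_params(seed = 1L))
    }
    cache
  }
})

# independent brute-force oracle for the macro metrics: per-class loops,
# no shared code with macro_metrics()
oracle_macro <- function(m) {
  r <- nrow(m)
  rec <- pre <- f1 <- numeric(r)
  for (i in seq_len(r)) {
    tp <- m[i, i]
    fn <- sum(m[i, ]) - tp
    fp <- sum(m[, i]) - tp
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    pre[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
  }
  mr <- mean(rec); mp <- mean(pre)
  list(
    macro_recall = mr, macro_precision = mp,
    macro_f1 = if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr),
    accuracy = sum(diag(m)) / sum(m)
  )
}

# independent brute-force oracle for the grouping algorithm: naive set
# operations following the red/yellow/SD-list steps literally
oracle_groups <- function(m, labels, pkg_of, tp_threshold = 48,
                          fn_threshold = 1) {
  red <- labels[diag(m) <= tp_threshold]
  sd_lists <- list()
  for (p in sort(unique(pkg_of[red]))) {
    members <- character(0)
    for (r in red[pkg_of[red] == p]) {
      i <- which(labels == r)
      yellow <- labels[m[i, ] >= fn_threshold]
      yellow <- setdiff(yellow, r)
      yellow <- yellow[pkg_of[yellow] == p]
      members <- union(members, c(r, yellow))
    }
    if (length(members) >= 2) {
      sd_lists[[p]] <- sort(members)
    }
  }
  residual <- sort(setdiff(labels, unlist(sd_lists)))
  list(groups = sd_lists[sort(names(sd_lists))], residual = residual)
}

random_cm <- function(r, max_count = 50) {
  m <- matrix(sample(0:max_count, r * r, replace = TRUE), r, r)
  confusion_matrix(m, sprintf("C%02d", seq_len(r)))
}
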