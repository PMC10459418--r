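#' Classifier architectures
#'
#' Architectures are declarative layer tables: an input layer followed by
#' convolution / max-pooling / fully connected layers with their kernel,
#' stride, padding and activation. The single-stage CNN (SSCNN) is an
#' AlexNet-shaped trunk — five convolutional and three fully connected
#' layers on a 227-pixel, 3-channel input — with the final softmax head
#' sized to the number of classes. Shape inference reproduces each layer's
#' spatial side exactly; training of the desk-scale backbone is handled by
#' [train_classifier()].
#'
#' @name architectures
NULL

layer_spec <- function(name, kind, maps = NA_integer_, kernel = NA_integer_,
                       stride = NA_integer_, padding = NA_integer_,
                       activation = "none", out_units = NA_integer_) {
  if (kind %in% c("conv", "maxpool")) {
    stopifnot(!is.na(kernel), !is.na(stride), stride >= 1, !is.na(padding))
  }
  tibble::tibble(
    name = name, kind = kind, maps = as.integer(maps),
    kernel = as.integer(kernel), stride = as.integer(stride),
    padding = as.integer(padding), activation = activation,
    out_units = as.integer(out_units)
  )
}

#' The SSCNN architecture table
#'
#' Builds the eight-layer AlexNet-shaped architecture: Conv1 96x11x11/4,
#' Pool1 3x3/2, Conv2 256x5x5/1 pad 2, Pool2 3x3/2, Conv3/4 384x3x3/1
#' pad 1, Conv5 256x3x3/1 pad 1, Pool5 3x3/2, then fully connected layers
#' of 4096, 4096 and `n_classes` units, ReLU throughout and softmax on the
#' head. Input is 227 x 227 x 3.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param input_side Input side in pixels (default 227).
#' @return An `architecture_spec`: a layer tibble with attributes
#'   `input_side`, `channels`, `n_classes`.
#' @export
sscnn_spec <- function(n_classes, input_side = 227L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  layers <- dplyr::bind_rows(
    layer_spec("Input", "input", maps = 3),
    layer_spec("Conv1", "conv", 96, kernel = 11, stride = 4, padding = 0,
      activation = "relu"),
    layer_spec("Pool1", "maxpool", 96, kernel = 3, stride = 2, padding = 0),
    layer_spec("Conv2", "conv", 256, kernel = 5, stride = 1, padding = 2,
      activation = "relu"),
    layer_spec("Pool2", "maxpool", 256, kernel = 3, stride = 2, padding = 0),
    layer_spec("Conv3", "conv", 384, kernel = 3, stride = 1, padding = 1,
      activation = "relu"),
    layer_spec("Conv4", "conv", 384, kernel = 3, stride = 1, padding = 1,
      activation = "relu"),
    layer_spec("Conv5", "conv", 256, kernel = 3, stride = 1, padding = 1,
      activation = "relu"),
    layer_spec("Pool5", "maxpool", 256, kernel = 3, stride = 2, padding = 0),
    layer_spec("Fc6", "dense", activation = "relu", out_units = 4096),
    layer_spec("Fc7", "dense", activation = "relu", out_units = 4096),
    layer_spec("Fc8", "dense", activation = "softmax",
      out_units = n_classes)
  )
  structure(layers, class = c("architecture_spec", class(layers)),
    input_side = as.integer(input_side), channels = 3L,
    n_classes = as.integer(n_classes))
}

#' Infer per-layer spatial sides
#'
#' Applies the standard output-size rule
#' `floor((n + 2 * padding - kernel) / stride) + 1` layer by layer from the
#' input side. Dense layers carry `NA` (no spatial extent). A layer whose
#' inferred side is not positive is an error naming the layer.
#'
#' @param spec An `architecture_spec`.
#' @return Tibble with columns `name`, `kind`, `side`; e.g. the SSCNN on a
#'   227-pixel input yields sides 55, 27, 27, 13, 13, 13, 13, 6 for
#'   Conv1..Pool5.
#' @export
infer_shapes <- function(spec) {
  side <- attr(spec, "input_side")
  out <- integer(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    if (kind == "input") {
      out[i] <- side
    } else if (kind %in% c("conv", "maxpool")) {
      side <- floor((side + 2 * spec$padding[i] - spec$kernel[i]) /
        spec$stride[i]) + 1
      if (side <= 0) {
        stop("layer ", spec$name[i], " collapses the spatial extent (side ",
          side, ")")
      }
      out[i] <- side
    } else {
      out[i] <- NA_integer_
    }
  }
  tibble::tibble(name = spec$name, kind = spec$kind, side = as.integer(out))
}

#' Training configuration
#'
#' Defaults follow the reference protocol: initial learning rate 1e-4,
#' batch size 32, momentum stochastic gradient descent (momentum
#' coefficient 0.9 — the conventional value; it is not fixed by the
#' protocol), at most 100 epochs with validation every epoch, and the
#' checkpoint with the highest validation accuracy (earliest epoch on
#' ties) returned as the final model. `max_iterations`, when set, caps the
#' total minibatch count instead.
#'
#' @param learning_rate Positive step size (default 1e-4).
#' @param batch_size Minibatch size (default 32).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param max_epochs Epoch cap (default 100).
#' @param max_iterations Optional minibatch cap overriding the epoch cap.
#' @param seed RNG seed controlling init and shuffling.
#' @param input_side Side images are resized to before the input layer
#'   (default 227; desk-scale runs use 32).
#' @param hidden_units Hidden width of the MLP backbone (0 = multinomial
#'   logistic regression).
#' @param pretrained_init Reserved flag for externally initialised
#'   weights; the desk-scale backbone always uses seeded random init.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         momentum = 0.9, max_epochs = 100L,
                         max_iterations = NULL, seed = 1L,
                         input_side = 227L, hidden_units = 64L,
                         pretrained_init = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, momentum >= 0,
    momentum < 1, max_epochs >= 1, input_side >= 1, hidden_units >= 0)
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      momentum = momentum, max_epochs = as.integer(max_epochs),
      max_iterations = if (is.null(max_iterations)) NULL else
        as.integer(max_iterations),
      seed = as.integer(seed), input_side = as.integer(input_side),
      hidden_units = as.integer(hidden_units),
      pretrained_init = isTRUE(pretrained_init)
    ),
    class = "train_config"
  )
}

# deterministic 32-bit sub-seed derivation, keeps everything under 2^31
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 1000003 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h)
}

images_to_features <- function(images, side) {
  if (length(images) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = side * side))
  }
  t(vapply(images, function(im) as.vector(resize_bilinear(im, side)),
    numeric(side * side)))
}

#' Train the desk-scale classifier
#'
#' Fits the trainable backbone — a one-hidden-layer ReLU/softmax
#' multilayer perceptron over resized pixel intensities — with minibatch
#' momentum SGD on the cross-entropy loss. Training and validation
#' accuracy and loss are recorded every epoch; the returned model carries
#' the parameters of the earliest epoch attaining the maximum validation
#' accuracy. Fully deterministic given `config$seed`.
#'
#' @param train_images,val_images Lists of grayscale image matrices (any
#'   sizes; resized to `config$input_side`).
#' @param train_labels,val_labels Character label vectors; validation
#'   labels must be a subset of training labels.
#' @param config A [train_config()].
#' @return A `tsidl_model` with the weights, ordered label set, per-epoch
#'   `curves` tibble, `best_epoch` and `seed`.
#' @export
train_classifier <- function(train_images, train_labels,
                             val_images, val_labels,
                             config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_images) == 0 || length(val_images) == 0) {
    stop("training and validation splits must be non-empty")
  }
  train_labels <- as.character(train_labels)
  val_labels <- as.character(val_labels)
  labels <- sort(unique(train_labels))
  if (length(labels) < 2) stop("training set has a single class")
  if (!all(val_labels %in% labels)) {
    stop("validation labels outside the training label set: ",
      paste(setdiff(val_labels, labels), collapse = ", "))
  }

  side <- config$input_side
  x_tr <- images_to_features(train_images, side) - 0.5
  x_va <- images_to_features(val_images, side) - 0.5
  y_tr <- match(train_labels, labels)
  y_va <- match(val_labels, labels)
  n <- nrow(x_tr)
  d <- ncol(x_tr)
  k <- length(labels)
  h <- config$hidden_units

  withr::with_seed(config$seed, {
    if (h > 0) {
      w1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
      b1 <- numeric(h)
      w2 <- matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k)
      b2 <- numeric(k)
      vel <- list(w1 = w1 * 0, b1 = b1, w2 = w2 * 0, b2 = b2)
    } else {
      w2 <- matrix(stats::rnorm(d * k, sd = sqrt(1 / d)), d, k)
      b2 <- numeric(k)
      w1 <- NULL; b1 <- NULL
      vel <- list(w2 = w2 * 0, b2 = b2)
    }

    forward <- function(x) {
      if (h > 0) {
        a1 <- pmax(sweep(x %*% w1, 2, b1, `+`), 0)
        z <- sweep(a1 %*% w2, 2, b2, `+`)
        list(a1 = a1, probs = softmax_rows(z))
      } else {
        z <- sweep(x %*% w2, 2, b2, `+`)
        list(a1 = NULL, probs = softmax_rows(z))
      }
    }
    eval_split <- function(x, y) {
      p <- forward(x)$probs
      pred <- max.col(p, ties.method = "first")
      loss <- -mean(log(pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)))
      c(loss = loss, acc = mean(pred == y))
    }

    lr <- config$learning_rate
    mom <- config$momentum
    bs <- config$batch_size
    iters <- 0L
    curves <- vector("list", config$max_epochs)
    best <- list(epoch = 0L, acc = -Inf, w1 = w1, b1 = b1, w2 = w2, b2 = b2)
    n_epochs_run <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1, n)]
        xb <- x_tr[idx, , drop = FALSE]
        yb <- y_tr[idx]
        m <- length(idx)
        fw <- forward(xb)
        delta <- fw$probs
        delta[cbind(seq_len(m), yb)] <- delta[cbind(seq_len(m), yb)] - 1
        delta <- delta / m
        if (h > 0) {
          g_w2 <- crossprod(fw$a1, delta)
          g_b2 <- colSums(delta)
          back <- delta %*% t(w2)
          back[fw$a1 <= 0] <- 0
          g_w1 <- crossprod(xb, back)
          g_b1 <- colSums(back)
          vel$w1 <- mom * vel$w1 - lr * g_w1
          vel$b1 <- mom * vel$b1 - lr * g_b1
          w1 <- w1 + vel$w1
          b1 <- b1 + vel$b1
        } else {
          g_w2 <- crossprod(xb, delta)
          g_b2 <- colSums(delta)
        }
        vel$w2 <- mom * vel$w2 - lr * g_w2
        vel$b2 <- mom * vel$b2 - lr * g_b2
        w2 <- w2 + vel$w2
        b2 <- b2 + vel$b2
        iters <- iters + 1L
        if (!is.null(config$max_iterations) &&
            iters >= config$max_iterations) break
      }
      tr <- eval_split(x_tr, y_tr)
      va <- eval_split(x_va, y_va)
      curves[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr[["loss"]], train_acc = tr[["acc"]],
        val_loss = va[["loss"]], val_acc = va[["acc"]]
      )
      n_epochs_run <- epoch
      if (va[["acc"]] > best$acc) {  # strict: earliest epoch wins ties
        best <- list(epoch = epoch, acc = va[["acc"]], w1 = w1, b1 = b1,
          w2 = w2, b2 = b2)
      }
      if (!is.null(config$max_iterations) &&
          iters >= config$max_iterations) break
    }
  })

  curves <- dplyr::bind_rows(curves[seq_len(n_epochs_run)])
  structure(
    list(
      w1 = best$w1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
      hidden_units = h, labels = labels, input_side = side,
      curves = curves, best_epoch = best$epoch, seed = config$seed,
      config = config,
      architecture = sprintf("mlp(%d-%s-%d)", d,
        if (h > 0) h else "linear", k)
    ),
    class = "tsidl_model"
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @export
print.tsidl_model <- function(x, ...) {
  cat(sprintf(
    "<tsidl_model> %s over %d classes | best epoch %d (val acc %.3f)\n",
    x$architecture, length(x$labels), x$best_epoch,
    x$curves$val_acc[x$best_epoch]))
  invisible(x)
}

#' Predict labels and class scores
#'
#' @param object A `tsidl_model`.
#' @param images List of grayscale image matrices (resized internally to
#'   the model's input side).
#' @param ... Unused.
#' @return Tibble with `.pred_label` (argmax) and one `.pred_<class>`
#'   score column per class; scores are softmax outputs summing to 1 per
#'   image. An empty image list yields a zero-row tibble.
#' @export
predict.tsidl_model <- function(object, images, ...) {
  x <- images_to_features(images, object$input_side) - 0.5
  k <- length(object$labels)
  if (nrow(x) == 0) {
    out <- tibble::tibble(.pred_label = character(0))
    for (l in object$labels) out[[paste0(".pred_", l)]] <- numeric(0)
    return(out)
  }
  if (object$hidden_units > 0) {
    a1 <- pmax(sweep(x %*% object$w1, 2, object$b1, `+`), 0)
    z <- sweep(a1 %*% object$w2, 2, object$b2, `+`)
  } else {
    z <- sweep(x %*% object$w2, 2, object$b2, `+`)
  }
  p <- softmax_rows(z)
  out <- tibble::tibble(
    .pred_label = object$labels[max.col(p, ties.method = "first")]
  )
  for (j in seq_len(k)) out[[paste0(".pred_", object$labels[j])]] <- p[, j]
  out
}

#' Tidy and summarise fitted models
#'
#' `tidy()` returns the per-epoch training/validation curves; `glance()` a
#' one-row summary with the best epoch and its validation accuracy.
#'
#' @param x A `tsidl_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tsidl_model <- function(x, ...) x$curves

#' @rdname tidy.tsidl_model
#' @export
glance.tsidl_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$labels),
    epochs_run = nrow(x$curves),
    best_epoch = x$best_epoch,
    best_val_acc = x$curves$val_acc[x$best_epoch],
    final_train_acc = x$curves$train_acc[nrow(x$curves)],
    seed = x$seed
  )
}

#' Training-curve plot
#'
#' @param object A `tsidl_model`.
#' @param ... Unused.
#' @return A ggplot object with accuracy and loss panels over epochs.
#' @export
autoplot.tsidl_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, -"epoch",
    names_to = c("split", "metric"), names_sep = "_",
    values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
      colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
      colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read a model checkpoint directory
#'
#' The checkpoint is a directory holding `weights.json` (parameter
#' arrays) and `meta.json` (architecture digest, ordered label set,
#' curves, best epoch, seed). The label order is part of the contract.
#'
#' @param model A `tsidl_model`.
#' @param dir Checkpoint directory (created if absent).
#' @return `read_model` returns a `tsidl_model`; `write_model` returns
#'   `dir` invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  weights <- list(w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2)
  jsonlite::write_json(weights, file.path(dir, "weights.json"),
    digits = NA, null = "null")
  meta <- list(
    architecture = model$architecture,
    hidden_units = model$hidden_units,
    labels = model$labels,
    input_side = model$input_side,
    best_epoch = model$best_epoch,
    seed = model$seed,
    curves = model$curves
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
    simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
    simplifyVector = TRUE)
  as_mat <- function(x) if (is.null(x) || length(x) == 0) NULL else as.matrix(x)
  structure(
    list(
      w1 = as_mat(w$w1), b1 = if (is.null(w$b1)) NULL else as.numeric(w$b1),
      w2 = as_mat(w$w2), b2 = as.numeric(w$b2),
      hidden_units = meta$hidden_units, labels = meta$labels,
      input_side = meta$input_side,
      curves = tibble::as_tibble(meta$curves),
      best_epoch = meta$best_epoch, seed = meta$seed,
      config = NULL, architecture = meta$architecture
    ),
    class = "tsidl_model"
  )
}
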