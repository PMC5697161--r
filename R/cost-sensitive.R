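#' Cost specification for imbalanced classification
#'
#' Misclassifying a minority (positive, severe) sample costs `c_min >= 1`;
#' misclassifying a majority sample costs 1; correct classification costs 0.
#'
#' @param minority_label Data label of the minority/positive class.
#' @param c_min Cost factor for misclassified minority samples (`>= 1`).
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(minority_label = 1L, c_min = 12) {
  if (c_min < 1) abort("`c_min` must be >= 1")
  structure(list(minority_label = minority_label, c_min = as.numeric(c_min)),
            class = "cost_spec")
}

#' Softmax classifier parameters
#'
#' Weight matrix `w` with one row per class and one column per input
#' feature (a bias can be absorbed as a constant feature), plus the weight
#' decay coefficient `lambda`. Columns listed in `decay_free_cols` (e.g. the
#' bias column) are excluded from the decay penalty.
#'
#' @param w Numeric matrix, `k` classes x `n` features.
#' @param lambda Weight-decay coefficient (`>= 0`).
#' @param decay_free_cols Integer column indices exempt from decay.
#' @return An object of class `softmax_params`.
#' @export
softmax_params <- function(w, lambda = 1e-4, decay_free_cols = integer()) {
  if (!is.matrix(w) || !all(is.finite(w))) {
    abort("`w` must be a finite numeric matrix")
  }
  if (lambda < 0) abort("`lambda` must be >= 0")
  structure(list(w = w, lambda = lambda,
                 decay_free_cols = as.integer(decay_free_cols)),
            class = "softmax_params")
}

#' Softmax class probabilities
#'
#' `p_j(x) = exp(w_j' x) / sum_s exp(w_s' x)`, computed with row-max
#' subtraction for overflow safety.
#'
#' @param params A [softmax_params()] object (or bare weight matrix).
#' @param x Feature vector of length `n`, or `m x n` matrix of rows.
#' @return An `m x k` matrix of probabilities (rows sum to 1); a vector
#'   when `x` is a vector.
#' @export
softmax_probs <- function(params, x) {
  w <- if (inherits(params, "softmax_params")) params$w else params
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) abort("`x` must be finite")
  logits <- x %*% t(w)                       # m x k
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  p <- e / rowSums(e)
  if (vec_in) drop(p) else p
}

# Per-sample cost factors: c_min for minority samples, 1 otherwise.
cost_factors <- function(y, cost) {
  ifelse(y == cost$minority_label, cost$c_min, 1)
}

# Map data labels to weight-matrix rows: row 1 = class 0, row 2 = class 1...
label_rows <- function(y, k) {
  rows <- as.integer(y) + 1L
  if (any(rows < 1L | rows > k)) abort("invalid class label in batch")
  rows
}

#' Cost-sensitive softmax cross-entropy
#'
#' The training objective
#' `J(w) = -(1/m) sum_i C_i log p_{y_i}(x_i) + (lambda/2) sum w^2`,
#' where `C_i = c_min` when sample `i` belongs to the minority class and 1
#' otherwise. With `c_min = 1` it reduces exactly to standard softmax
#' cross-entropy with weight decay.
#'
#' @param params A [softmax_params()].
#' @param x `m x n` matrix of feature rows.
#' @param y Length-`m` vector of 0-based class labels.
#' @param cost A [cost_spec()].
#' @return Scalar loss.
#' @export
cs_cross_entropy <- function(params, x, y, cost = cost_spec()) {
  w <- params$w
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) != length(y)) abort("batch sizes of `x` and `y` differ")
  k <- nrow(w)
  m <- nrow(x)
  rows <- label_rows(y, k)
  p <- softmax_probs(params, x)
  if (m == 1L) p <- matrix(p, nrow = 1)
  p_true <- p[cbind(seq_len(m), rows)]
  cf <- cost_factors(y, cost)
  decay_w <- w
  if (length(params$decay_free_cols)) decay_w[, params$decay_free_cols] <- 0
  -(1 / m) * sum(cf * log(p_true)) + params$lambda / 2 * sum(decay_w^2)
}

#' Analytic gradient of the cost-sensitive cross-entropy
#'
#' For every class row `j`:
#' `grad_j = -(1/m) sum_i C_i x_i (I(y_i = j) - p_j(x_i)) + lambda w_j`.
#'
#' @inheritParams cs_cross_entropy
#' @return Gradient matrix, same shape as `params$w`.
#' @export
cs_gradient <- function(params, x, y, cost = cost_spec()) {
  w <- params$w
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) != length(y)) abort("batch sizes of `x` and `y` differ")
  k <- nrow(w)
  m <- nrow(x)
  rows <- label_rows(y, k)
  p <- softmax_probs(params, x)
  if (m == 1L) p <- matrix(p, nrow = 1)
  ind <- matrix(0, m, k)
  ind[cbind(seq_len(m), rows)] <- 1
  cf <- cost_factors(y, cost)
  grad <- -(1 / m) * t(ind - p) %*% (x * cf)   # k x n
  decay <- params$lambda * w
  if (length(params$decay_free_cols)) decay[, params$decay_free_cols] <- 0
  grad + decay
}

#' Training configuration for mini-batch gradient descent
#'
#' Defaults follow the reference setup: mini-batches of 64 samples, initial
#' learning rate 0.001 reduced to one tenth every 500 iterations, 2000
#' iterations in total, evaluation logged every 50 iterations.
#'
#' @param batch_size Mini-batch size `m`.
#' @param lr0 Initial learning rate.
#' @param max_iter Total number of iterations (mini-batch updates).
#' @param decay_step Iterations between learning-rate reductions.
#' @param decay_factor Multiplicative learning-rate factor, in `(0, 1]`.
#' @param eval_interval Iterations between logged evaluations.
#' @param lambda Weight-decay coefficient.
#' @param seed RNG seed for batch shuffling and initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, lr0 = 0.001, max_iter = 2000,
                         decay_step = 500, decay_factor = 0.1,
                         eval_interval = 50, lambda = 1e-4, seed = 1L) {
  if (batch_size < 1 || lr0 <= 0 || max_iter < 1 || decay_step < 1) {
    abort("batch_size, lr0, max_iter and decay_step must be positive")
  }
  if (decay_factor <= 0 || decay_factor > 1) {
    abort("`decay_factor` must lie in (0, 1]")
  }
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 max_iter = as.integer(max_iter),
                 decay_step = as.integer(decay_step),
                 decay_factor = decay_factor,
                 eval_interval = as.integer(eval_interval),
                 lambda = lambda, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at iteration t
#'
#' `lr(t) = lr0 * decay_factor ^ floor(t / decay_step)` — a step schedule
#' that reduces the rate to one tenth every `decay_step` iterations under
#' the defaults.
#'
#' @param t Iteration number (0-based), vectorized.
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
learning_rate <- function(t, config = train_config()) {
  config$lr0 * config$decay_factor^floor(t / config$decay_step)
}

#' Train a cost-sensitive softmax classifier by mini-batch gradient descent
#'
#' Fits the weights minimizing the cost-sensitive cross-entropy on tabular
#' features. Batches are drawn by epoch-wise seeded shuffling without
#' replacement; the learning rate follows [learning_rate()]. A bias is
#' absorbed as a constant feature and excluded from weight decay. When test
#' data are supplied, test loss and accuracy are logged every
#' `eval_interval` iterations.
#'
#' @param data Data frame with feature columns and a `label` column (0/1
#'   or 0-based classes, minority = positive = 1 by convention).
#' @param cost A [cost_spec()].
#' @param config A [train_config()].
#' @param test_data Optional held-out data frame of the same shape.
#' @param label_col Name of the label column.
#' @return An object of class `cs_fit` with elements `params`
#'   ([softmax_params()]), `log` (tibble: iteration, lr, train_loss,
#'   test_loss, test_accuracy), `cost`, `config`, `feature_names`.
#' @export
train_cs_softmax <- function(data, cost = cost_spec(),
                             config = train_config(), test_data = NULL,
                             label_col = "label") {
  xy <- split_features(data, label_col)
  y <- xy$y
  if (length(unique(y)) < 2L) abort("training data contain a single class")
  x <- cbind(xy$x, bias = 1)
  k <- length(unique(c(y, 0L, 1L)))
  k <- max(k, max(y) + 1L)
  n <- ncol(x)
  bias_col <- n

  x_test <- NULL
  y_test <- NULL
  if (!is.null(test_data)) {
    xyt <- split_features(test_data, label_col)
    x_test <- cbind(xyt$x, bias = 1)
    y_test <- xyt$y
  }

  with_seed(config$seed, {
    w <- matrix(stats::rnorm(k * n, sd = 0.01), k, n)
    params <- softmax_params(w, lambda = config$lambda,
                             decay_free_cols = bias_col)
    m <- nrow(x)
    order_idx <- integer(0)
    log_rows <- list()
    for (t in seq_len(config$max_iter) - 1L) {
      if (length(order_idx) < config$batch_size) {
        order_idx <- c(order_idx, sample.int(m))
      }
      take <- seq_len(min(config$batch_size, length(order_idx)))
      batch <- order_idx[take]
      order_idx <- order_idx[-take]
      lr <- learning_rate(t, config)
      g <- cs_gradient(params, x[batch, , drop = FALSE], y[batch], cost)
      params$w <- params$w - lr * g
      if ((t + 1L) %% config$eval_interval == 0L ||
          (t + 1L) == config$max_iter) {
        train_loss <- cs_cross_entropy(params, x[batch, , drop = FALSE],
                                       y[batch], cost)
        test_loss <- NA_real_
        test_acc <- NA_real_
        if (!is.null(x_test)) {
          test_loss <- cs_cross_entropy(params, x_test, y_test, cost)
          pred <- max.col(softmax_probs(params, x_test)) - 1L
          test_acc <- mean(pred == y_test)
        }
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          iteration = t + 1L, lr = lr, train_loss = train_loss,
          test_loss = test_loss, test_accuracy = test_acc
        )
      }
    }
    structure(
      list(params = params, log = dplyr::bind_rows(log_rows), cost = cost,
           config = config, feature_names = colnames(xy$x)),
      class = "cs_fit"
    )
  })
}

split_features <- function(data, label_col = "label") {
  if (!label_col %in% names(data)) {
    abort(sprintf("no `%s` column in data", label_col))
  }
  y <- as.integer(data[[label_col]])
  x <- as.matrix(data[setdiff(names(data), label_col)])
  storage.mode(x) <- "double"
  list(x = x, y = y)
}

#' Predict from a fitted cost-sensitive softmax classifier
#'
#' @param object A `cs_fit` from [train_cs_softmax()].
#' @param newdata Data frame of features (a `label` column, if present, is
#'   ignored).
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param ... Unused.
#' @return A tibble of per-class probabilities, or an integer label vector.
#' @export
predict.cs_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  feats <- intersect(object$feature_names, names(newdata))
  if (length(feats) != length(object$feature_names)) {
    abort("`newdata` is missing training feature columns")
  }
  x <- cbind(as.matrix(newdata[object$feature_names]), bias = 1)
  p <- softmax_probs(object$params, x)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (type == "class") {
    return(max.col(p) - 1L)
  }
  colnames(p) <- paste0("p", seq_len(ncol(p)) - 1L)
  tibble::as_tibble(p)
}

#' Threshold-moving prediction
#'
#' Cost-sensitive inference without retraining: class posteriors are
#' multiplied by per-class weights before the argmax, shifting the decision
#' threshold toward low-cost classes so that high-cost (minority) classes
#' are harder to misclassify. Ties break toward the minority class.
#'
#' @param probs `m x k` matrix (or tibble) of class probabilities, columns
#'   in class order 0, 1, ...
#' @param class_weights Positive per-class multipliers, length `k`.
#' @param minority_label Label (0-based) that wins ties.
#' @return Integer vector of 0-based predicted labels.
#' @export
threshold_moving_predict <- function(probs, class_weights,
                                     minority_label = 1L) {
  probs <- as.matrix(probs)
  if (length(class_weights) != ncol(probs)) {
    abort("`class_weights` length must equal the number of classes")
  }
  if (any(class_weights <= 0)) abort("`class_weights` must be positive")
  scaled <- sweep(probs, 2, class_weights, `*`)
  apply(scaled, 1, function(row) {
    top <- which(row == max(row)) - 1L
    if (length(top) > 1L && (minority_label %in% top)) {
      minority_label
    } else {
      top[1]
    }
  })
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf(
    "Cost-sensitive softmax fit: %d classes, %d features, c_min = %g\n",
    nrow(x$params$w), ncol(x$params$w) - 1L, x$cost$c_min))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final train loss %.4f", last$train_loss))
    if (!is.na(last$test_accuracy)) {
      cat(sprintf(", test accuracy %.3f", last$test_accuracy))
    }
    cat("\n")
  }
  invisible(x)
}
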