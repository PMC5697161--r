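#' Stratified k-fold split
#'
#' Partitions sample indices into `k` folds so that positive samples are
#' divided equally (counts per fold differ by at most one per class).
#' Deterministic under `seed`.
#'
#' @param labels 0/1 label vector; each class needs at least `k` samples.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble with columns `index`, `label`, `fold`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  classes <- unique(labels)
  for (cl in classes) {
    if (sum(labels == cl) < k) {
      abort(sprintf("class %s has fewer than k = %d samples", cl, k))
    }
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))   # round-robin deal
    }
    tibble::tibble(index = seq_along(labels), label = labels, fold = fold)
  })
}

#' Grid search over the cost factor
#'
#' Trains one cost-sensitive classifier per cost-factor value on a fixed
#' stratified four-fifths / one-fifth split, and records the held-out
#' accuracy and false negative rate at each grid point. The selected cost
#' factor is the smallest value inside the widest contiguous region where
#' accuracy stays at or above `acc_floor` and FNR at or below
#' `fnr_ceiling` (the reference lines drawn at 0.9 and 0.14); when no grid
#' point qualifies, the value maximizing the G-mean is returned instead.
#'
#' @param data Data frame of features plus `label` (1 = minority).
#' @param c_grid Cost-factor grid (values `>= 1`); default 1..50, step 1.
#' @param config A [train_config()] shared by all grid points.
#' @param acc_floor,fnr_ceiling Stability thresholds.
#' @param seed Seed for the train/test split.
#' @param train_fn Training function
#'   `(train_data, cost, config, test_data) -> fit` with a
#'   `predict(fit, newdata, type = "class")` method; defaults to
#'   [train_cs_softmax()].
#' @return An object of class `grid_search_result`: a list with `curve`
#'   (tibble `c_min`, `accuracy`, `fnr`, `sensitivity`, `specificity`,
#'   `g_mean`), `selected_c`, `acc_floor`, `fnr_ceiling`.
#' @export
grid_search_cost <- function(data, c_grid = 1:50,
                             config = train_config(max_iter = 200),
                             acc_floor = 0.9, fnr_ceiling = 0.14,
                             seed = 1L, train_fn = NULL) {
  if (length(c_grid) == 0L) abort("`c_grid` must be non-empty")
  if (any(c_grid < 1)) abort("cost factors must be >= 1")
  train_fn <- train_fn %||% function(train_data, cost, config, test_data) {
    train_cs_softmax(train_data, cost = cost, config = config,
                     test_data = test_data)
  }
  split <- stratified_kfold(data$label, k = 5L, seed = seed)
  test_idx <- split$index[split$fold == 1L]
  train_data <- data[-test_idx, ]
  test_data <- data[test_idx, ]

  rows <- purrr::map_dfr(c_grid, function(cm) {
    fit <- train_fn(train_data, cost_spec(c_min = cm), config, test_data)
    pred <- stats::predict(fit, test_data, type = "class")
    rep <- metric_report(test_data$label, pred)
    tibble::tibble(c_min = cm, accuracy = rep$accuracy, fnr = rep$fnr,
                   sensitivity = rep$sensitivity,
                   specificity = rep$specificity, g_mean = rep$g_mean)
  })

  ok <- !is.na(rows$accuracy) & !is.na(rows$fnr) &
    rows$accuracy >= acc_floor & rows$fnr <= fnr_ceiling
  selected <- if (any(ok)) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    rows$c_min[starts[best]]
  } else {
    rows$c_min[which.max(rows$g_mean)]
  }
  structure(list(curve = rows, selected_c = selected,
                 acc_floor = acc_floor, fnr_ceiling = fnr_ceiling),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "Cost-factor grid search over %d values; selected c_min = %g\n",
    nrow(x$curve), x$selected_c))
  invisible(x)
}

# Built-in method constructors for run_comparison(). Each spec is a list
# with `fit(train_data, seed)` and `predict(fit, newdata)` returning
# positive-class scores.
comparison_method <- function(spec) {
  if (is.list(spec) && !is.null(spec$fit) && !is.null(spec$predict)) {
    return(spec)
  }
  abort("each method must be a list with `fit` and `predict` functions")
}

#' Built-in comparison method specifications
#'
#' Constructs method specs for [run_comparison()]: a cost-sensitive (or
#' cost-free, `c_min = 1`) softmax classifier, optionally preceded by a
#' data-level resampler, or a random-forest baseline.
#'
#' @param name Label for the report row.
#' @param c_min Cost factor (1 = cost-free).
#' @param resample `NULL`, `"smote"`, `"bsmote"` or `"under"` applied to
#'   the training fold only.
#' @param classifier `"softmax"` or `"rf"`.
#' @param config A [train_config()] for the softmax trainer.
#' @return A method spec list for [run_comparison()].
#' @export
method_spec <- function(name, c_min = 1, resample = NULL,
                        classifier = c("softmax", "rf"),
                        config = train_config(max_iter = 200)) {
  classifier <- match.arg(classifier)
  list(
    name = name,
    fit = function(train_data, seed) {
      if (!is.null(resample)) {
        cfg <- resample_config(seed = seed)
        train_data <- rebalance(train_data, method = resample, cfg = cfg)
        train_data$synthetic <- NULL
      }
      if (classifier == "rf") {
        fit_baseline(train_data, classifier = "rf")
      } else {
        cfg <- config
        cfg$seed <- seed
        train_cs_softmax(train_data, cost = cost_spec(c_min = c_min),
                         config = cfg)
      }
    },
    predict = function(fit, newdata) {
      p <- stats::predict(fit, newdata, type = "prob")
      p[[ncol(p)]]
    }
  )
}

#' Compare methods under shared stratified cross-validation
#'
#' Runs each method on identical fold splits (paired comparison), scores
#' every fold with the full metric report, and aggregates fold means and
#' standard deviations per method.
#'
#' @param methods Named list of method specs (see [method_spec()]).
#' @param data Data frame of features plus `label`.
#' @param k Number of folds.
#' @param seed Seed controlling the folds and per-fold method seeds.
#' @return An object of class `comparison_result`: list with `summary`
#'   (tibble: method x aggregated metrics), `per_fold` (tibble of raw fold
#'   reports), `folds` (the fold tibble), `curves` (per-method pooled ROC
#'   and PR tibbles).
#' @export
run_comparison <- function(methods, data, k = 5L, seed = 1L) {
  if (length(methods) == 0L) abort("need at least one method")
  if (is.null(names(methods)) || any(names(methods) == "")) {
    names(methods) <- purrr::map_chr(methods, function(m) {
      m$name %||% "method"
    })
  }
  folds <- stratified_kfold(data$label, k = k, seed = seed)
  per_fold <- list()
  curves <- list()
  for (mn in names(methods)) {
    m <- comparison_method(methods[[mn]])
    scores_all <- rep(NA_real_, nrow(data))
    for (f in seq_len(k)) {
      test_idx <- folds$index[folds$fold == f]
      fit <- tryCatch(
        m$fit(data[-test_idx, ], seed = child_seed(seed, f)),
        error = function(e) {
          abort(sprintf("method `%s` failed on fold %d: %s", mn, f,
                        conditionMessage(e)))
        }
      )
      scores <- m$predict(fit, data[test_idx, ])
      scores_all[test_idx] <- scores
      rep <- metric_report(data$label[test_idx],
                           as.integer(scores >= 0.5), scores)
      rep$method <- mn
      rep$fold <- f
      per_fold[[length(per_fold) + 1L]] <- rep
    }
    rp <- roc_pr_auc(scores_all, data$label)
    curves[[mn]] <- list(roc = rp$roc, pr = rp$pr,
                         pooled_auc = rp$auc_roc)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- per_fold |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(df, key) {
      agg <- aggregate_folds(df[setdiff(names(df), "fold")])
      tidyr::pivot_wider(agg, names_from = "metric",
                         values_from = c("mean", "sd"),
                         names_glue = "{metric}_{.value}")
    }) |>
    dplyr::ungroup()
  structure(list(summary = summary, per_fold = per_fold, folds = folds,
                 curves = curves),
            class = "comparison_result")
}

#' Extract the convergence curve from a training log
#'
#' @param fit A `cs_fit` or `cs_net_fit` (or a bare log tibble with an
#'   `iteration` column).
#' @return Tibble of logged evaluation points (loss and accuracy vs
#'   iteration).
#' @export
log_convergence <- function(fit) {
  log <- if (is.data.frame(fit)) fit else fit$log
  if (is.null(log) || nrow(log) == 0L) abort("empty training log")
  stopifnot(all(diff(log$iteration) > 0))
  tibble::as_tibble(log)
}
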