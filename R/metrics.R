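#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length vectors of 0/1 labels (1 = positive).
#' @return A tibble with one row: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length")
  }
  if (length(y_true) == 0L) abort("empty label vectors")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort("labels must be 0 or 1")
  }
  tibble::tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fn = sum(y_true == 1 & y_pred == 0)
  )
}

# 0/0 ratios are undefined and reported as NA, never silently 0: a zero
# would corrupt fold means.
safe_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Basic classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, plus the false negative
#' rate `1 - sensitivity`. Ratios with zero denominators are `NA`.
#'
#' @param cc One-row tibble (or list) with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `fnr`.
#' @export
basic_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  sens <- safe_ratio(tp, tp + fn)
  tibble::tibble(
    accuracy = safe_ratio(tp + tn, tp + fn + tn + fp),
    sensitivity = sens,
    specificity = safe_ratio(tn, tn + fp),
    precision = safe_ratio(tp, tp + fp),
    fnr = 1 - sens
  )
}

#' F1-measure and G-mean
#'
#' `F1 = 2 * recall * precision / (recall + precision)`;
#' `G-mean = sqrt(sensitivity * specificity)`. Both are low whenever the
#' classifier neglects either class, which makes them informative under
#' class imbalance. Undefined (`NA`) inputs propagate.
#'
#' @param report One-row tibble from [basic_metrics()].
#' @return A one-row tibble: `f1_measure`, `g_mean`.
#' @export
f1_and_gmean <- function(report) {
  p <- report$precision
  s <- report$sensitivity
  sp <- report$specificity
  f1 <- if (is.na(p) || is.na(s)) {
    NA_real_
  } else if (p + s == 0) {
    NA_real_
  } else {
    2 * s * p / (s + p)
  }
  g <- if (is.na(s) || is.na(sp)) NA_real_ else sqrt(s * sp)
  tibble::tibble(f1_measure = f1, g_mean = g)
}

#' Full metric report for binary predictions
#'
#' Convenience wrapper combining [confusion()], [basic_metrics()],
#' [f1_and_gmean()] and, when positive-class scores are supplied,
#' trapezoidal ROC AUC.
#'
#' @param y_true,y_pred 0/1 label vectors.
#' @param scores Optional positive-class scores for AUC.
#' @return A one-row tibble of metrics.
#' @export
metric_report <- function(y_true, y_pred, scores = NULL) {
  cc <- confusion(y_true, y_pred)
  rep <- basic_metrics(cc)
  rep <- dplyr::bind_cols(rep, f1_and_gmean(rep))
  if (!is.null(scores) && length(unique(y_true)) == 2L) {
    rep$auc_roc <- roc_pr_auc(scores, y_true)$auc_roc
  } else {
    rep$auc_roc <- NA_real_
  }
  dplyr::bind_cols(cc, rep)
}

#' ROC and PR curves with trapezoidal ROC AUC
#'
#' Sweeps the decision threshold over the unique score values (predicting
#' positive when `score >= threshold`), yielding the ROC curve (false
#' positive rate vs true positive rate) and PR curve (recall vs precision).
#' AUC is the trapezoidal area under the ROC curve; tied scores enter a
#' single operating point, so ties contribute 1/2, matching the
#' Mann-Whitney pair statistic.
#'
#' @param scores Positive-class scores.
#' @param y_true 0/1 labels; both classes must be present.
#' @return A list: `roc` (tibble `threshold`, `fpr`, `tpr`), `pr`
#'   (tibble `threshold`, `recall`, `precision`), `auc_roc`.
#' @export
roc_pr_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) {
    abort("`scores` and `y_true` must have equal length")
  }
  if (length(unique(y_true)) < 2L) {
    abort("both classes must be present to compute ROC")
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thresholds, function(t) {
    pred <- as.integer(scores >= t)
    tibble::tibble(
      threshold = t,
      tp = sum(pred == 1 & y_true == 1),
      fp = sum(pred == 1 & y_true == 0)
    )
  })
  roc <- tibble::tibble(
    threshold = c(Inf, pts$threshold),
    fpr = c(0, pts$fp / n_neg),
    tpr = c(0, pts$tp / n_pos)
  )
  pr <- tibble::tibble(
    threshold = pts$threshold,
    recall = pts$tp / n_pos,
    precision = ifelse(pts$tp + pts$fp == 0, NA_real_,
                       pts$tp / (pts$tp + pts$fp))
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, pr = pr, auc_roc = auc)
}

#' Aggregate per-fold metric reports
#'
#' Mean and sample (n-1) standard deviation of each numeric metric across
#' cross-validation folds, the form in which fold-wise results are usually
#' reported. `NA` (undefined) fold values are dropped per metric.
#'
#' @param reports A tibble with one row per fold (e.g. stacked
#'   [metric_report()] rows), or a list of such rows.
#' @return A tibble with columns `metric`, `mean`, `sd`, `n_folds`.
#' @export
aggregate_folds <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- dplyr::bind_rows(reports)
  }
  if (nrow(reports) < 2L) abort("need at least 2 folds to aggregate")
  num <- reports[vapply(reports, is.numeric, logical(1))]
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_folds = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Format an aggregated report as percentage strings
#'
#' Renders `mean (sd)` pairs as percentages with two decimals, the common
#' presentation for fold-aggregated results (columns ACC, SPC, SEN, F1_M,
#' G_M, AUC).
#'
#' @param agg Output of [aggregate_folds()].
#' @return A tibble with `metric` and `formatted` columns.
#' @export
format_percent_report <- function(agg) {
  order_pref <- c("accuracy", "specificity", "sensitivity", "f1_measure",
                  "g_mean", "auc_roc")
  agg <- agg[agg$metric %in% order_pref, ]
  agg <- agg[order(match(agg$metric, order_pref)), ]
  tibble::tibble(
    metric = agg$metric,
    formatted = sprintf("%.2f (%.2f)", 100 * agg$mean, 100 * agg$sd)
  )
}
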