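#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   labs theme_minimal
NULL

#' Plot accuracy and FNR curves from a cost-factor grid search
#'
#' Mirrors the usual presentation: accuracy and FNR against the cost
#' factor, with dashed reference lines at the stability thresholds and a
#' vertical mark at the selected cost factor.
#'
#' @param object A `grid_search_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_search_result <- function(object, ...) {
  curve <- tidyr::pivot_longer(
    object$curve[c("c_min", "accuracy", "fnr")],
    c("accuracy", "fnr"), names_to = "series", values_to = "value"
  )
  ggplot(curve, aes(x = .data$c_min, y = .data$value,
                    colour = .data$series)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_hline(yintercept = object$acc_floor, linetype = "dashed") +
    geom_hline(yintercept = object$fnr_ceiling, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$selected_c,
                        linetype = "dotted") +
    labs(x = "cost factor", y = NULL, colour = NULL,
         title = "Accuracy and FNR vs cost factor") +
    theme_minimal()
}

#' Plot the convergence log of a fitted classifier
#'
#' Test loss and test accuracy against iteration, as logged every
#' `eval_interval` iterations during training.
#'
#' @param object A `cs_fit` or `cs_net_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cs_fit <- function(object, ...) {
  log <- log_convergence(object)
  cols <- intersect(c("train_loss", "test_loss", "test_accuracy"),
                    names(log))
  long <- tidyr::pivot_longer(log[c("iteration", cols)], -"iteration",
                              names_to = "series", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot(long, aes(x = .data$iteration, y = .data$value,
                   colour = .data$series)) +
    geom_line() +
    labs(x = "iteration", y = NULL, colour = NULL,
         title = "Training convergence") +
    theme_minimal()
}

#' @rdname autoplot.cs_fit
#' @export
autoplot.cs_net_fit <- autoplot.cs_fit

#' Plot pooled ROC curves from a method comparison
#'
#' @param object A `comparison_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_result <- function(object, ...) {
  roc <- purrr::imap_dfr(object$curves, function(cv, nm) {
    dplyr::mutate(cv$roc, method = nm)
  })
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr, colour = .data$method)) +
    geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = "Pooled ROC curves", colour = NULL) +
    theme_minimal()
}
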