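#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cost-sensitive softmax fit
#'
#' One row per (class, feature) weight.
#'
#' @param x A `cs_fit`.
#' @param ... Unused.
#' @return A tibble with `class`, `term`, `estimate`.
#' @export
tidy.cs_fit <- function(x, ...) {
  w <- x$params$w
  terms <- c(x$feature_names, "(bias)")
  tibble::tibble(
    class = rep(seq_len(nrow(w)) - 1L, times = ncol(w)),
    term = rep(terms, each = nrow(w)),
    estimate = as.numeric(w)
  )
}

#' Glance at a cost-sensitive softmax fit
#'
#' @param x A `cs_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `c_min`, `lambda`, `iterations`,
#'   `final_train_loss`, `final_test_loss`, `final_test_accuracy`.
#' @export
glance.cs_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    c_min = x$cost$c_min,
    lambda = x$params$lambda,
    iterations = x$config$max_iter,
    final_train_loss = last$train_loss,
    final_test_loss = last$test_loss,
    final_test_accuracy = last$test_accuracy
  )
}

#' Tidy a cost-factor grid search
#'
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @return The per-cost-factor curve tibble.
#' @export
tidy.grid_search_result <- function(x, ...) x$curve

#' @rdname tidy.grid_search_result
#' @export
glance.grid_search_result <- function(x, ...) {
  tibble::tibble(selected_c = x$selected_c, n_grid = nrow(x$curve),
                 acc_floor = x$acc_floor, fnr_ceiling = x$fnr_ceiling)
}

#' Tidy a method comparison
#'
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @return The per-fold metric tibble (`tidy`) or the aggregated summary
#'   (`glance`).
#' @export
tidy.comparison_result <- function(x, ...) x$per_fold

#' @rdname tidy.comparison_result
#' @export
glance.comparison_result <- function(x, ...) x$summary
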