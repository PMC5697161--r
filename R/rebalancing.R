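#' Resampling configuration
#'
#' @param k_neighbors Number of nearest neighbours used by the
#'   over-samplers (default 5).
#' @param r Target minority:majority ratio after resampling (default 1,
#'   i.e. balanced classes).
#' @param seed Integer seed.
#' @return An object of class `resample_config`.
#' @export
resample_config <- function(k_neighbors = 5L, r = 1, seed = 1L) {
  if (k_neighbors < 1L) abort("`k_neighbors` must be >= 1")
  if (r <= 0) abort("`r` must be positive")
  structure(list(k_neighbors = as.integer(k_neighbors), r = r,
                 seed = as.integer(seed)),
            class = "resample_config")
}

# Pairwise nearest neighbours on standardized features (Euclidean metric).
# Returns an n_query x k matrix of indices into `ref`.
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[sdv == 0] <- 1
  qs <- sweep(sweep(query, 2, mu), 2, sdv, `/`)
  rs <- sweep(sweep(ref, 2, mu), 2, sdv, `/`)
  d2 <- outer(rowSums(qs^2), rep(1, nrow(rs))) +
    outer(rep(1, nrow(qs)), rowSums(rs^2)) - 2 * qs %*% t(rs)
  t(vapply(seq_len(nrow(qs)), function(i) {
    o <- order(d2[i, ])
    if (exclude_self) o <- o[o != i]
    o[seq_len(k)]
  }, integer(k)))
}

smote_interpolate <- function(x_min, seeds_idx, nn, n_syn) {
  n_seed <- length(seeds_idx)
  syn <- matrix(0, n_syn, ncol(x_min))
  pick_seed <- rep_len(seq_len(n_seed), n_syn)
  for (s in seq_len(n_syn)) {
    i <- seeds_idx[pick_seed[s]]
    j <- nn[pick_seed[s], sample.int(ncol(nn), 1)]
    u <- stats::runif(1)
    syn[s, ] <- x_min[i, ] + u * (x_min[j, ] - x_min[i, ])
  }
  syn
}

target_synthetic_count <- function(n_min, n_maj, r) {
  max(0L, as.integer(round(r * n_maj)) - n_min)
}

#' SMOTE minority over-sampling
#'
#' Synthetic minority samples are interpolations `x + u (x_nn - x)` with
#' `u ~ Uniform(0, 1)` between a minority point and one of its
#' `k_neighbors` nearest minority neighbours (Euclidean metric on
#' standardized features), generated until the minority:majority ratio
#' reaches `cfg$r`.
#'
#' @param x_minority,x_majority Numeric feature matrices (rows = samples).
#' @param cfg A [resample_config()].
#' @return The augmented minority matrix (originals first); attribute
#'   `n_synthetic` gives the number of appended rows.
#' @export
smote <- function(x_minority, x_majority, cfg = resample_config()) {
  x_minority <- as.matrix(x_minority)
  x_majority <- as.matrix(x_majority)
  if (nrow(x_minority) <= cfg$k_neighbors) {
    abort(sprintf(
      "SMOTE needs more than k_neighbors = %d minority samples, got %d",
      cfg$k_neighbors, nrow(x_minority)))
  }
  n_syn <- target_synthetic_count(nrow(x_minority), nrow(x_majority), cfg$r)
  if (n_syn == 0L) {
    out <- x_minority
    attr(out, "n_synthetic") <- 0L
    return(out)
  }
  with_seed(cfg$seed, {
    nn <- knn_indices(x_minority, x_minority, cfg$k_neighbors,
                      exclude_self = TRUE)
    syn <- smote_interpolate(x_minority, seq_len(nrow(x_minority)), nn,
                             n_syn)
    out <- rbind(x_minority, syn)
    attr(out, "n_synthetic") <- n_syn
    out
  })
}

#' Borderline-SMOTE minority over-sampling
#'
#' Only "danger" minority points seed synthesis: points for which more than
#' half, but not all, of their `k_neighbors` nearest neighbours in the
#' combined dataset belong to the majority class. Points whose neighbours
#' are all majority are treated as noise and generate nothing.
#' Interpolation partners are drawn from the minority nearest neighbours of
#' each danger point (borderline variant 1). When no danger points exist, a
#' warning is issued and plain [smote()] is used.
#'
#' @inheritParams smote
#' @return As [smote()]; attribute `danger_idx` lists the seeding rows.
#' @export
borderline_smote <- function(x_minority, x_majority,
                             cfg = resample_config()) {
  x_minority <- as.matrix(x_minority)
  x_majority <- as.matrix(x_majority)
  if (nrow(x_minority) <= cfg$k_neighbors) {
    abort(sprintf(
      "borderline-SMOTE needs more than k_neighbors = %d minority samples",
      cfg$k_neighbors))
  }
  k <- cfg$k_neighbors
  combined <- rbind(x_minority, x_majority)
  is_majority <- c(rep(FALSE, nrow(x_minority)), rep(TRUE, nrow(x_majority)))
  nn_all <- knn_indices(x_minority, combined, k + 1L)
  # Drop each point itself (its nearest neighbour in the combined set).
  maj_count <- vapply(seq_len(nrow(x_minority)), function(i) {
    nbrs <- setdiff(nn_all[i, ], i)[seq_len(k)]
    sum(is_majority[nbrs])
  }, integer(1))
  danger <- which(maj_count > k / 2 & maj_count < k)
  if (length(danger) == 0L) {
    warning("no danger points found; falling back to plain SMOTE",
            call. = FALSE)
    return(smote(x_minority, x_majority, cfg))
  }
  n_syn <- target_synthetic_count(nrow(x_minority), nrow(x_majority), cfg$r)
  if (n_syn == 0L) {
    out <- x_minority
    attr(out, "n_synthetic") <- 0L
    attr(out, "danger_idx") <- danger
    return(out)
  }
  with_seed(cfg$seed, {
    k_min <- min(k, nrow(x_minority) - 1L)
    nn_min <- knn_indices(x_minority[danger, , drop = FALSE], x_minority,
                          k_min + 1L)
    nn_min <- t(vapply(seq_along(danger), function(i) {
      setdiff(nn_min[i, ], danger[i])[seq_len(k_min)]
    }, integer(k_min)))
    syn <- smote_interpolate(x_minority, danger, nn_min, n_syn)
    out <- rbind(x_minority, syn)
    attr(out, "n_synthetic") <- n_syn
    attr(out, "danger_idx") <- danger
    out
  })
}

#' Random under-sampling of the majority class
#'
#' Uniform subsample of the majority class without replacement down to
#' `round(n_minority / r)` rows; the minority class is untouched.
#'
#' @inheritParams smote
#' @return The reduced majority matrix; attribute `kept_idx` gives the
#'   retained row indices.
#' @export
under_sample <- function(x_minority, x_majority, cfg = resample_config()) {
  x_minority <- as.matrix(x_minority)
  x_majority <- as.matrix(x_majority)
  target <- as.integer(round(nrow(x_minority) / cfg$r))
  if (nrow(x_majority) < target) {
    abort("not enough majority samples to reach the requested ratio")
  }
  if (nrow(x_majority) == target) {
    out <- x_majority
    attr(out, "kept_idx") <- seq_len(nrow(x_majority))
    return(out)
  }
  with_seed(cfg$seed, {
    keep <- sort(sample.int(nrow(x_majority), target))
    out <- x_majority[keep, , drop = FALSE]
    attr(out, "kept_idx") <- keep
    out
  })
}

#' Rebalance a labelled feature tibble
#'
#' Tidy wrapper over [smote()], [borderline_smote()] and [under_sample()]:
#' takes a data frame with feature columns and a 0/1 `label` column
#' (1 = minority) and returns the rebalanced data.
#'
#' @param data Data frame of features plus `label`.
#' @param method `"smote"`, `"bsmote"` or `"under"`.
#' @param cfg A [resample_config()].
#' @param label_col Name of the label column.
#' @return A tibble with the same columns plus `synthetic` (logical).
#' @export
rebalance <- function(data, method = c("smote", "bsmote", "under"),
                      cfg = resample_config(), label_col = "label") {
  method <- match.arg(method)
  xy <- split_features(data, label_col)
  x_min <- xy$x[xy$y == 1L, , drop = FALSE]
  x_maj <- xy$x[xy$y == 0L, , drop = FALSE]
  if (method == "under") {
    maj <- under_sample(x_min, x_maj, cfg)
    feats <- rbind(x_min, maj)
    labels <- rep(c(1L, 0L), c(nrow(x_min), nrow(maj)))
    synthetic <- rep(FALSE, nrow(feats))
  } else {
    minority <- if (method == "smote") {
      smote(x_min, x_maj, cfg)
    } else {
      borderline_smote(x_min, x_maj, cfg)
    }
    feats <- rbind(minority, x_maj)
    labels <- rep(c(1L, 0L), c(nrow(minority), nrow(x_maj)))
    synthetic <- c(rep(FALSE, nrow(x_min)),
                   rep(TRUE, attr(minority, "n_synthetic")),
                   rep(FALSE, nrow(x_maj)))
  }
  out <- tibble::as_tibble(as.data.frame(feats))
  out[[label_col]] <- labels
  out$synthetic <- synthetic
  out
}
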