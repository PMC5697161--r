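# Shared in-code fixtures: tiny deterministic images and datasets.

# Rasterize an ideal circle outline into a logical matrix (1-px ring).
raster_circle <- function(size, cx, cy, r) {
  m <- matrix(FALSE, size, size)
  n_theta <- ceiling(2 * pi * r) * 2
  th <- 2 * pi * seq_len(n_theta) / n_theta
  xs <- pmin(pmax(round(cx + r * cos(th)), 1), size)
  ys <- pmin(pmax(round(cy + r * sin(th)), 1), size)
  m[cbind(ys, xs)] <- TRUE
  m
}

# A sharp bright disc on a dark background (no noise).
disc_image <- function(size, cx, cy, r, fg = 0.9, bg = 0.1) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  img <- matrix(bg, size, size)
  img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- fg
  img
}

# Independent brute-force Hough accumulator (oracle): counts edge pixels
# whose distance to (cx, cy) rounds to r.
brute_hough_score <- function(edge_map, cx, cy, r) {
  idx <- which(edge_map != 0, arr.ind = TRUE)
  d <- sqrt((idx[, 2] - cx)^2 + (idx[, 1] - cy)^2)
  sum(abs(d - r) <= 0.5)
}

# Independent Mann-Whitney AUC oracle: pairs with tied scores count 1/2.
pair_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Central-difference gradient of the cost-sensitive loss (oracle).
numeric_cs_gradient <- function(params, x, y, cost, h = 1e-5) {
  g <- params$w * 0
  for (i in seq_along(params$w)) {
    wp <- params; wp$w[i] <- wp$w[i] + h
    wm <- params; wm$w[i] <- wm$w[i] - h
    g[i] <- (cs_cross_entropy(wp, x, y, cost) -
               cs_cross_entropy(wm, x, y, cost)) / (2 * h)
  }
  g
}

# The Gaussian-probe study conditions used across experiment tests: class
# sizes mirror one CV training share of the 735/1970 imbalance.
probe_train <- function(seed) {
  generate_feature_dataset(147, 394, dim = 2, class_separation = 2,
                           seed = seed)
}
probe_test <- function(seed) {
  generate_feature_dataset(147, 394, dim = 2, class_separation = 2,
                           seed = seed + 1000L)
}
probe_config <- function(seed, max_iter = 2000) {
  train_config(lr0 = 0.05, max_iter = max_iter, seed = seed)
}
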