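#' Local binary pattern histogram
#'
#' Circular LBP codes: for each interior pixel, `P` points are sampled on a
#' circle of the given radius (bilinear interpolation); each sample at or
#' above the centre value contributes its bit. The `2^P` code histogram is
#' L1-normalized. The default `P = 9` is honoured literally; `P = 8` gives
#' the textbook variant.
#'
#' @param image Grayscale matrix, sides larger than `2 * radius + 1`.
#' @param n_points Number of circular sampling points `P`.
#' @param radius Sampling circle radius, pixels.
#' @return Numeric vector of length `2^P`, summing to 1.
#' @export
lbp_features <- function(image, n_points = 9L, radius = 1) {
  stop_if_not_image(image)
  if (min(dim(image)) < 2 * radius + 1) {
    abort("image too small for the requested LBP radius")
  }
  h <- nrow(image)
  w <- ncol(image)
  rr <- ceiling(radius)
  ys <- (rr + 1):(h - rr)
  xs <- (rr + 1):(w - rr)
  centers <- image[ys, xs, drop = FALSE]
  codes <- matrix(0, length(ys), length(xs))
  for (p in seq_len(n_points) - 1L) {
    ang <- 2 * pi * p / n_points
    dx <- radius * cos(ang)
    dy <- -radius * sin(ang)
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0; fy <- dy - y0
    # Avoid stepping past the frame when the offset is exactly integral.
    ox1 <- if (fx < 1e-9) 0L else 1L
    oy1 <- if (fy < 1e-9) 0L else 1L
    sample_at <- function(oy, ox) {
      image[ys + y0 + oy, xs + x0 + ox, drop = FALSE]
    }
    val <- (1 - fy) * (1 - fx) * sample_at(0, 0) +
      (1 - fy) * fx * sample_at(0, ox1) +
      fy * (1 - fx) * sample_at(oy1, 0) +
      fy * fx * sample_at(oy1, ox1)
    codes <- codes + 2^p * (val >= centers - 1e-9)
  }
  hist <- tabulate(as.integer(codes) + 1L, nbins = 2^n_points)
  hist / sum(hist)
}

haar_step <- function(m) {
  # One orthonormal 2-D Haar analysis step; sides must be even.
  ev_r <- seq(1, nrow(m), by = 2)
  ev_c <- seq(1, ncol(m), by = 2)
  a <- m[ev_r, , drop = FALSE]; b <- m[ev_r + 1, , drop = FALSE]
  lo_r <- (a + b) / sqrt(2)
  hi_r <- (a - b) / sqrt(2)
  split_cols <- function(x) {
    a <- x[, ev_c, drop = FALSE]; b <- x[, ev_c + 1, drop = FALSE]
    list(lo = (a + b) / sqrt(2), hi = (a - b) / sqrt(2))
  }
  rl <- split_cols(lo_r)
  rh <- split_cols(hi_r)
  list(ll = rl$lo, lh = rl$hi, hl = rh$lo, hh = rh$hi)
}

#' Two-level Haar wavelet features
#'
#' Orthonormal 2-D Haar decomposition to `levels` levels (images are
#' edge-padded to a multiple of `2^levels`); for each of the
#' `3 * levels + 1` subbands the mean absolute coefficient and the
#' coefficient standard deviation are concatenated (7 subbands, 14 values,
#' at the default 2 levels).
#'
#' @param image Grayscale matrix.
#' @param levels Decomposition depth.
#' @return Named numeric vector of length `2 * (3 * levels + 1)`.
#' @export
haar_wavelet_features <- function(image, levels = 2L) {
  stop_if_not_image(image)
  mult <- 2^levels
  pad_to <- function(n) ceiling(n / mult) * mult
  ph <- pad_to(nrow(image))
  pw <- pad_to(ncol(image))
  if (ph != nrow(image) || pw != ncol(image)) {
    image <- crop_padded(image, 1, pw, 1, ph)
  }
  bands <- list()
  ll <- image
  for (l in seq_len(levels)) {
    st <- haar_step(ll)
    bands[[paste0("lh", l)]] <- st$lh
    bands[[paste0("hl", l)]] <- st$hl
    bands[[paste0("hh", l)]] <- st$hh
    ll <- st$ll
  }
  bands[[paste0("ll", levels)]] <- ll
  out <- unlist(unname(purrr::imap(bands, function(b, nm) {
    v <- c(mean(abs(b)), stats::sd(as.numeric(b)))
    names(v) <- paste0(nm, c("_meanabs", "_sd"))
    v
  })))
  out[is.na(out)] <- 0   # sd of a single coefficient
  out
}

# Gray-level co-occurrence matrix at displacement (dy, dx), symmetric,
# normalized to sum 1.
glcm_single <- function(q, n_gray, dy, dx) {
  h <- nrow(q); w <- ncol(q)
  ys <- seq_len(h - abs(dy))
  xs <- seq_len(w - abs(dx))
  y1 <- if (dy >= 0) ys else ys + abs(dy)
  x1 <- if (dx >= 0) xs else xs + abs(dx)
  a <- q[y1, x1, drop = FALSE]
  b <- q[y1 + dy, x1 + dx, drop = FALSE]
  counts <- table(factor(a, levels = seq_len(n_gray)),
                  factor(b, levels = seq_len(n_gray)))
  m <- matrix(as.numeric(counts), n_gray, n_gray)
  m <- m + t(m)
  m / sum(m)
}

glcm_stats <- function(p) {
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p))
  sd_j <- sqrt(sum((j - mu_j)^2 * p))
  correlation <- if (sd_i * sd_j == 0) 0 else {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  }
  c(contrast = sum((i - j)^2 * p),
    correlation = correlation,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + (i - j)^2)))
}

# Gray-gradient co-occurrence matrix: joint distribution of quantized
# intensity and quantized Sobel gradient magnitude, with the standard 15
# secondary statistics.
ggcm_stats <- function(image, n_gray = 16L, n_gradient = 10L) {
  sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(image, sobel_x, boundary = "replicate")
  gy <- EBImage::filter2(image, t(sobel_x), boundary = "replicate")
  gmag <- sqrt(gx^2 + gy^2)
  quant <- function(x, n) {
    rng <- range(x)
    if (diff(rng) == 0) return(matrix(1L, nrow(x), ncol(x)))
    q <- floor((x - rng[1]) / diff(rng) * n) + 1L
    pmin(q, n)
  }
  gq <- quant(image, n_gray)
  sq <- quant(gmag, n_gradient)
  counts <- table(factor(gq, levels = seq_len(n_gray)),
                  factor(sq, levels = seq_len(n_gradient)))
  hm <- matrix(as.numeric(counts), n_gray, n_gradient)
  p <- hm / sum(hm)
  i <- matrix(seq_len(n_gray), n_gray, n_gradient)        # gray index
  j <- matrix(seq_len(n_gradient), n_gray, n_gradient, byrow = TRUE)
  p_i <- rowSums(p)
  p_j <- colSums(p)
  mu_i <- sum(seq_len(n_gray) * p_i)
  mu_j <- sum(seq_len(n_gradient) * p_j)
  sd_i <- sqrt(sum((seq_len(n_gray) - mu_i)^2 * p_i))
  sd_j <- sqrt(sum((seq_len(n_gradient) - mu_j)^2 * p_j))
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  c(
    small_gradient_dominance = sum(sweep(p, 2, j[1, ]^2, `/`)),
    large_gradient_dominance = sum(sweep(p, 2, j[1, ]^2, `*`)),
    gray_asymmetry = sum(p_i^2),
    gradient_asymmetry = sum(p_j^2),
    energy = sum(p^2),
    gray_mean = mu_i,
    gradient_mean = mu_j,
    gray_sd = sd_i,
    gradient_sd = sd_j,
    correlation = if (sd_i * sd_j == 0) 0 else {
      sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
    },
    gray_entropy = ent(p_i),
    gradient_entropy = ent(p_j),
    mixed_entropy = ent(p),
    inertia = sum((i - j)^2 * p),
    inverse_difference_moment = sum(p / (1 + (i - j)^2))
  )
}

#' Color/texture co-occurrence features
#'
#' Concatenates (a) gray-level co-occurrence statistics at displacement
#' `d = 1` averaged over four orientations (0, 45, 90, 135 degrees) on a
#' 16-level quantization — contrast, correlation, energy, homogeneity; (b)
#' the 15 standard gray-gradient co-occurrence statistics with 10 gradient
#' levels; and (c) intensity moments (mean, standard deviation, skewness).
#'
#' @param image Grayscale matrix, at least 2 x 2.
#' @param d Co-occurrence displacement, pixels.
#' @param n_gray Gray-level quantization for the GLCM.
#' @param n_gradient Gradient quantization for the gray-gradient matrix.
#' @return Named numeric vector of length 22.
#' @export
cote_features <- function(image, d = 1L, n_gray = 16L, n_gradient = 10L) {
  stop_if_not_image(image)
  if (min(dim(image)) < 2L) abort("image must be at least 2 x 2")
  rng <- range(image)
  q <- if (diff(rng) == 0) {
    matrix(1L, nrow(image), ncol(image))
  } else {
    pmin(floor((image - rng[1]) / diff(rng) * n_gray) + 1L, n_gray)
  }
  dirs <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  glcm_avg <- Reduce(`+`, purrr::map(dirs, function(o) {
    glcm_single(q, n_gray, o[1], o[2])
  })) / length(dirs)
  gl <- glcm_stats(glcm_avg)
  names(gl) <- paste0("glcm_", names(gl))
  gg <- ggcm_stats(image, n_gray = n_gray, n_gradient = n_gradient)
  names(gg) <- paste0("ggcm_", names(gg))
  mu <- mean(image)
  sdv <- stats::sd(as.numeric(image))
  skew <- if (sdv == 0) 0 else mean(((image - mu) / sdv)^3)
  c(gl, gg, moment_mean = mu, moment_sd = sdv, moment_skew = skew)
}

#' Extract conventional features from an image dataset
#'
#' Applies one of the texture extractors to every image of a dataset tibble
#' (as produced by [generate_eye_dataset()] or lens crops) and returns a
#' feature tibble ready for [fit_baseline()] or [rebalance()].
#'
#' @param data Tibble with list-column `image` and a `label` column.
#' @param method `"lbp"`, `"wt"` (Haar wavelet) or `"cote"`.
#' @param ... Passed to the extractor.
#' @return A tibble of features plus `label`.
#' @export
extract_features <- function(data, method = c("lbp", "wt", "cote"), ...) {
  method <- match.arg(method)
  fn <- switch(method, lbp = lbp_features, wt = haar_wavelet_features,
               cote = cote_features)
  feats <- purrr::map(data$image, fn, ...)
  mat <- do.call(rbind, feats)
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0(method, seq_len(ncol(mat)))
  }
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- make.names(names(out), unique = TRUE)
  out$label <- data$label
  out
}

#' Fit a conventional baseline classifier
#'
#' Thin adapter around the standard implementations with the reference
#' parameters: random forest with 300 trees, or a linear-kernel SVM with
#' probability estimates.
#'
#' @param data Data frame of features plus a `label` column (0/1).
#' @param classifier `"rf"` or `"svm"`.
#' @param n_trees Random-forest size.
#' @param label_col Name of the label column.
#' @param ... Passed to the underlying implementation.
#' @return An object of class `baseline_fit` with elements `model`,
#'   `classifier`, `params`, `feature_names`.
#' @export
fit_baseline <- function(data, classifier = c("rf", "svm"), n_trees = 300L,
                         label_col = "label", ...) {
  classifier <- match.arg(classifier)
  xy <- split_features(data, label_col)
  if (length(unique(xy$y)) < 2L) abort("training data contain a single class")
  yf <- factor(xy$y, levels = c(0L, 1L))
  model <- if (classifier == "rf") {
    randomForest::randomForest(x = xy$x, y = yf, ntree = n_trees, ...)
  } else {
    e1071::svm(x = xy$x, y = yf, kernel = "linear", probability = TRUE, ...)
  }
  params <- if (classifier == "rf") {
    list(n_trees = n_trees)
  } else {
    list(kernel = "linear")
  }
  structure(list(model = model, classifier = classifier, params = params,
                 feature_names = colnames(xy$x)),
            class = "baseline_fit")
}

#' Predict from a baseline classifier adapter
#'
#' @param object A `baseline_fit`.
#' @param newdata Data frame of features.
#' @param type `"prob"` (per-class probabilities) or `"class"`.
#' @param ... Unused.
#' @return Probability tibble (`p0`, `p1`) or 0/1 integer labels.
#' @export
predict.baseline_fit <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[object$feature_names])
  if (object$classifier == "rf") {
    p <- stats::predict(object$model, x, type = "prob")
  } else {
    pr <- stats::predict(object$model, x, probability = TRUE)
    p <- attr(pr, "probabilities")[, c("0", "1"), drop = FALSE]
  }
  p <- matrix(as.numeric(p), nrow = nrow(p),
              dimnames = list(NULL, c("p0", "p1")))
  if (type == "class") {
    return(as.integer(p[, "p1"] >= p[, "p0"]))
  }
  tibble::as_tibble(as.data.frame(p))
}
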