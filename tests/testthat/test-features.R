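test_that("LBP histograms are proper distributions", {
  img <- matrix(runif(32 * 32), 32, 32)
  h <- lbp_features(img, n_points = 9)
  expect_length(h, 2^9)
  expect_equal(sum(h), 1)
  # constant image: all comparisons are >= so every bit fires -> one bin
  hc <- lbp_features(matrix(0.4, 16, 16), n_points = 8)
  expect_equal(sum(hc > 0), 1L)
  expect_equal(max(hc), 1)
  expect_error(lbp_features(matrix(1, 3, 3), radius = 2), "too small")
})

test_that("the centre LBP code of a 3x3 image matches a hand oracle", {
  img <- matrix(c(0.9, 0.2, 0.7,
                  0.1, 0.5, 0.8,
                  0.3, 0.6, 0.4), 3, 3, byrow = TRUE)
  h <- lbp_features(img, n_points = 8, radius = 1)
  # independent oracle: sample the 8 circle points bilinearly by hand
  center <- img[2, 2]
  code <- 0
  for (p in 0:7) {
    ang <- 2 * pi * p / 8
    x <- 2 + cos(ang)
    y <- 2 - sin(ang)
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    gx <- function(yy, xx) img[min(max(yy, 1), 3), min(max(xx, 1), 3)]
    val <- (1 - fy) * (1 - fx) * gx(y0, x0) +
      (1 - fy) * fx * gx(y0, x0 + 1) +
      fy * (1 - fx) * gx(y0 + 1, x0) +
      fy * fx * gx(y0 + 1, x0 + 1)
    if (val >= center - 1e-9) code <- code + 2^p
  }
  expect_equal(which(h > 0) - 1L, as.integer(code))
})

test_that("LBP code multiset is preserved under 90-degree rotation (P = 8)", {
  set.seed(41)
  img <- matrix(runif(400), 20, 20)
  rot <- t(img)[, rev(seq_len(20))]     # 90-degree rotation
  h1 <- lbp_features(img, n_points = 8)
  h2 <- lbp_features(rot, n_points = 8)
  # rotation permutes codes by bit rotation (2 positions for P=8)
  rotate_code <- function(code, by = -2L, p = 8L) {
    bits <- as.integer(intToBits(code))[1:p]
    sum(bits[((seq_len(p) - 1L - by) %% p) + 1L] * 2^(0:(p - 1)))
  }
  perm <- vapply(0:255, rotate_code, numeric(1)) + 1L
  expect_equal(h2[perm], h1, tolerance = 1e-12)
})

test_that("Haar features match hand transforms and conserve energy", {
  # 2x2 constant block: orthonormal level-1 approximation is 2a
  a <- 0.3
  st <- csresnet:::haar_step(matrix(a, 2, 2))
  expect_equal(as.numeric(st$ll), 2 * a)
  expect_equal(as.numeric(st$lh), 0)
  expect_equal(as.numeric(st$hl), 0)
  expect_equal(as.numeric(st$hh), 0)

  hw <- haar_wavelet_features(matrix(0.25, 16, 16))
  details <- hw[!grepl("^ll", names(hw))]
  expect_true(all(details == 0))
  expect_equal(unname(hw["ll2_meanabs"]), 4 * 0.25)  # two levels of x2

  set.seed(42)
  m <- matrix(runif(64), 8, 8)
  st1 <- csresnet:::haar_step(m)
  expect_equal(sum(m^2),
               sum(st1$ll^2) + sum(st1$lh^2) + sum(st1$hl^2) +
                 sum(st1$hh^2))
  expect_length(haar_wavelet_features(m), 14L)
  # odd sizes are padded, not rejected
  expect_length(haar_wavelet_features(matrix(runif(49), 7, 7)), 14L)
})

test_that("co-occurrence features match hand-built toy matrices", {
  # constant image: single diagonal GLCM entry -> energy 1, contrast 0
  f <- cote_features(matrix(0.7, 8, 8))
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_correlation"]), 0)  # degenerate, flagged 0
  expect_equal(unname(f["moment_sd"]), 0)

  # checkerboard, horizontal displacement: all co-occurrence off-diagonal
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  q <- matrix(ifelse(cb == 1, 2L, 1L), 8, 8)
  g_h <- csresnet:::glcm_single(q, 2L, 0L, 1L)
  expect_equal(g_h[1, 1] + g_h[2, 2], 0)
  st <- csresnet:::glcm_stats(g_h)
  expect_equal(unname(st["contrast"]), 1)    # (2-1)^2 on every pair
  # feature length is image-independent
  expect_length(cote_features(matrix(runif(100), 10, 10)),
                length(cote_features(matrix(runif(64), 8, 8))))
})

test_that("feature extraction is deterministic and storage-order invariant", {
  set.seed(43)
  img <- matrix(runif(256), 16, 16)
  expect_identical(cote_features(img), cote_features(img))
  expect_identical(lbp_features(img), lbp_features(img))
  img2 <- matrix(as.numeric(img), 16, 16)   # fresh storage, same values
  expect_identical(haar_wavelet_features(img),
                   haar_wavelet_features(img2))
})

test_that("baseline adapters expose the reference parameters and separate easy data", {
  d <- generate_feature_dataset(30, 60, dim = 3, class_separation = 6,
                                seed = 44)
  set.seed(1)
  rf <- fit_baseline(d, "rf")
  expect_equal(rf$params$n_trees, 300)
  expect_equal(mean(predict(rf, d, type = "class") == d$label), 1.0)
  sv <- fit_baseline(d, "svm")
  expect_equal(sv$params$kernel, "linear")
  p <- predict(sv, d)
  expect_named(p, c("p0", "p1"))
  expect_equal(rowSums(as.matrix(p)), rep(1, 90), tolerance = 1e-6)
  expect_error(fit_baseline(dplyr::filter(d, label == 0), "rf"),
               "single class")
})

test_that("dataset-level extraction yields a model-ready tibble", {
  d <- generate_eye_dataset(4, 6, eye_image_params(image_size = 64),
                            seed = 45)
  fe <- extract_features(d, "wt")
  expect_equal(nrow(fe), 10L)
  expect_true("label" %in% names(fe))
  expect_equal(ncol(fe), 15L)   # 14 wavelet statistics + label
})
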