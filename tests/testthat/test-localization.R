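test_that("iou matches hand-computed areas and is a proper overlap", {
  a <- bounding_box(0, 0, 10, 10)
  b <- bounding_box(5, 0, 15, 10)
  expect_equal(iou(a, b), 1 / 3)      # 50 / 150
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, bounding_box(20, 20, 30, 30)), 0)
  expect_equal(iou(a, b), iou(b, a))
  expect_error(bounding_box(5, 0, 5, 10), "degenerate")
  # random boxes stay in [0, 1] and symmetric
  set.seed(1)
  for (i in 1:20) {
    p <- sort(runif(4, 0, 20))
    q <- sort(runif(4, 0, 20))
    b1 <- bounding_box(p[1], p[2], p[3] + 1, p[4] + 1)
    b2 <- bounding_box(q[1], q[2], q[3] + 1, q[4] + 1)
    v <- iou(b1, b2)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(b2, b1))
  }
})

test_that("canny finds no edges in a constant image and rejects bad thresholds", {
  expect_true(all(!canny_edges(matrix(0.5, 32, 32))))
  img <- disc_image(64, 32, 32, 15)
  expect_error(canny_edges(img, low_threshold = 0.5, high_threshold = 0.2),
               "low_threshold")
})

test_that("canny edges of a sharp disc hug the true boundary", {
  img <- disc_image(128, 64, 64, 30)
  e <- canny_edges(img)
  idx <- which(e, arr.ind = TRUE)
  expect_gt(nrow(idx), 50)
  d <- sqrt((idx[, 2] - 64)^2 + (idx[, 1] - 64)^2)
  expect_true(all(abs(d - 30) <= 2))
})

test_that("hough ranks circles by support, matching a brute-force oracle", {
  # Two disjoint ideal circles with different perimeters on a toy image.
  em <- raster_circle(64, 20, 20, 12) | raster_circle(64, 48, 48, 8)
  cand <- hough_circle(em, r_min = 5, r_max = 15, n_candidates = 2,
                       min_score = 5)
  expect_gte(length(cand), 2L)
  scores <- vapply(cand, function(c) c$score, numeric(1))
  expect_true(all(diff(scores) <= 0))
  # Oracle: support of the true circles.
  s_big <- brute_hough_score(em, 20, 20, 12)
  s_small <- brute_hough_score(em, 48, 48, 8)
  expect_gt(s_big, s_small)
  expect_lt(abs(cand[[1]]$cx - 20), 2.1)
  expect_lt(abs(cand[[1]]$cy - 20), 2.1)
  expect_lt(abs(cand[[1]]$r - 12), 2.1)
  # And the package score agrees with the oracle support at the peak.
  expect_lt(abs(cand[[1]]$score - s_big) / s_big, 0.35)

  expect_identical(hough_circle(matrix(FALSE, 32, 32), 5, 10), list())
  expect_error(hough_circle(em, r_min = 2, r_max = 10), "r_min")
  expect_error(hough_circle(em, r_min = 5, r_max = 40), "half the shorter")
})

test_that("hough detection of an ideal circle is accurate within 2 px", {
  em <- raster_circle(256, 128, 128, 60)
  cand <- hough_circle(em, r_min = 40, r_max = 80, n_candidates = 1)
  expect_lt(abs(cand[[1]]$cx - 128), 2.1)
  expect_lt(abs(cand[[1]]$cy - 128), 2.1)
  expect_lt(abs(cand[[1]]$r - 60), 2.1)
})

test_that("detected centres are translation-equivariant", {
  base <- disc_image(160, 70, 75, 30)
  shifted <- disc_image(160, 82, 63, 30)   # moved by (+12, -12)
  c1 <- hough_circle(canny_edges(base), 20, 45, 1)[[1]]
  c2 <- hough_circle(canny_edges(shifted), 20, 45, 1)[[1]]
  expect_lte(abs((c2$cx - c1$cx) - 12), 1)
  expect_lte(abs((c2$cy - c1$cy) + 12), 1)
})

test_that("localize_lens crops to the configured size and refines the circle", {
  p <- eye_image_params(lesion_count = 2, lesion_radius_range = c(8, 14))
  g <- generate_eye_image(p, seed = 3)
  loc <- localize_lens(g$image)
  expect_identical(dim(loc$crop), c(128L, 128L))
  expect_gte(iou(circle_bbox(loc$circle), circle_bbox(g$circle)), 0.8)

  cfg64 <- localize_config(out_size = 64)
  expect_identical(dim(localize_lens(g$image, cfg64)$crop), c(64L, 64L))

  # blank image: pass-1 failure signalled with the pass index
  err <- tryCatch(localize_lens(matrix(0.5, 128, 128)),
                  error = function(e) e)
  expect_s3_class(err, "csresnet_localization_failed")
  expect_identical(err$pass, 1L)
})

test_that("two-pass refinement does not degrade localization", {
  set.seed(99)
  p <- eye_image_params(noise_sd = 0.04)
  iou1 <- iou2 <- numeric(8)
  for (i in 1:8) {
    d <- generate_eye_dataset(1, 0, p, seed = 200 + i)
    img <- d$image[[1]]
    gt <- circle_bbox(list(cx = d$cx[1], cy = d$cy[1], r = d$r[1]))
    one <- localize_lens(img, localize_config(two_pass = FALSE))
    two <- localize_lens(img, localize_config(two_pass = TRUE))
    iou1[i] <- iou(circle_bbox(one$circle), gt)
    iou2[i] <- iou(circle_bbox(two$circle), gt)
  }
  expect_gte(median(iou2), median(iou1))
})

test_that("evaluate_localization averages IoUs with failures as zero", {
  gt <- list(circle_roi(50, 50, 20), circle_roi(60, 60, 25))
  perfect <- evaluate_localization(gt, gt)
  expect_equal(perfect$mean_iou, 1.0)
  half <- evaluate_localization(list(gt[[1]], NA), gt)
  expect_equal(half$mean_iou, 0.5)
  expect_equal(half$per_sample$iou, c(1, 0))
  expect_error(evaluate_localization(gt[1], gt), "equal length")
})
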