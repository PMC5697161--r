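test_that("batch normalization matches the closed forms", {
  bn <- bn_state(1, epsilon = 1e-5)
  out <- batch_norm_forward(matrix(c(0, 2), 2, 1), bn, "train")
  expect_equal(out$batch_mean, 1)
  expect_equal(out$batch_var, 1)          # biased (1/m) variance
  expect_equal(as.numeric(out$out), c(-1, 1) / sqrt(1 + 1e-5),
               tolerance = 1e-12)

  # constant batch: xhat = 0, output = beta
  bn2 <- bn_state(2)
  bn2$gamma <- c(3, -1); bn2$beta <- c(0.5, 2)
  outc <- batch_norm_forward(matrix(5, 4, 2), bn2, "train")
  expect_true(all(outc$out[, 1] == 0.5))
  expect_true(all(outc$out[, 2] == 2))

  # already standardized batch passes through up to O(epsilon)
  x <- matrix(c(-1, 1, -1, 1), 4, 1)
  out3 <- batch_norm_forward(x, bn_state(1), "train")
  expect_equal(as.numeric(out3$out), as.numeric(x), tolerance = 1e-4)

  expect_error(batch_norm_forward(matrix(1, 1, 2), bn_state(2), "train"),
               "m >= 2")
  expect_error(batch_norm_forward(matrix(c(1, NA), 2, 1), bn_state(1)),
               "non-finite")
})

test_that("train-mode BN output has mean beta and variance ~ gamma^2", {
  set.seed(21)
  bn <- bn_state(3)
  bn$gamma <- c(2, 0.5, 1.5); bn$beta <- c(-1, 0, 3)
  x <- matrix(rnorm(60, sd = 4), 20, 3)
  out <- batch_norm_forward(x, bn, "train")
  expect_equal(colMeans(out$out), bn$beta, tolerance = 1e-10)
  v <- apply(out$out, 2, function(c) mean((c - mean(c))^2))
  expect_equal(v, bn$gamma^2, tolerance = 1e-3)
  # inference mode uses running statistics, not the batch
  out_inf <- batch_norm_forward(x, out$state, "infer")
  expect_false(isTRUE(all.equal(colMeans(out_inf$out), bn$beta,
                                tolerance = 1e-6)))
})

test_that("zero residual branch reduces the block to ReLU(shortcut)", {
  blk <- csresnet:::with_seed(1, bottleneck_init(2, 2, 4))
  # force an identity shortcut by matching widths
  blk2 <- csresnet:::with_seed(1, bottleneck_init(4, 2, 4))
  blk2$conv1$w[] <- 0; blk2$conv2$w[] <- 0; blk2$conv3$w[] <- 0
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  out <- bottleneck_forward(x, blk2, "train")
  expect_equal(out$out, pmax(x, 0))
  expect_null(blk2$proj)
  expect_false(is.null(blk$proj))   # width change needs projection
})

test_that("stride-2 block halves the spatial extent", {
  blk <- csresnet:::with_seed(2, bottleneck_init(2, 2, 4, stride = 2))
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  out <- bottleneck_forward(x, blk, "train")
  expect_identical(dim(out$out), c(4L, 4L, 4L, 3L))
  expect_true(all(is.finite(out$out)))
  expect_error(bottleneck_forward(array(0, c(4, 4, 3, 2)), blk),
               "in_width")
})

test_that("block gradients match central differences on a toy input", {
  blk <- csresnet:::with_seed(3, bottleneck_init(2, 2, 4, stride = 1))
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  loss_of <- function(b, xx) {
    sum(bottleneck_forward(xx, b, "train")$out^2) / 2
  }
  f <- bottleneck_forward(x, blk, "train")
  bb <- csresnet:::bottleneck_backward(f$out, f$cache, blk)
  h <- 1e-5
  check_param <- function(path_get, path_set, analytic) {
    num <- analytic * 0
    for (i in seq_along(num)) {
      bp <- path_set(blk, i, h)
      bm <- path_set(blk, i, -h)
      num[i] <- (loss_of(bp, x) - loss_of(bm, x)) / (2 * h)
    }
    expect_lt(max(abs(analytic - num)) / max(abs(num)), 1e-4)
  }
  check_param(NULL, function(b, i, d) { b$conv2$w[i] <- b$conv2$w[i] + d; b },
              bb$grads$conv2)
  check_param(NULL, function(b, i, d) { b$conv1$w[i] <- b$conv1$w[i] + d; b },
              bb$grads$conv1)
  check_param(NULL, function(b, i, d) { b$bn3$gamma[i] <- b$bn3$gamma[i] + d; b },
              bb$grads$bn3$dgamma)
  check_param(NULL, function(b, i, d) { b$proj$w[i] <- b$proj$w[i] + d; b },
              bb$grads$proj)
  # input gradient on a subset of entries
  num_dx <- numeric(24)
  for (i in seq_len(24)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num_dx[i] <- (loss_of(blk, xp) - loss_of(blk, xm)) / (2 * h)
  }
  expect_lt(max(abs(bb$dx[1:24] - num_dx)) / max(abs(num_dx)), 1e-4)
})

test_that("the reference architecture prints the published totals", {
  arch <- build_reference_arch()
  expect_equal(n_residual_blocks(arch), 16L)
  expect_equal(n_block_convs(arch), 48L)
  expect_equal(arch$stem$n_kernels, 64L)
  expect_equal(arch$stem$kernel_size, 7L)
  expect_equal(vapply(arch$stages, `[[`, integer(1), "n_repeats"),
               c(3L, 4L, 6L, 3L))
  expect_equal(arch$head$classes, 2L)
})

test_that("mini architecture keeps the block grammar at desk scale", {
  arch <- build_mini_arch()
  expect_equal(n_residual_blocks(arch), 4L)
  expect_equal(n_block_convs(arch), 12L)
  one <- build_mini_arch(stage_repeats = 1L, bottleneck_widths = 2L,
                         out_widths = 8L)
  expect_equal(n_residual_blocks(one), 1L)
  expect_error(build_mini_arch(stage_repeats = 1L, bottleneck_widths = 8L,
                               out_widths = 4L), "exceed")
  # round-trip through JSON
  js <- arch_to_json(arch)
  back <- arch_from_json(js)
  expect_equal(n_residual_blocks(back), 4L)
  expect_equal(back$stem$n_kernels, arch$stem$n_kernels)
})

test_that("a forward pass yields probabilities summing to one", {
  arch <- build_mini_arch()
  net <- csresnet:::init_network(arch, in_channels = 1, seed = 4)
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  f <- csresnet:::network_features(net, x, mode = "train")
  feats <- cbind(f$features, bias = 1)
  p <- softmax_probs(net$head, feats)
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12)
  expect_true(all(is.finite(f$features)))
})

test_that("short training on tiny crops reduces the loss and logs it", {
  d <- generate_eye_dataset(6, 6, eye_image_params(image_size = 64),
                            seed = 30)
  crops <- lapply(d$image, function(im) csresnet:::resize_bilinear(im, 16))
  arch <- build_mini_arch(stage_repeats = 1L, bottleneck_widths = 2L,
                          out_widths = 8L, input_size = 16L)
  fit <- train_cs_network(
    crops, d$label, arch, cost_spec(c_min = 2),
    train_config(batch_size = 12, lr0 = 0.05, max_iter = 16,
                 eval_interval = 4, seed = 1),
    test_images = crops, test_labels = d$label
  )
  expect_equal(nrow(fit$log), 4L)
  expect_lt(fit$log$train_loss[4], fit$log$train_loss[1])
  p <- predict(fit, crops[1:3])
  expect_equal(rowSums(as.matrix(p)), rep(1, 3), tolerance = 1e-12)
})

test_that("augmentation is identity-free only when asked", {
  img <- matrix(runif(64), 8, 8)
  none <- augment_images(list(img), flips = FALSE, max_shift = 0, seed = 1)
  expect_identical(none[[1]], img)
  # double flip is the identity; a single flip preserves the pixel multiset
  flip <- img[, rev(seq_len(ncol(img)))]
  expect_identical(flip[, rev(seq_len(ncol(flip)))], img)
  expect_equal(sum(flip), sum(img))
  set.seed(1)
  shifted <- augment_images(rep(list(img), 8), flips = TRUE, max_shift = 2,
                            seed = 5)
  expect_identical(augment_images(rep(list(img), 8), flips = TRUE,
                                  max_shift = 2, seed = 5), shifted)
  expect_error(augment_images(list(img), max_shift = 8), "below the image")
})
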