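test_that("softmax probabilities are proper and shift-invariant", {
  w <- matrix(0, 3, 4)
  p <- softmax_probs(softmax_params(w), c(1, 2, 3, 4))
  expect_equal(p, rep(1 / 3, 3))
  w2 <- matrix(rnorm(8), 2, 4)
  w2[2, ] <- w2[1, ]
  expect_equal(softmax_probs(softmax_params(w2), rnorm(4)), c(0.5, 0.5))
  set.seed(4)
  w3 <- matrix(rnorm(12), 3, 4)
  x <- rnorm(4)
  expect_equal(softmax_probs(w3, x),
               softmax_probs(w3 + matrix(rnorm(1), 3, 4), x))
  p3 <- softmax_probs(softmax_params(w3), matrix(rnorm(20), 5, 4))
  expect_equal(rowSums(p3), rep(1, 5), tolerance = 1e-12)
  expect_error(softmax_probs(softmax_params(w3), c(1, NA, 1, 1)), "finite")
})

test_that("the cost-weighted loss matches hand evaluation and degenerates", {
  # minority sample predicted at p = 0.5, c_min = 12, lambda = 0
  par <- softmax_params(matrix(0, 2, 2), lambda = 0)
  J <- cs_cross_entropy(par, matrix(c(1, 1), 1, 2), 1L,
                        cost_spec(c_min = 12))
  expect_equal(J, 12 * log(2), tolerance = 1e-12)

  # c_min = 1 equals plain cross-entropy for an arbitrary batch
  set.seed(5)
  w <- matrix(rnorm(6), 2, 3)
  x <- matrix(rnorm(15), 5, 3)
  y <- c(0L, 1L, 1L, 0L, 1L)
  par2 <- softmax_params(w, lambda = 0)
  plain <- {
    p <- softmax_probs(par2, x)
    -mean(log(p[cbind(1:5, y + 1L)]))
  }
  expect_equal(cs_cross_entropy(par2, x, y, cost_spec(c_min = 1)), plain)

  # near-perfect prediction drives the loss toward zero
  wbig <- matrix(c(50, -50, -50, 50), 2, 2)  # row 2 favoured for x = (0, 1)
  parb <- softmax_params(wbig, lambda = 0)
  expect_lt(cs_cross_entropy(parb, matrix(c(0, 1), 1, 2), 1L,
                             cost_spec(c_min = 12)), 1e-10)
})

test_that("loss is monotone in the cost factor", {
  set.seed(6)
  w <- matrix(rnorm(8), 2, 4)
  x <- matrix(rnorm(24), 6, 4)
  y <- c(1L, 0L, 1L, 0L, 0L, 1L)
  par <- softmax_params(w, lambda = 0)
  J <- vapply(c(1, 2, 5, 12, 30), function(cm) {
    cs_cross_entropy(par, x, y, cost_spec(c_min = cm))
  }, numeric(1))
  expect_true(all(diff(J) > 0))   # minority samples imperfectly predicted
})

test_that("analytic gradient matches hand value and the numeric oracle", {
  # w = 0, single minority sample: p = 0.5 each, rows are -x and +x
  x <- c(0.3, -1.2, 2)
  par <- softmax_params(matrix(0, 2, 3), lambda = 0)
  g <- cs_gradient(par, matrix(x, 1, 3), 1L, cost_spec(c_min = 2))
  expect_equal(g[2, ], -x)   # true class row (label 1 -> row 2)
  expect_equal(g[1, ], +x)

  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    n <- sample(2:10, 1)
    m <- sample(1:8, 1)
    par <- softmax_params(matrix(rnorm(k * n), k, n),
                          lambda = runif(1, 0, 0.1))
    x <- matrix(rnorm(m * n), m, n)
    y <- c(0L, sample(0:(k - 1), m - 1, replace = TRUE))
    cost <- cost_spec(minority_label = 1L, c_min = sample(c(1, 3, 12), 1))
    ga <- cs_gradient(par, x, y, cost)
    gn <- numeric_cs_gradient(par, x, y, cost)
    expect_lt(max(abs(ga - gn)) / max(max(abs(gn)), 1), 1e-6)
  }
})

test_that("c_min = 1 reduces training exactly to the cost-free baseline", {
  d <- generate_feature_dataset(20, 60, dim = 2, class_separation = 2,
                                seed = 9)
  f1 <- train_cs_softmax(d, cost_spec(c_min = 1), probe_config(9, 100))
  f2 <- train_cs_softmax(d, cost_spec(c_min = 1), probe_config(9, 100))
  expect_identical(f1$params$w, f2$params$w)
  g1 <- cs_gradient(f1$params, as.matrix(cbind(d[1:4, 1:2], 1)),
                    d$label[1:4], cost_spec(c_min = 1))
  g2 <- {
    p <- f1$params; p$lambda <- p$lambda
    cs_gradient(p, as.matrix(cbind(d[1:4, 1:2], 1)), d$label[1:4],
                cost_spec(c_min = 1))
  }
  expect_identical(g1, g2)
})

test_that("the learning-rate schedule steps down by decay_factor", {
  cfg <- train_config()
  expect_equal(learning_rate(0, cfg), 0.001)
  expect_equal(learning_rate(500, cfg), 0.0001)
  expect_equal(learning_rate(1000, cfg), 0.00001)
  expect_equal(learning_rate(499, cfg), 0.001)
})

test_that("training loss trends down on separable data", {
  d <- generate_feature_dataset(100, 100, dim = 2, class_separation = 6,
                                seed = 10)
  fit <- train_cs_softmax(d, cost_spec(c_min = 1), probe_config(10, 500),
                          test_data = d)
  log <- log_convergence(fit)
  smooth5 <- stats::filter(log$test_loss, rep(1 / 5, 5), sides = 1)
  smooth5 <- smooth5[!is.na(smooth5)]
  expect_true(all(diff(smooth5) <= 1e-6))
  expect_error(train_cs_softmax(dplyr::filter(d, label == 1),
                                cost_spec(), train_config()),
               "single class")
})

test_that("weight decay shrinks trained weights on pure-noise data", {
  d <- generate_feature_dataset(50, 50, dim = 4, class_separation = 0,
                                seed = 12)
  cfg0 <- probe_config(12, 400); cfg0$lambda <- 0
  cfgl <- probe_config(12, 400); cfgl$lambda <- 0.05
  f0 <- train_cs_softmax(d, cost_spec(c_min = 1), cfg0)
  fl <- train_cs_softmax(d, cost_spec(c_min = 1), cfgl)
  nw <- function(f) sum(f$params$w[, seq_len(4)]^2)  # exclude bias
  expect_lt(nw(fl), nw(f0))
})

test_that("raising the cost factor trades specificity for sensitivity", {
  sens <- spec <- matrix(NA_real_, 3, 3)
  for (s in 1:3) {
    tr <- probe_train(s)
    te <- probe_test(s)
    for (ci in seq_along(c(1, 4, 12))) {
      cm <- c(1, 4, 12)[ci]
      f <- train_cs_softmax(tr, cost_spec(c_min = cm), probe_config(s))
      r <- basic_metrics(confusion(te$label, predict(f, te, "class")))
      sens[s, ci] <- r$sensitivity
      spec[s, ci] <- r$specificity
    }
  }
  med_sens <- apply(sens, 2, median)
  med_spec <- apply(spec, 2, median)
  expect_true(all(diff(med_sens) >= 0))
  expect_true(all(diff(med_spec) <= 0))
})

test_that("threshold moving shifts decisions toward the minority class", {
  probs <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(1, 0))
  expect_equal(threshold_moving_predict(probs, c(1, 4)), c(1L, 1L, 0L))
  expect_equal(threshold_moving_predict(probs, c(1, 1)), c(0L, 1L, 0L))
  # exact tie goes to the minority class
  expect_equal(threshold_moving_predict(rbind(c(0.8, 0.2)), c(1, 4)), 1L)
  expect_error(threshold_moving_predict(probs, c(1, 2, 3)), "number of classes")
  expect_error(threshold_moving_predict(probs, c(1, -1)), "positive")
})

test_that("tidy and glance expose fit internals as tibbles", {
  d <- generate_feature_dataset(20, 40, dim = 2, class_separation = 2,
                                seed = 13)
  fit <- train_cs_softmax(d, cost_spec(c_min = 4), probe_config(13, 100),
                          test_data = d)
  td <- tidy(fit)
  expect_named(td, c("class", "term", "estimate"))
  expect_equal(nrow(td), 2 * 3)    # 2 classes x (2 features + bias)
  gl <- glance(fit)
  expect_equal(gl$c_min, 4)
  expect_equal(gl$iterations, 100)
})
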