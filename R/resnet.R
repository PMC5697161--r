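# Tensors are arrays with dim c(h, w, channels, batch). All layers provide
# forward and backward passes in plain R; the package targets desk-scale
# inputs, where clarity and testability beat raw speed.

pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

unpad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  x[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , , drop = FALSE]
}

im2col <- function(x, kh, kw, stride) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  cols <- matrix(0, kh * kw * cin, oh * ow * n)
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      patch <- x[ki + stride * (seq_len(oh) - 1L),
                 kj + stride * (seq_len(ow) - 1L), , , drop = FALSE]
      pm <- matrix(aperm(patch, c(1, 2, 4, 3)), oh * ow * n, cin)
      rows <- (seq_len(cin) - 1L) * kh * kw + (kj - 1L) * kh + ki
      cols[rows, ] <- t(pm)
    }
  }
  list(cols = cols, oh = oh, ow = ow)
}

col2im <- function(dcols, dim_x, kh, kw, stride, oh, ow) {
  h <- dim_x[1]; w <- dim_x[2]; cin <- dim_x[3]; n <- dim_x[4]
  dx <- array(0, dim_x)
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      rows <- (seq_len(cin) - 1L) * kh * kw + (kj - 1L) * kh + ki
      block <- array(t(dcols[rows, , drop = FALSE]), c(oh, ow, n, cin))
      block <- aperm(block, c(1, 2, 4, 3))
      ys <- ki + stride * (seq_len(oh) - 1L)
      xs <- kj + stride * (seq_len(ow) - 1L)
      dx[ys, xs, , ] <- dx[ys, xs, , , drop = FALSE] + block
    }
  }
  dx
}

# Convolution layer parameters: weights dim c(kh, kw, cin, cout), no bias
# (a BN + scaling block follows every convolution).
conv_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       stride = 1L, pad = 0L)
}

conv_forward <- function(x, layer) {
  d <- dim(layer$w)
  xp <- pad_spatial(x, layer$pad)
  ic <- im2col(xp, d[1], d[2], layer$stride)
  wm <- matrix(layer$w, d[1] * d[2] * d[3], d[4])
  out_m <- t(ic$cols) %*% wm                     # (oh*ow*n) x cout
  n <- dim(x)[4]
  out <- aperm(array(out_m, c(ic$oh, ic$ow, n, d[4])), c(1, 2, 4, 3))
  list(out = out,
       cache = list(cols = ic$cols, dim_xp = dim(xp), oh = ic$oh,
                    ow = ic$ow, n = n))
}

conv_backward <- function(dout, cache, layer) {
  d <- dim(layer$w)
  dout_m <- matrix(aperm(dout, c(1, 2, 4, 3)),
                   cache$oh * cache$ow * cache$n, d[4])
  wm <- matrix(layer$w, d[1] * d[2] * d[3], d[4])
  dwm <- cache$cols %*% dout_m
  dcols <- wm %*% t(dout_m)
  dxp <- col2im(dcols, cache$dim_xp, d[1], d[2], layer$stride,
                cache$oh, cache$ow)
  list(dx = unpad_spatial(dxp, layer$pad), dw = array(dwm, d))
}

#' Batch-normalization state
#'
#' Per-channel trainable scale `gamma` and shift `beta`, the numerical
#' stabilizer `epsilon`, and exponentially averaged running statistics used
#' at inference time.
#'
#' @param channels Number of channels.
#' @param epsilon Positive stabilizer added to the variance.
#' @param momentum Running-average factor in `(0, 1]`:
#'   `running <- momentum * running + (1 - momentum) * batch`.
#' @return An object of class `bn_state`.
#' @export
bn_state <- function(channels, epsilon = 1e-5, momentum = 0.9) {
  if (epsilon <= 0) abort("`epsilon` must be positive")
  if (momentum <= 0 || momentum > 1) abort("`momentum` must lie in (0, 1]")
  structure(list(gamma = rep(1, channels), beta = rep(0, channels),
                 epsilon = epsilon, momentum = momentum,
                 running_mean = rep(0, channels),
                 running_var = rep(1, channels)),
            class = "bn_state")
}

#' Batch normalization and scaling, forward pass
#'
#' In training mode each channel is standardized by the mini-batch mean and
#' (biased) variance, `xhat = (x - mu_m) / sqrt(sigma2_m + epsilon)`, then
#' scaled and shifted, `y = gamma * xhat + beta`; running statistics are
#' updated. In inference mode the running statistics are used instead.
#'
#' @param x A matrix (`m` samples x channels) or a 4-D tensor
#'   `(h, w, channels, batch)`; normalization is per channel over every
#'   other dimension.
#' @param state A [bn_state()].
#' @param mode `"train"` (requires an effective batch of at least 2 values
#'   per channel) or `"infer"`.
#' @return A list: `out` (same shape as `x`), `state` (updated running
#'   statistics), `cache` (for the backward pass), `batch_mean`,
#'   `batch_var`.
#' @export
batch_norm_forward <- function(x, state, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  if (!all(is.finite(x))) abort("non-finite input to batch normalization")
  is_4d <- length(dim(x)) == 4L
  if (is_4d) {
    ch <- dim(x)[3]
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = ch)   # rows = h*w*n
  } else {
    xm <- as.matrix(x)
    ch <- ncol(xm)
  }
  m <- nrow(xm)
  if (mode == "train") {
    if (m < 2L) abort("training-mode batch normalization requires m >= 2")
    mu <- colMeans(xm)
    centered <- sweep(xm, 2, mu)
    sigma2 <- colMeans(centered^2)                      # biased, 1/m
    inv_std <- 1 / sqrt(sigma2 + state$epsilon)
    xhat <- sweep(centered, 2, inv_std, `*`)
    state$running_mean <- state$momentum * state$running_mean +
      (1 - state$momentum) * mu
    state$running_var <- state$momentum * state$running_var +
      (1 - state$momentum) * sigma2
  } else {
    mu <- state$running_mean
    sigma2 <- state$running_var
    inv_std <- 1 / sqrt(sigma2 + state$epsilon)
    xhat <- sweep(sweep(xm, 2, mu), 2, inv_std, `*`)
  }
  ym <- sweep(sweep(xhat, 2, state$gamma, `*`), 2, state$beta, `+`)
  out <- if (is_4d) {
    d <- dim(x)
    aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else if (is.matrix(x)) {
    ym
  } else {
    drop(ym)
  }
  list(out = out, state = state,
       cache = list(xhat = xhat, inv_std = inv_std, is_4d = is_4d,
                    dim_x = dim(x), m = m),
       batch_mean = mu, batch_var = sigma2)
}

batch_norm_backward <- function(dout, cache, state) {
  ch <- length(state$gamma)
  dym <- if (cache$is_4d) {
    matrix(aperm(dout, c(1, 2, 4, 3)), ncol = ch)
  } else {
    as.matrix(dout)
  }
  m <- cache$m
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, state$gamma, `*`)
  dxm <- sweep(
    dxhat - matrix(colMeans(dxhat), m, ch, byrow = TRUE) -
      xhat * matrix(colMeans(dxhat * xhat), m, ch, byrow = TRUE),
    2, cache$inv_std, `*`
  )
  dx <- if (cache$is_4d) {
    d <- cache$dim_x
    aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else {
    dxm
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu <- function(x) pmax(x, 0)

maxpool_forward <- function(x, size = 2L, stride = size) {
  d <- dim(x)
  oh <- (d[1] - size) %/% stride + 1L
  ow <- (d[2] - size) %/% stride + 1L
  mx <- array(-Inf, c(oh, ow, d[3], d[4]))
  for (kj in seq_len(size)) {
    for (ki in seq_len(size)) {
      patch <- x[ki + stride * (seq_len(oh) - 1L),
                 kj + stride * (seq_len(ow) - 1L), , , drop = FALSE]
      mx <- pmax(mx, patch)
    }
  }
  list(out = mx, cache = list(x = x, mx = mx, size = size, stride = stride,
                              oh = oh, ow = ow))
}

maxpool_backward <- function(dout, cache) {
  dx <- array(0, dim(cache$x))
  assigned <- array(FALSE, dim(dout))
  s <- cache$stride
  for (kj in seq_len(cache$size)) {
    for (ki in seq_len(cache$size)) {
      ys <- ki + s * (seq_len(cache$oh) - 1L)
      xs <- kj + s * (seq_len(cache$ow) - 1L)
      patch <- cache$x[ys, xs, , , drop = FALSE]
      hit <- (patch == cache$mx) & !assigned
      assigned <- assigned | hit
      dx[ys, xs, , ] <- dx[ys, xs, , , drop = FALSE] + dout * hit
    }
  }
  dx
}

global_avg_pool <- function(x) {
  d <- dim(x)
  feats <- t(apply(x, c(3, 4), mean))     # n x channels
  list(out = matrix(feats, d[4], d[3]), hw = d[1] * d[2], dim_x = d)
}

global_avg_pool_backward <- function(dfeats, cache) {
  d <- cache$dim_x
  dx <- array(0, d)
  for (ch in seq_len(d[3])) {
    for (s in seq_len(d[4])) {
      dx[, , ch, s] <- dfeats[s, ch] / cache$hw
    }
  }
  dx
}

#' Bottleneck residual block parameters
#'
#' A three-convolution bottleneck: 1x1 reduce, 3x3, 1x1 expand, each
#' followed by batch normalization + scaling; ReLU after the first two BNs
#' and after the residual addition. The shortcut is the identity when the
#' input width and stride match, otherwise a 1x1 projection convolution
#' with its own BN.
#'
#' @param in_width,bottleneck_width,out_width Channel counts
#'   (`out_width > bottleneck_width`).
#' @param stride Spatial stride of the 3x3 convolution (and projection).
#' @return A list of class `bottleneck_block` holding all parameters.
#' @export
bottleneck_init <- function(in_width, bottleneck_width, out_width,
                            stride = 1L) {
  if (out_width <= bottleneck_width) {
    abort("`out_width` must exceed `bottleneck_width`")
  }
  conv2 <- conv_init(3, 3, bottleneck_width, bottleneck_width)
  conv2$stride <- as.integer(stride)
  conv2$pad <- 1L
  block <- list(
    conv1 = conv_init(1, 1, in_width, bottleneck_width),
    bn1 = bn_state(bottleneck_width),
    conv2 = conv2,
    bn2 = bn_state(bottleneck_width),
    conv3 = conv_init(1, 1, bottleneck_width, out_width),
    bn3 = bn_state(out_width),
    in_width = in_width, out_width = out_width, stride = as.integer(stride)
  )
  if (in_width != out_width || stride != 1L) {
    proj <- conv_init(1, 1, in_width, out_width)
    proj$stride <- as.integer(stride)
    block$proj <- proj
    block$bn_proj <- bn_state(out_width)
  }
  structure(block, class = "bottleneck_block")
}

#' Bottleneck residual block, forward pass
#'
#' `out = ReLU(F(x) + shortcut(x))` where `F` is
#' conv1x1 - BN - ReLU - conv3x3 - BN - ReLU - conv1x1 - BN and the
#' shortcut is the identity or a projection conv + BN.
#'
#' @param x Input tensor `(h, w, in_width, batch)`.
#' @param block A [bottleneck_init()] object.
#' @param mode `"train"` or `"infer"` (affects batch normalization).
#' @return A list: `out`, `block` (updated BN running stats), `cache`.
#' @export
bottleneck_forward <- function(x, block, mode = "train") {
  if (dim(x)[3] != block$in_width) {
    abort("input width does not match block `in_width`")
  }
  c1 <- conv_forward(x, block$conv1)
  b1 <- batch_norm_forward(c1$out, block$bn1, mode)
  block$bn1 <- b1$state
  r1 <- relu(b1$out)
  c2 <- conv_forward(r1, block$conv2)
  b2 <- batch_norm_forward(c2$out, block$bn2, mode)
  block$bn2 <- b2$state
  r2 <- relu(b2$out)
  c3 <- conv_forward(r2, block$conv3)
  b3 <- batch_norm_forward(c3$out, block$bn3, mode)
  block$bn3 <- b3$state

  if (!is.null(block$proj)) {
    cp <- conv_forward(x, block$proj)
    bp <- batch_norm_forward(cp$out, block$bn_proj, mode)
    block$bn_proj <- bp$state
    shortcut <- bp$out
    proj_cache <- list(conv = cp$cache, bn = bp$cache)
  } else {
    if (!identical(dim(x), dim(b3$out))) {
      abort("width/stride mismatch requires a projection shortcut")
    }
    shortcut <- x
    proj_cache <- NULL
  }
  pre <- b3$out + shortcut
  out <- relu(pre)
  list(out = out, block = block,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2,
                    c3 = c3$cache, b3 = b3$cache,
                    proj = proj_cache, pre = pre, b1_out = b1$out,
                    b2_out = b2$out))
}

bottleneck_backward <- function(dout, cache, block) {
  dpre <- dout * (cache$pre > 0)
  bb3 <- batch_norm_backward(dpre, cache$b3, block$bn3)
  cb3 <- conv_backward(bb3$dx, cache$c3, block$conv3)
  dr2 <- cb3$dx * (cache$b2_out > 0)
  bb2 <- batch_norm_backward(dr2, cache$b2, block$bn2)
  cb2 <- conv_backward(bb2$dx, cache$c2, block$conv2)
  dr1 <- cb2$dx * (cache$b1_out > 0)
  bb1 <- batch_norm_backward(dr1, cache$b1, block$bn1)
  cb1 <- conv_backward(bb1$dx, cache$c1, block$conv1)

  dx <- cb1$dx
  grads <- list(conv1 = cb1$dw, bn1 = list(dgamma = bb1$dgamma,
                                           dbeta = bb1$dbeta),
                conv2 = cb2$dw, bn2 = list(dgamma = bb2$dgamma,
                                           dbeta = bb2$dbeta),
                conv3 = cb3$dw, bn3 = list(dgamma = bb3$dgamma,
                                           dbeta = bb3$dbeta))
  if (!is.null(cache$proj)) {
    bbp <- batch_norm_backward(dpre, cache$proj$bn, block$bn_proj)
    cbp <- conv_backward(bbp$dx, cache$proj$conv, block$proj)
    dx <- dx + cbp$dx
    grads$proj <- cbp$dw
    grads$bn_proj <- list(dgamma = bbp$dgamma, dbeta = bbp$dbeta)
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

#' Reference 50-layer architecture specification
#'
#' The full-depth layout: a 7x7 stem convolution with 64 kernels (stride
#' 2), a 3x3 max pool (stride 2), four stages of bottleneck residual blocks
#' repeated (3, 4, 6, 3) times with widths 64-256, 128-512, 256-1024,
#' 512-2048, then global average pooling and a binary softmax head —
#' 16 residual blocks holding 48 convolutions in total.
#'
#' @return An object of class `arch_spec`.
#' @export
build_reference_arch <- function() {
  stages <- list(
    list(n_repeats = 3L, bottleneck_width = 64L, out_width = 256L,
         stride = 1L),
    list(n_repeats = 4L, bottleneck_width = 128L, out_width = 512L,
         stride = 2L),
    list(n_repeats = 6L, bottleneck_width = 256L, out_width = 1024L,
         stride = 2L),
    list(n_repeats = 3L, bottleneck_width = 512L, out_width = 2048L,
         stride = 2L)
  )
  structure(
    list(stem = list(kernel_size = 7L, n_kernels = 64L, stride = 2L),
         pool = list(size = 3L, stride = 2L),
         stages = stages,
         head = list(classes = 2L),
         input_size = 128L),
    class = "arch_spec"
  )
}

#' Desk-scale mini architecture specification
#'
#' Same block grammar as the reference network at reduced depth and width,
#' sized for CPU training on small synthetic crops (default: 4 bottleneck
#' blocks, 12 in-block convolutions, 32x32 inputs).
#'
#' @param stage_repeats Integer vector of block repeats per stage.
#' @param bottleneck_widths,out_widths Channel counts per stage
#'   (`out > bottleneck` elementwise).
#' @param input_size Expected input side, pixels.
#' @return An object of class `arch_spec`.
#' @export
build_mini_arch <- function(stage_repeats = c(2L, 2L),
                            bottleneck_widths = c(4L, 8L),
                            out_widths = c(16L, 32L),
                            input_size = 32L) {
  if (length(stage_repeats) < 1L) abort("need at least one stage")
  if (length(bottleneck_widths) != length(stage_repeats) ||
      length(out_widths) != length(stage_repeats)) {
    abort("stage width vectors must match `stage_repeats` in length")
  }
  if (any(out_widths <= bottleneck_widths)) {
    abort("each `out_width` must exceed its `bottleneck_width`")
  }
  stages <- purrr::pmap(
    list(stage_repeats, bottleneck_widths, out_widths,
         c(1L, rep(2L, length(stage_repeats) - 1L))),
    function(n, bw, ow, s) {
      list(n_repeats = as.integer(n), bottleneck_width = as.integer(bw),
           out_width = as.integer(ow), stride = as.integer(s))
    }
  )
  structure(
    list(stem = list(kernel_size = 3L, n_kernels = 8L, stride = 1L),
         pool = list(size = 2L, stride = 2L),
         stages = stages,
         head = list(classes = 2L),
         input_size = as.integer(input_size)),
    class = "arch_spec"
  )
}

#' Count residual blocks in an architecture
#' @param arch An `arch_spec`.
#' @return Integer number of bottleneck residual blocks.
#' @export
n_residual_blocks <- function(arch) {
  sum(vapply(arch$stages, function(s) s$n_repeats, integer(1)))
}

#' Count convolutions inside residual blocks
#' @param arch An `arch_spec`.
#' @return Integer: 3 convolutions per bottleneck block (projection
#'   shortcuts not counted).
#' @export
n_block_convs <- function(arch) 3L * n_residual_blocks(arch)

#' Serialize an architecture specification to JSON
#' @param arch An `arch_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
arch_to_json <- function(arch, path = NULL) {
  json <- jsonlite::toJSON(unclass(arch), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read an architecture specification from JSON
#' @param path File path or JSON string.
#' @return An `arch_spec`.
#' @export
arch_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  obj$stages <- purrr::map(obj$stages, function(s) {
    purrr::map(s, as.integer)
  })
  structure(obj, class = "arch_spec")
}

# Instantiate all trainable parameters of an architecture.
init_network <- function(arch, in_channels = 1L, seed = 1L) {
  with_seed(seed, {
    stem <- conv_init(arch$stem$kernel_size, arch$stem$kernel_size,
                      in_channels, arch$stem$n_kernels)
    stem$stride <- arch$stem$stride
    stem$pad <- (arch$stem$kernel_size - 1L) %/% 2L
    blocks <- list()
    width <- arch$stem$n_kernels
    for (st in arch$stages) {
      for (rep_i in seq_len(st$n_repeats)) {
        stride <- if (rep_i == 1L) st$stride else 1L
        blocks[[length(blocks) + 1L]] <-
          bottleneck_init(width, st$bottleneck_width, st$out_width, stride)
        width <- st$out_width
      }
    }
    head_w <- matrix(stats::rnorm(arch$head$classes * (width + 1L),
                                  sd = 0.01),
                     arch$head$classes, width + 1L)
    list(arch = arch, stem = stem, bn_stem = bn_state(arch$stem$n_kernels),
         blocks = blocks,
         head = softmax_params(head_w, decay_free_cols = width + 1L),
         feature_width = width)
  })
}

# Forward pass to pooled features (n x feature_width matrix).
network_features <- function(net, x, mode = "train", keep_cache = FALSE) {
  cs <- conv_forward(x, net$stem)
  bs <- batch_norm_forward(cs$out, net$bn_stem, mode)
  net$bn_stem <- bs$state
  rs <- relu(bs$out)
  mp <- maxpool_forward(rs, net$arch$pool$size, net$arch$pool$stride)
  h <- mp$out
  block_caches <- vector("list", length(net$blocks))
  for (i in seq_along(net$blocks)) {
    bf <- bottleneck_forward(h, net$blocks[[i]], mode)
    net$blocks[[i]] <- bf$block
    h <- bf$out
    if (keep_cache) block_caches[[i]] <- bf$cache
  }
  gp <- global_avg_pool(h)
  cache <- NULL
  if (keep_cache) {
    cache <- list(stem_conv = cs$cache, stem_bn = bs$cache,
                  stem_bn_out = bs$out, pool = mp$cache,
                  blocks = block_caches, gap = gp)
  }
  list(features = gp$out, net = net, cache = cache)
}

network_backward <- function(dfeats, cache, net) {
  dh <- global_avg_pool_backward(dfeats, cache$gap)
  block_grads <- vector("list", length(net$blocks))
  for (i in rev(seq_along(net$blocks))) {
    bb <- bottleneck_backward(dh, cache$blocks[[i]], net$blocks[[i]])
    block_grads[[i]] <- bb$grads
    dh <- bb$dx
  }
  dmp <- maxpool_backward(dh, cache$pool)
  drs <- dmp * (cache$stem_bn_out > 0)
  bbs <- batch_norm_backward(drs, cache$stem_bn, net$bn_stem)
  cbs <- conv_backward(bbs$dx, cache$stem_conv, net$stem)
  list(stem = cbs$dw,
       bn_stem = list(dgamma = bbs$dgamma, dbeta = bbs$dbeta),
       blocks = block_grads)
}

apply_block_update <- function(block, g, lr) {
  block$conv1$w <- block$conv1$w - lr * g$conv1
  block$conv2$w <- block$conv2$w - lr * g$conv2
  block$conv3$w <- block$conv3$w - lr * g$conv3
  block$bn1$gamma <- block$bn1$gamma - lr * g$bn1$dgamma
  block$bn1$beta <- block$bn1$beta - lr * g$bn1$dbeta
  block$bn2$gamma <- block$bn2$gamma - lr * g$bn2$dgamma
  block$bn2$beta <- block$bn2$beta - lr * g$bn2$dbeta
  block$bn3$gamma <- block$bn3$gamma - lr * g$bn3$dgamma
  block$bn3$beta <- block$bn3$beta - lr * g$bn3$dbeta
  if (!is.null(g$proj)) {
    block$proj$w <- block$proj$w - lr * g$proj
    block$bn_proj$gamma <- block$bn_proj$gamma - lr * g$bn_proj$dgamma
    block$bn_proj$beta <- block$bn_proj$beta - lr * g$bn_proj$dbeta
  }
  block
}

#' Train a cost-sensitive residual network (desk scale)
#'
#' End-to-end mini-batch gradient descent on image tensors through the mini
#' architecture: stem conv - BN - ReLU - max pool - bottleneck blocks -
#' global average pooling - cost-sensitive softmax head. Intended for small
#' synthetic crops; the full-depth architecture is supported in principle
#' but impractical to train without accelerators.
#'
#' @param images List of grayscale matrices (equal size) or a 4-D tensor.
#' @param labels 0/1 labels.
#' @param arch An `arch_spec`, typically [build_mini_arch()].
#' @param cost A [cost_spec()].
#' @param config A [train_config()] (use small `max_iter`).
#' @param test_images,test_labels Optional held-out data for logging.
#' @return An object of class `cs_net_fit` with `net`, `log`, `cost`,
#'   `config`.
#' @export
train_cs_network <- function(images, labels, arch = build_mini_arch(),
                             cost = cost_spec(),
                             config = train_config(batch_size = 8,
                                                   max_iter = 60,
                                                   eval_interval = 10),
                             test_images = NULL, test_labels = NULL) {
  x <- as_tensor(images)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) abort("training data contain a single class")
  x_test <- if (!is.null(test_images)) as_tensor(test_images)
  net <- init_network(arch, in_channels = dim(x)[3], seed = config$seed)
  net$head$lambda <- config$lambda
  m_all <- dim(x)[4]
  with_seed(config$seed + 1L, {
    order_idx <- integer(0)
    log_rows <- list()
    for (t in seq_len(config$max_iter) - 1L) {
      if (length(order_idx) < config$batch_size) {
        order_idx <- c(order_idx, sample.int(m_all))
      }
      take <- seq_len(min(config$batch_size, length(order_idx)))
      batch <- order_idx[take]
      order_idx <- order_idx[-take]
      xb <- x[, , , batch, drop = FALSE]
      yb <- y[batch]
      lr <- learning_rate(t, config)

      fwd <- network_features(net, xb, mode = "train", keep_cache = TRUE)
      net <- fwd$net
      feats <- cbind(fwd$features, bias = 1)
      head <- net$head
      loss <- cs_cross_entropy(head, feats, yb, cost)
      ghead <- cs_gradient(head, feats, yb, cost)
      # dJ/dlogits = (C/m) (p - ind); features gradient via the head.
      p <- softmax_probs(head, feats)
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      k <- nrow(head$w)
      ind <- matrix(0, length(yb), k)
      ind[cbind(seq_along(yb), label_rows(yb, k))] <- 1
      cf <- cost_factors(yb, cost)
      dlogits <- (p - ind) * cf / length(yb)
      dfeats <- dlogits %*% head$w[, seq_len(net$feature_width),
                                   drop = FALSE]
      grads <- network_backward(dfeats, fwd$cache, net)

      net$head$w <- net$head$w - lr * ghead
      net$stem$w <- net$stem$w - lr * grads$stem
      net$bn_stem$gamma <- net$bn_stem$gamma - lr * grads$bn_stem$dgamma
      net$bn_stem$beta <- net$bn_stem$beta - lr * grads$bn_stem$dbeta
      for (i in seq_along(net$blocks)) {
        net$blocks[[i]] <- apply_block_update(net$blocks[[i]],
                                              grads$blocks[[i]], lr)
      }

      if ((t + 1L) %% config$eval_interval == 0L ||
          (t + 1L) == config$max_iter) {
        test_loss <- NA_real_
        test_acc <- NA_real_
        if (!is.null(x_test)) {
          tf <- network_features(net, x_test, mode = "infer")
          tfeats <- cbind(tf$features, bias = 1)
          test_loss <- cs_cross_entropy(net$head, tfeats,
                                        as.integer(test_labels), cost)
          pred <- max.col(softmax_probs(net$head, tfeats)) - 1L
          test_acc <- mean(pred == as.integer(test_labels))
        }
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          iteration = t + 1L, lr = lr, train_loss = loss,
          test_loss = test_loss, test_accuracy = test_acc
        )
      }
    }
    structure(list(net = net, log = dplyr::bind_rows(log_rows),
                   cost = cost, config = config),
              class = "cs_net_fit")
  })
}

#' Predict from a fitted residual network
#'
#' @param object A `cs_net_fit`.
#' @param newdata List of matrices or 4-D tensor.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return Probability tibble or 0-based label vector.
#' @export
predict.cs_net_fit <- function(object, newdata,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_tensor(newdata)
  tf <- network_features(object$net, x, mode = "infer")
  feats <- cbind(tf$features, bias = 1)
  p <- softmax_probs(object$net$head, feats)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (type == "class") return(max.col(p) - 1L)
  colnames(p) <- paste0("p", seq_len(ncol(p)) - 1L)
  tibble::as_tibble(p)
}

as_tensor <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  if (is.matrix(images)) images <- list(images)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
  x
}

#' Augment images by horizontal reflection and translation
#'
#' Each image is mirrored horizontally with probability 0.5 and shifted by
#' integer offsets drawn uniformly from `[-max_shift, max_shift]` in both
#' axes, with edge replication at the borders.
#'
#' @param images List of grayscale matrices.
#' @param flips Enable random horizontal mirroring.
#' @param max_shift Maximum absolute shift, pixels (below the image side).
#' @param seed Integer seed.
#' @return List of augmented matrices.
#' @export
augment_images <- function(images, flips = TRUE, max_shift = 2L, seed = 1L) {
  if (is.matrix(images)) images <- list(images)
  if (max_shift >= min(dim(images[[1]]))) {
    abort("`max_shift` must be below the image side")
  }
  with_seed(seed, {
    purrr::map(images, function(img) {
      if (flips && stats::runif(1) < 0.5) {
        img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
      }
      if (max_shift > 0L) {
        dx <- sample(-max_shift:max_shift, 1)
        dy <- sample(-max_shift:max_shift, 1)
        img <- crop_padded(img, 1 - dx, ncol(img) - dx,
                           1 - dy, nrow(img) - dy)
      }
      img
    })
  })
}
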