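#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort %||% .data
#' @useDynLib csresnet, .registration = TRUE
NULL

# Deterministic child seed for the i-th item under a single global seed, so
# that inserting or removing later items never changes earlier ones.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647) * 48271 + 12345 * i) %% 2147483647L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not_image <- function(image, arg = "image") {
  if (!is.matrix(image) || length(image) == 0L) {
    abort(sprintf("`%s` must be a non-empty 2-D numeric matrix", arg))
  }
  if (!all(is.finite(image))) {
    abort(sprintf("`%s` contains non-finite values", arg))
  }
  invisible(image)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Extract a sub-window [y0, y1] x [x0, x1] (1-based, inclusive) from `image`,
# replicating edge pixels where the window extends past the frame.
crop_padded <- function(image, x0, x1, y0, y1) {
  h <- nrow(image)
  w <- ncol(image)
  rows <- pmin(pmax(y0:y1, 1L), h)
  cols <- pmin(pmax(x0:x1, 1L), w)
  image[rows, cols, drop = FALSE]
}

# Bilinear resize of a 2-D matrix.
resize_bilinear <- function(image, out_size) {
  out <- EBImage::resize(image, w = out_size, h = out_size)
  matrix(as.numeric(out), nrow = out_size, ncol = out_size)
}
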