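#' Circle region of interest
#'
#' A detected (or ground-truth) lens circle. Coordinates are 1-based pixel
#' positions with `cx` the column (x) and `cy` the row (y); `score` is the
#' Hough accumulator support (number of supporting edge pixels).
#'
#' @param cx,cy Centre, pixels.
#' @param r Radius, pixels (`> 0`).
#' @param score Non-negative accumulator support.
#' @return An object of class `circle_roi`.
#' @export
circle_roi <- function(cx, cy, r, score = 0) {
  if (r <= 0) abort("circle radius must be positive")
  if (score < 0) abort("circle score must be non-negative")
  structure(list(cx = cx, cy = cy, r = r, score = score),
            class = "circle_roi")
}

#' Axis-aligned bounding box
#'
#' Half-open box `[x_min, x_max) x [y_min, y_max)` in pixel units.
#'
#' @param x_min,y_min,x_max,y_max Box edges; `x_max > x_min` and
#'   `y_max > y_min`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  if (!(x_max > x_min) || !(y_max > y_min)) {
    abort("degenerate bounding box: max edges must exceed min edges")
  }
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bounding_box")
}

#' Bounding box of a circle
#'
#' @param circle A [circle_roi()] (or list with `cx`, `cy`, `r`).
#' @return A [bounding_box()] enclosing the circle.
#' @export
circle_bbox <- function(circle) {
  bounding_box(circle$cx - circle$r, circle$cy - circle$r,
               circle$cx + circle$r, circle$cy + circle$r)
}

#' Intersection over union of two boxes
#'
#' `area(intersection) / area(union)`; 0 for disjoint boxes.
#'
#' @param box_p,box_gt [bounding_box()] objects (prediction, ground truth).
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(box_p, box_gt) {
  for (b in list(box_p, box_gt)) {
    if (!(b$x_max > b$x_min) || !(b$y_max > b$y_min)) {
      abort("degenerate bounding box")
    }
  }
  ix <- max(0, min(box_p$x_max, box_gt$x_max) - max(box_p$x_min, box_gt$x_min))
  iy <- max(0, min(box_p$y_max, box_gt$y_max) - max(box_p$y_min, box_gt$y_min))
  inter <- ix * iy
  area_p <- (box_p$x_max - box_p$x_min) * (box_p$y_max - box_p$y_min)
  area_gt <- (box_gt$x_max - box_gt$x_min) * (box_gt$y_max - box_gt$y_min)
  inter / (area_p + area_gt - inter)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis linking (weak edges are kept
#' only in connected components that contain a strong edge). Thresholds
#' default to quantiles of the non-zero gradient magnitude, which is robust
#' to exposure differences between images.
#'
#' @param image 2-D numeric matrix (rows = y, columns = x).
#' @param low_threshold,high_threshold Absolute hysteresis thresholds on
#'   gradient magnitude; `0 <= low < high`. When `NULL`, derived from
#'   `low_quantile` / `high_quantile`.
#' @param smoothing_sd Gaussian pre-smoothing standard deviation, pixels.
#' @param low_quantile,high_quantile Quantiles of the non-zero gradient
#'   magnitude used when absolute thresholds are not given.
#' @return Logical matrix of edge pixels, same shape as `image`.
#' @export
canny_edges <- function(image, low_threshold = NULL, high_threshold = NULL,
                        smoothing_sd = 2, low_quantile = 0.7,
                        high_quantile = 0.9) {
  stop_if_not_image(image)
  if (!is.null(low_threshold) && !is.null(high_threshold)) {
    if (low_threshold < 0 || low_threshold >= high_threshold) {
      abort("need 0 <= low_threshold < high_threshold")
    }
  }
  img <- image
  if (smoothing_sd > 0) {
    img <- EBImage::gblur(image, sigma = smoothing_sd)
  }
  sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(img, sobel_x, boundary = "replicate")  # d/dx (cols)
  gy <- EBImage::filter2(img, t(sobel_x), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)

  nz <- mag[mag > 1e-12]
  if (length(nz) == 0L) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (is.null(high_threshold)) {
    high_threshold <- stats::quantile(nz, high_quantile, names = FALSE)
  }
  if (is.null(low_threshold)) {
    low_threshold <- stats::quantile(nz, low_quantile, names = FALSE)
  }
  if (low_threshold >= high_threshold) {
    low_threshold <- 0.5 * high_threshold
  }

  # Non-maximum suppression: keep pixels that are local maxima of `mag`
  # along the gradient direction quantized to {0, 45, 90, 135} degrees.
  h <- nrow(mag)
  w <- ncol(mag)
  ang <- atan2(gy, gx)                     # (-pi, pi]
  ang <- (ang + pi) %% pi                  # direction modulo 180 deg
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE

  shift_mat <- function(m, dy, dx) {
    out <- matrix(0, h, w)
    ys <- seq_len(h) + dy
    xs <- seq_len(w) + dx
    ok_y <- ys >= 1 & ys <= h
    ok_x <- xs >= 1 & xs <= w
    out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  # Neighbour offsets (dy, dx) per sector, along the gradient direction.
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nms <- matrix(FALSE, h, w)
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- shift_mat(mag, o[1], o[2])
    n2 <- shift_mat(mag, -o[1], -o[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }

  strong <- nms & mag >= high_threshold
  weak <- nms & mag >= low_threshold
  if (!any(strong)) {
    return(matrix(FALSE, h, w))
  }
  labels <- EBImage::bwlabel(weak)
  keep <- unique(labels[strong])
  keep <- keep[keep > 0]
  matrix(labels %in% keep, h, w)
}

#' Hough circle transform
#'
#' Accumulates votes from edge pixels over a radius grid; every edge pixel
#' votes for each candidate centre at distance `r` (offsets deduplicated per
#' radius, so a peak's score approximates the number of edge pixels on the
#' circle). Candidate circles are ranked by descending score; ties break
#' toward the larger radius, then the smaller `(cy, cx)`.
#'
#' @param edge_map Logical/numeric matrix of edge pixels.
#' @param r_min,r_max Radius search bounds, pixels; `r_min >= 3`,
#'   `r_max > r_min`, `r_max` below half the shorter image side.
#' @param n_candidates Maximum number of circles to return.
#' @param r_step Radius grid step, pixels.
#' @param min_score Minimum accumulator support for a candidate.
#' @return A list of [circle_roi()] sorted by non-increasing score; empty
#'   when the edge map has no edges or no candidate reaches `min_score`.
#' @export
hough_circle <- function(edge_map, r_min, r_max, n_candidates = 3,
                         r_step = 1, min_score = 8) {
  if (!is.matrix(edge_map)) abort("`edge_map` must be a matrix")
  r_min <- as.integer(round(r_min))
  r_max <- as.integer(round(r_max))
  if (r_min < 3L) abort("`r_min` must be >= 3")
  if (r_max <= r_min) abort("`r_max` must exceed `r_min`")
  if (r_max >= min(dim(edge_map)) / 2) {
    abort("`r_max` must be below half the shorter image side")
  }
  idx <- which(edge_map != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  radii <- as.integer(seq(r_min, r_max, by = r_step))
  acc <- hough_accumulate_cpp(
    edge_x = as.integer(idx[, 2] - 1L),
    edge_y = as.integer(idx[, 1] - 1L),
    width = ncol(edge_map), height = nrow(edge_map),
    radii = radii
  )
  h <- dim(acc)[1]
  w <- dim(acc)[2]

  # Only cells within striking distance of the global peak can rank; this
  # keeps the sort cheap without changing the top candidates.
  thr <- max(min_score, ceiling(0.5 * max(acc)))
  ord <- which(acc >= thr)
  if (length(ord) == 0L) return(list())
  votes <- acc[ord]
  coord <- arrayInd(ord, dim(acc))
  cy <- coord[, 1]
  cx <- coord[, 2]
  rr <- radii[coord[, 3]]
  o <- order(-votes, -rr, cy, cx)
  cy <- cy[o]; cx <- cx[o]; rr <- rr[o]; votes <- votes[o]

  out <- list()
  for (i in seq_along(votes)) {
    if (length(out) >= n_candidates) break
    # Suppress candidates whose centre falls near an already-accepted one.
    clash <- FALSE
    for (c0 in out) {
      if ((cx[i] - c0$cx)^2 + (cy[i] - c0$cy)^2 < (0.5 * c0$r)^2) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      out[[length(out) + 1L]] <- circle_roi(cx = cx[i], cy = cy[i],
                                            r = rr[i], score = votes[i])
    }
  }
  out
}

#' Configuration for lens localization
#'
#' @param out_size Side of the final square crop, pixels (128 retains the
#'   whole pupil while excluding most surrounding noise).
#' @param smoothing_sd,low_quantile,high_quantile Canny parameters, see
#'   [canny_edges()].
#' @param r_bounds_frac Coarse-pass Hough radius bounds as fractions of the
#'   shorter image side.
#' @param r_step_coarse,r_step_fine Radius grid steps for the two passes.
#' @param crop_pad Padding added around the detected circle, as a fraction
#'   of its radius.
#' @param two_pass Refine with a second Canny+Hough pass inside the coarse
#'   crop (the twice-applied procedure); `FALSE` runs a single pass.
#' @param min_score Minimum Hough support for a detection.
#' @return A list of class `localize_config`.
#' @export
localize_config <- function(out_size = 128,
                            smoothing_sd = 2,
                            low_quantile = 0.7,
                            high_quantile = 0.9,
                            r_bounds_frac = c(0.15, 0.45),
                            r_step_coarse = 2,
                            r_step_fine = 1,
                            crop_pad = 0.15,
                            two_pass = TRUE,
                            min_score = 8) {
  structure(
    list(out_size = as.integer(out_size), smoothing_sd = smoothing_sd,
         low_quantile = low_quantile, high_quantile = high_quantile,
         r_bounds_frac = r_bounds_frac, r_step_coarse = r_step_coarse,
         r_step_fine = r_step_fine, crop_pad = crop_pad,
         two_pass = isTRUE(two_pass), min_score = min_score),
    class = "localize_config"
  )
}

localization_failed <- function(pass) {
  abort(sprintf("localization failed in pass %d", pass),
        class = "csresnet_localization_failed", pass = pass)
}

#' Localize the crystalline lens by twice-applied Canny + Hough
#'
#' Pass 1 detects a coarse circle on the full image; a padded square around
#' it is cropped and pass 2 re-runs Canny + Hough inside the crop to refine
#' the centre and radius. The refined circle's padded bounding square is
#' cropped (edge-replicated at frame borders) and resized bilinearly to
#' `config$out_size`.
#'
#' @param image 2-D numeric matrix, at least 64 x 64.
#' @param config A [localize_config()].
#' @return A list with `circle` (refined [circle_roi()] in original-image
#'   coordinates) and `crop` (`out_size` x `out_size` matrix).
#' @export
localize_lens <- function(image, config = localize_config()) {
  stop_if_not_image(image)
  if (min(dim(image)) < 64L) abort("image must be at least 64 x 64")
  side <- min(dim(image))
  edges <- canny_edges(image, smoothing_sd = config$smoothing_sd,
                       low_quantile = config$low_quantile,
                       high_quantile = config$high_quantile)
  cand <- hough_circle(edges,
                       r_min = max(3, config$r_bounds_frac[1] * side),
                       r_max = config$r_bounds_frac[2] * side,
                       n_candidates = 1, r_step = config$r_step_coarse,
                       min_score = config$min_score)
  if (length(cand) == 0L) localization_failed(1L)
  coarse <- cand[[1]]

  refined <- coarse
  if (config$two_pass) {
    pad <- 1 + 2 * config$crop_pad
    half <- ceiling(coarse$r * pad)
    x0 <- round(coarse$cx) - half
    y0 <- round(coarse$cy) - half
    sub <- crop_padded(image, x0, x0 + 2 * half, y0, y0 + 2 * half)
    sub_side <- min(dim(sub))
    r_lo <- max(3, 0.7 * coarse$r)
    r_hi <- min(1.25 * coarse$r, sub_side / 2 - 1)
    sub_edges <- canny_edges(sub, smoothing_sd = config$smoothing_sd,
                             low_quantile = config$low_quantile,
                             high_quantile = config$high_quantile)
    cand2 <- hough_circle(sub_edges, r_min = r_lo, r_max = r_hi,
                          n_candidates = 1, r_step = config$r_step_fine,
                          min_score = config$min_score)
    if (length(cand2) == 0L) localization_failed(2L)
    fine <- cand2[[1]]
    refined <- circle_roi(cx = fine$cx + x0 - 1, cy = fine$cy + y0 - 1,
                          r = fine$r, score = fine$score)
  }

  half_out <- ceiling(refined$r * (1 + config$crop_pad))
  cx0 <- round(refined$cx)
  cy0 <- round(refined$cy)
  crop <- crop_padded(image, cx0 - half_out, cx0 + half_out,
                      cy0 - half_out, cy0 + half_out)
  crop <- resize_bilinear(crop, config$out_size)
  list(circle = refined, crop = crop)
}

#' Score localizations against ground truth by mean IoU
#'
#' Failed localizations (`NA` prediction entries) count as IoU 0.
#'
#' @param predictions List of [circle_roi()] (or `NA` for failures), or a
#'   tibble with columns `cx`, `cy`, `r`.
#' @param ground_truth List of [bounding_box()] or [circle_roi()] objects,
#'   or a tibble with columns `cx`, `cy`, `r`.
#' @return A list with `mean_iou` and `per_sample` (tibble with an `iou`
#'   column).
#' @export
evaluate_localization <- function(predictions, ground_truth) {
  as_box_list <- function(obj) {
    if (is.data.frame(obj)) {
      obj <- purrr::pmap(obj[c("cx", "cy", "r")], circle_roi)
    }
    purrr::map(obj, function(el) {
      if (length(el) == 1L && is.na(el[[1]])) return(NA)
      if (inherits(el, "bounding_box")) el else circle_bbox(el)
    })
  }
  p <- as_box_list(predictions)
  g <- as_box_list(ground_truth)
  if (length(p) != length(g)) {
    abort("`predictions` and `ground_truth` must have equal length")
  }
  ious <- purrr::map2_dbl(p, g, function(bp, bg) {
    if (length(bp) == 1L && is.na(bp[[1]])) 0 else iou(bp, bg)
  })
  list(mean_iou = mean(ious),
       per_sample = tibble::tibble(sample = seq_along(ious), iou = ious))
}
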