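#' Parameters for one synthetic retro-illumination eye image
#'
#' Describes the geometry and photometry of a synthetic retro-illumination
#' image: a bright, near-circular pupil disc (the crystalline lens lit from
#' behind) on a darker iris/sclera background, optionally with a soft
#' distractor annulus and speckle outside the pupil, and dark opacity lesions
#' inside the pupil. Lesions model posterior capsular opacification; an image
#' is labelled positive (severe) when the fraction of the pupil covered by
#' lesions exceeds `severity_threshold`.
#'
#' @param image_size Side of the square image, pixels.
#' @param pupil_center Numeric `(x, y)` in pixels (1-based column, row).
#'   Default: image centre.
#' @param pupil_radius Pupil radius in pixels. Default: `0.28 * image_size`.
#' @param pupil_intensity,background_intensity Gray levels in `[0, 1]`.
#' @param lesion_count Number of opacity lesions to paint inside the pupil.
#' @param lesion_radius_range Length-2 vector, lesion radii in pixels.
#' @param lesion_contrast Gray-level drop of a lesion relative to the pupil.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param distractor_ring Paint a soft iris-like annulus plus speckle blobs
#'   outside the pupil, emulating the structured noise that surrounds the
#'   lens in real images.
#' @param severity_threshold Lesion-area fraction of the pupil above which
#'   the image is labelled positive. The clinical labels this emulates come
#'   from ophthalmologist grading; the area rule is a configurable surrogate.
#'
#' @return An object of class `eye_image_params`.
#' @export
eye_image_params <- function(image_size = 256,
                             pupil_center = NULL,
                             pupil_radius = NULL,
                             pupil_intensity = 0.85,
                             background_intensity = 0.2,
                             lesion_count = 0,
                             lesion_radius_range = NULL,
                             lesion_contrast = 0.35,
                             noise_sd = 0.02,
                             distractor_ring = TRUE,
                             severity_threshold = 0.1) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) abort("`image_size` must be at least 32 pixels")
  pupil_radius <- pupil_radius %||% (0.28 * image_size)
  pupil_center <- pupil_center %||% c(image_size / 2, image_size / 2)
  lesion_radius_range <- lesion_radius_range %||%
    (c(0.08, 0.2) * pupil_radius)
  ints <- c(pupil_intensity, background_intensity)
  if (any(ints < 0 | ints > 1)) abort("intensities must lie in [0, 1]")
  if (pupil_radius <= 0) abort("`pupil_radius` must be positive")
  if (pupil_center[1] - pupil_radius < 1 ||
      pupil_center[1] + pupil_radius > image_size ||
      pupil_center[2] - pupil_radius < 1 ||
      pupil_center[2] + pupil_radius > image_size) {
    abort("pupil disc must lie fully inside the image frame")
  }
  if (lesion_count < 0) abort("`lesion_count` must be >= 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(
    list(
      image_size = image_size,
      pupil_center = as.numeric(pupil_center),
      pupil_radius = as.numeric(pupil_radius),
      pupil_intensity = pupil_intensity,
      background_intensity = background_intensity,
      lesion_count = as.integer(lesion_count),
      lesion_radius_range = as.numeric(lesion_radius_range),
      lesion_contrast = lesion_contrast,
      noise_sd = noise_sd,
      distractor_ring = isTRUE(distractor_ring),
      severity_threshold = severity_threshold
    ),
    class = "eye_image_params"
  )
}

#' Generate one synthetic retro-illumination image
#'
#' Renders the image described by `params` and derives its severity label
#' from the painted lesion mask: label 1 (positive) when lesion pixels cover
#' more than `severity_threshold` of the pupil disc.
#'
#' @param params An [eye_image_params()] object.
#' @param seed Integer seed; the same seed reproduces the image bit for bit.
#' @return A list with `image` (matrix in `[0, 1]`, rows = y, columns = x),
#'   `circle` (a [circle_roi()] with the true pupil geometry), `label`
#'   (0/1) and `lesion_fraction`.
#' @export
generate_eye_image <- function(params, seed = 1L) {
  if (!inherits(params, "eye_image_params")) {
    abort("`params` must be created by eye_image_params()")
  }
  with_seed(seed, {
    n <- params$image_size
    cx <- params$pupil_center[1]
    cy <- params$pupil_center[2]
    r <- params$pupil_radius
    xs <- matrix(seq_len(n), n, n, byrow = TRUE)   # column index = x
    ys <- matrix(seq_len(n), n, n)                 # row index = y
    d2 <- (xs - cx)^2 + (ys - cy)^2
    pupil <- d2 <= r^2

    img <- matrix(params$background_intensity, n, n)

    if (params$distractor_ring) {
      # Soft iris annulus: smooth radial profile, no sharp circular edge.
      dd <- sqrt(d2)
      ring <- 0.18 * exp(-((dd - 1.35 * r) / (0.25 * r))^2)
      img <- img + ring * (dd > r)
      # Scattered speckle blobs outside the pupil (sclera texture).
      n_blob <- rpois(1, 12)
      for (b in seq_len(n_blob)) {
        bx <- runif(1, 1, n)
        by <- runif(1, 1, n)
        if ((bx - cx)^2 + (by - cy)^2 <= (1.1 * r)^2) next
        br <- runif(1, 2, 6)
        blob <- (xs - bx)^2 + (ys - by)^2 <= br^2
        img[blob & !pupil] <- img[blob & !pupil] + runif(1, -0.1, 0.15)
      }
    }

    img[pupil] <- params$pupil_intensity

    lesion_mask <- matrix(FALSE, n, n)
    if (params$lesion_count > 0L) {
      for (l in seq_len(params$lesion_count)) {
        # Lesion centre uniform in the pupil disc.
        u <- runif(1)
        ang <- runif(1, 0, 2 * pi)
        lr <- runif(1, params$lesion_radius_range[1],
                    params$lesion_radius_range[2])
        rad <- sqrt(u) * max(r - lr, 0)
        lx <- cx + rad * cos(ang)
        ly <- cy + rad * sin(ang)
        lesion_mask <- lesion_mask | ((xs - lx)^2 + (ys - ly)^2 <= lr^2)
      }
      lesion_mask <- lesion_mask & pupil
      img[lesion_mask] <- img[lesion_mask] - params$lesion_contrast
    }

    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, 0, params$noise_sd), n, n)
    }
    img <- clip01(img)

    lesion_fraction <- sum(lesion_mask) / sum(pupil)
    label <- as.integer(lesion_fraction > params$severity_threshold)
    list(
      image = img,
      circle = circle_roi(cx = cx, cy = cy, r = r),
      label = label,
      lesion_fraction = lesion_fraction
    )
  })
}

# Draw per-image parameters that will realize the requested label.
sample_params_for_label <- function(label, base) {
  size <- base$image_size
  r <- runif(1, 0.2, 0.33) * size
  margin <- 1.05 * r + 2
  cx <- runif(1, margin, size - margin)
  cy <- runif(1, margin, size - margin)
  if (label == 1L) {
    lesion_count <- sample(3:6, 1)
    lesion_radius_range <- c(0.22, 0.34) * r
  } else {
    # Few small lesions (possibly none), safely below the severity threshold.
    lesion_count <- sample(0:2, 1)
    lesion_radius_range <- c(0.04, 0.1) * r
  }
  eye_image_params(
    image_size = size,
    pupil_center = c(cx, cy),
    pupil_radius = r,
    pupil_intensity = base$pupil_intensity,
    background_intensity = base$background_intensity,
    lesion_count = lesion_count,
    lesion_radius_range = lesion_radius_range,
    lesion_contrast = base$lesion_contrast,
    noise_sd = base$noise_sd,
    distractor_ring = base$distractor_ring,
    severity_threshold = base$severity_threshold
  )
}

#' Generate a labelled synthetic eye-image dataset
#'
#' Produces exactly `n_pos` positive (severe, minority-class) and `n_neg`
#' negative images with known pupil geometry, shuffled deterministically by
#' `seed`. Each image gets its own RNG substream derived from `seed`, so the
#' i-th image does not depend on how many images follow it. Positive images
#' receive larger/multiple lesions until the painted lesion area exceeds the
#' severity threshold; images are re-drawn (fresh substream) in the rare case
#' the realized label misses the request.
#'
#' @param n_pos,n_neg Number of positive / negative images (`>= 0`). The
#'   class imbalance this emulates is 735 positive vs 1970 negative.
#' @param params Base [eye_image_params()]; per-image pupil geometry and
#'   lesion load are drawn around it.
#' @param seed Integer seed.
#' @return A tibble with list-column `image` and columns `label`, `cx`,
#'   `cy`, `r`, `lesion_fraction`.
#' @export
generate_eye_dataset <- function(n_pos, n_neg,
                                 params = eye_image_params(),
                                 seed = 1L) {
  if (n_pos < 0 || n_neg < 0) abort("`n_pos` and `n_neg` must be >= 0")
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  labels_wanted <- rep(c(1L, 0L), c(n_pos, n_neg))
  rows <- purrr::map(seq_along(labels_wanted), function(i) {
    want <- labels_wanted[i]
    for (attempt in 0:9) {
      s <- child_seed(seed, i * 10L + attempt)
      draw <- with_seed(s, sample_params_for_label(want, params))
      out <- generate_eye_image(draw, seed = s + 1L)
      if (out$label == want) {
        return(tibble::tibble(
          image = list(out$image),
          label = out$label,
          cx = out$circle$cx,
          cy = out$circle$cy,
          r = out$circle$r,
          lesion_fraction = out$lesion_fraction
        ))
      }
    }
    abort("could not realize requested label after 10 attempts")
  })
  data <- dplyr::bind_rows(rows)
  perm <- with_seed(child_seed(seed, 0L), sample.int(nrow(data)))
  if (nrow(data) > 0L) data <- data[perm, ]
  data
}

#' Generate a two-class Gaussian feature dataset
#'
#' Fast tabular substrate for testing the cost-sensitive loss, optimizer and
#' resamplers without rendering images: two spherical unit-variance Gaussian
#' classes in `dim` dimensions whose means differ by `class_separation`
#' along the first axis. Label 1 is the positive/minority class.
#'
#' @param n_pos,n_neg Class sizes.
#' @param dim Feature dimension (`>= 1`).
#' @param class_separation Euclidean distance between class means (`>= 0`).
#' @param seed Integer seed.
#' @return A tibble with columns `x1 ... x<dim>` and `label` (0/1).
#' @export
generate_feature_dataset <- function(n_pos, n_neg, dim = 2,
                                     class_separation = 2, seed = 1L) {
  if (dim < 1) abort("`dim` must be >= 1")
  if (class_separation < 0) abort("`class_separation` must be >= 0")
  if (n_pos < 0 || n_neg < 0) abort("class sizes must be >= 0")
  with_seed(seed, {
    n <- n_pos + n_neg
    x <- matrix(rnorm(n * dim), n, dim)
    labels <- rep(c(1L, 0L), c(n_pos, n_neg))
    x[labels == 1L, 1] <- x[labels == 1L, 1] + class_separation
    perm <- sample.int(n)
    x <- x[perm, , drop = FALSE]
    labels <- labels[perm]
    out <- tibble::as_tibble(as.data.frame(x),
                             .name_repair = ~ paste0("x", seq_len(dim)))
    out$label <- labels
    out
  })
}

#' Write a synthetic eye dataset to disk
#'
#' Writes each image as an 8-bit grayscale PNG plus a `manifest.csv` with
#' columns `filename,label,cx,cy,r`.
#'
#' @param data Tibble from [generate_eye_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_eye_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  filenames <- sprintf("eye_%04d.png", seq_len(nrow(data)))
  purrr::walk2(data$image, filenames, function(img, f) {
    png::writePNG(clip01(img), file.path(dir, f))
  })
  manifest <- tibble::tibble(
    filename = filenames,
    label = data$label,
    cx = data$cx, cy = data$cy, r = data$r
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a synthetic eye dataset back from a manifest
#'
#' @param dir Directory containing `manifest.csv` and the PNG files.
#' @return A tibble with list-column `image` and columns `label,cx,cy,r`.
#' @export
read_eye_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) abort(sprintf("no manifest.csv under %s", dir))
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  images <- purrr::map(manifest$filename, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  tibble::tibble(
    image = images,
    label = as.integer(manifest$label),
    cx = manifest$cx, cy = manifest$cy, r = manifest$r
  )
}
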