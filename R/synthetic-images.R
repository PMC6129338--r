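#' Synthetic skin-image generation
#'
#' Builds labelled synthetic skin images with exact ground truth so that
#' every downstream stage (filtering, rotation, vertical segmentation,
#' texture statistics, lesion-area recovery, classification) can be
#' exercised and scored without clinical photographs. Each image contains
#' an elongated bright "epithelium" (a rotated super-ellipse of skin-toned
#' pixels) on a dark background; disease classes paint a textured circular
#' lesion inside it, and salt-and-pepper noise is applied last.
#'
#' @name synthetic-images
NULL

SYNTH_CLASSES <- c("normal", "herpes", "paederus_dermatitis", "psoriasis")
DISEASE_CLASSES <- c("herpes", "paederus_dermatitis", "psoriasis")

# Chromatic direction of each tissue type: RGB = luminance-field * hue / lum,
# where lum is the Rec.601 luminance of the hue vector, so the generated
# grayscale luminance equals the designed luminance field (up to clipping).
HUE_SKIN   <- c(1.00, 0.82, 0.70)
HUE_LESION <- c(1.00, 0.55, 0.50)

#' Default texture parameters per class
#'
#' The three disease textures are designed so their lesion-region GLCM
#' contrast ranges are pairwise disjoint, mirroring the qualitative class
#' separation of reported clinical texture tables: herpes lesions are
#' high-contrast coarse speckle (dark vesicles on an erythematous base),
#' paederus dermatitis is a dense fine grain of intermediate contrast, and
#' psoriasis is coarse two-tone plaque/scale patches of low contrast.
#'
#' @param class_label one of `"normal"`, `"herpes"`, `"paederus_dermatitis"`,
#'   `"psoriasis"`.
#' @return a list with elements `base_gray` (mean lesion luminance),
#'   `amplitude` (texture modulation, gray levels), `spot_density`
#'   (fraction of lesion area covered by speckle spots, herpes only) and
#'   `patch_sigma` (Gaussian smoothing scale of the patch field in px,
#'   psoriasis only).
#' @export
default_texture_params <- function(class_label) {
  switch(class_label,
    normal = list(base_gray = 0, amplitude = 0, spot_density = 0, patch_sigma = 0),
    herpes = list(base_gray = 125, amplitude = 90, spot_density = 0.30, patch_sigma = 0),
    paederus_dermatitis = list(base_gray = 120, amplitude = 40, spot_density = 0, patch_sigma = 0),
    psoriasis = list(base_gray = 125, amplitude = 28, spot_density = 0, patch_sigma = 6),
    stop("unknown class_label: ", class_label)
  )
}

# Default lesion radii (px on a 256x256 canvas); ordered so mean pixel area
# obeys psoriasis > herpes > paederus dermatitis.
default_lesion_radius <- function(class_label) {
  switch(class_label,
    normal = 0, herpes = 40, paederus_dermatitis = 25, psoriasis = 60,
    stop("unknown class_label: ", class_label)
  )
}

#' Specification of one synthetic skin image
#'
#' @param class_label tissue class; one of `"normal"`, `"herpes"`,
#'   `"paederus_dermatitis"`, `"psoriasis"`.
#' @param image_size integer `(height, width)` in px; each >= 32.
#' @param lesion_radius_px lesion disk radius in px; must be smaller than
#'   half the smaller image dimension. Ignored (forced 0) for `"normal"`.
#' @param texture_params list as produced by [default_texture_params()];
#'   `NULL` selects the class default.
#' @param noise_fraction fraction in \[0, 1\] of pixels corrupted by
#'   salt-and-pepper noise (applied after the scene is painted).
#' @param orientation_deg orientation of the epithelium's long axis,
#'   degrees; 0 = horizontal.
#' @param seed integer RNG seed; identical specs (including seed) produce
#'   bit-identical images.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(class_label,
                       image_size = c(256L, 256L),
                       lesion_radius_px = default_lesion_radius(class_label),
                       texture_params = NULL,
                       noise_fraction = 0,
                       orientation_deg = 0,
                       seed = 1L) {
  class_label <- match.arg(class_label, SYNTH_CLASSES)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 32L))
    stop("invalid `image_size`: need (height, width), each >= 32")
  if (class_label == "normal") lesion_radius_px <- 0
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction > 1)
    stop("invalid `noise_fraction`: must lie in [0, 1]")
  if (class_label != "normal") {
    if (!is.numeric(lesion_radius_px) || lesion_radius_px <= 0)
      stop("invalid `lesion_radius_px`: must be positive for disease classes")
    if (lesion_radius_px >= min(image_size) / 2)
      stop("invalid `lesion_radius_px`: must be < min(image_size)/2")
  }
  if (!is.numeric(orientation_deg) || !is.finite(orientation_deg))
    stop("invalid `orientation_deg`: must be finite")
  if (is.null(texture_params)) texture_params <- default_texture_params(class_label)
  structure(list(
    class_label = class_label,
    image_size = image_size,
    lesion_radius_px = lesion_radius_px,
    texture_params = texture_params,
    noise_fraction = noise_fraction,
    orientation_deg = orientation_deg,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

# Luminance field of the lesion texture on the pixels of `disk` (logical
# matrix); returns a matrix aligned with the image, defined inside the disk.
lesion_luminance <- function(spec, disk) {
  p <- spec$texture_params
  h <- nrow(disk); w <- ncol(disk)
  lum <- matrix(p$base_gray, h, w)
  idx <- which(disk)
  n_in <- length(idx)
  if (n_in == 0L) return(lum)
  cl <- spec$class_label
  if (cl == "herpes") {
    # dark vesicular speckle: small disks of radius 1-2 px covering
    # ~spot_density of the lesion area, each base_gray - amplitude
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    n_spots <- max(1L, round(p$spot_density * n_in / (pi * 1.5^2)))
    ctr <- sample.int(n_in, n_spots, replace = TRUE)
    rad <- sample(1:2, n_spots, replace = TRUE)
    spot <- matrix(FALSE, h, w)
    for (k in seq_len(n_spots)) {
      r0 <- rows[ctr[k]]; c0 <- cols[ctr[k]]; rd <- rad[k]
      rr <- max(1L, r0 - rd):min(h, r0 + rd)
      cc <- max(1L, c0 - rd):min(w, c0 + rd)
      dd <- outer((rr - r0)^2, (cc - c0)^2, "+") <= rd^2
      spot[rr, cc] <- spot[rr, cc] | dd
    }
    lum[spot] <- p$base_gray - p$amplitude
  } else if (cl == "paederus_dermatitis") {
    # dense fine grain: iid uniform modulation, pixel-scale correlation
    lum[idx] <- p$base_gray + runif(n_in, -p$amplitude, p$amplitude)
  } else if (cl == "psoriasis") {
    # coarse plaque/scale patches: thresholded smoothed noise, two tones
    field <- matrix(rnorm(h * w), h, w)
    field <- from_ebimage(EBImage::gblur(as_ebimage(field, 1), sigma = p$patch_sigma), 1)
    hi <- field > stats::median(field[idx])
    lum[idx] <- ifelse(hi[idx], p$base_gray + p$amplitude, p$base_gray - p$amplitude)
  }
  lum
}

#' Generate one synthetic skin image with ground truth
#'
#' Paints a skin-toned super-elliptical epithelium at `orientation_deg` on
#' a dark background; for disease classes, a textured circular lesion of
#' the requested radius is painted at the epithelium centre (clipped to the
#' epithelium). Salt-and-pepper noise is applied last. The scene is drawn
#' analytically in rotated coordinates, so no resampling is involved and
#' the lesion mask is an exact pixel disk.
#'
#' @param spec a [synth_spec()].
#' @return a list with `image` (`h x w x 3` array, \[0, 255\]) and
#'   `ground_truth`, itself a list with `label`, `lesion_mask` (logical
#'   matrix marking exactly the painted lesion pixels), `lesion_area_px`,
#'   and `foreground_mask` (the painted epithelium).
#' @export
generate_image <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop("`spec` must be a synth_spec object")
  with_local_seed(spec$seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    cy <- (h - 1) / 2; cx <- (w - 1) / 2
    phi <- spec$orientation_deg * pi / 180
    x <- matrix(rep(0:(w - 1), each = h), h, w) - cx
    y <- matrix(rep(0:(h - 1), times = w), h, w) - cy
    # coordinates along (u) / across (v) the epithelium's long axis
    u <- x * cos(phi) + y * sin(phi)
    v <- -x * sin(phi) + y * cos(phi)
    a <- 0.41 * w; b <- 0.19 * h
    fg <- (abs(u / a)^4 + abs(v / b)^4) <= 1

    # skin luminance: smooth base with gentle falloff plus mild grain
    base <- 150 - 18 * (abs(u / a)^2 + abs(v / b)^2) + rnorm(h * w, 0, 2.5)
    lum_bg <- 10 + rnorm(h * w, 0, 2)

    lesion <- matrix(FALSE, h, w)
    if (spec$class_label != "normal" && spec$lesion_radius_px > 0) {
      # lesion disk centred on the epithelium centre (rotation-invariant)
      lesion <- (x^2 + y^2) <= spec$lesion_radius_px^2
      lesion <- lesion & fg
    }

    img <- array(0, c(h, w, 3))
    lum_sk <- matrix(base, h, w)
    sk_scale <- HUE_SKIN / sum(c(0.299, 0.587, 0.114) * HUE_SKIN)
    bg_mat <- matrix(lum_bg, h, w)
    for (ch in 1:3) {
      plane <- bg_mat
      plane[fg] <- lum_sk[fg] * sk_scale[ch]
      img[, , ch] <- plane
    }
    if (any(lesion)) {
      lum_le <- lesion_luminance(spec, lesion)
      le_scale <- HUE_LESION / sum(c(0.299, 0.587, 0.114) * HUE_LESION)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[lesion] <- lum_le[lesion] * le_scale[ch]
        img[, , ch] <- plane
      }
    }
    img <- clamp255(img)

    if (spec$noise_fraction > 0) {
      n_noise <- round(spec$noise_fraction * h * w)
      if (n_noise > 0) {
        pix <- sample.int(h * w, n_noise)
        val <- sample(c(0, 255), n_noise, replace = TRUE)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[pix] <- val
          img[, , ch] <- plane
        }
      }
    }

    list(
      image = img,
      ground_truth = list(
        label = spec$class_label,
        lesion_mask = lesion,
        lesion_area_px = sum(lesion),
        foreground_mask = fg
      )
    )
  })
}

#' Generate a balanced labelled dataset of synthetic skin images
#'
#' Produces `n_per_class` images for each requested class with
#' class-default texture parameters, lesion radii jittered around the
#' class default (preserving the ordering psoriasis > herpes > paederus
#' dermatitis in expectation) and per-image random orientations.
#'
#' @param n_per_class images per class; >= 1.
#' @param classes character vector of classes to generate; defaults to the
#'   three disease classes.
#' @param image_size `(height, width)` px.
#' @param noise_fraction salt-and-pepper fraction applied to every image.
#' @param seed master RNG seed; per-image seeds are derived from it, so
#'   the whole dataset is reproducible.
#' @return a list of length `n_per_class * length(classes)`; each element
#'   is the result of [generate_image()] (image + ground truth).
#' @export
generate_dataset <- function(n_per_class,
                             classes = DISEASE_CLASSES,
                             image_size = c(256L, 256L),
                             noise_fraction = 0.02,
                             seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("invalid `n_per_class`: must be >= 1")
  n_per_class <- as.integer(n_per_class)
  classes <- match.arg(classes, SYNTH_CLASSES, several.ok = TRUE)
  draws <- with_local_seed(seed, {
    lapply(seq_len(n_per_class * length(classes)), function(i) {
      list(seed = sample.int(2^31 - 1, 1),
           radius_jitter = runif(1, 0.9, 1.1),
           orient = runif(1, -30, 30))
    })
  })
  out <- vector("list", n_per_class * length(classes))
  i <- 0L
  for (cl in classes) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      r <- default_lesion_radius(cl) * draws[[i]]$radius_jitter
      sp <- synth_spec(cl,
        image_size = image_size,
        lesion_radius_px = if (cl == "normal") 0 else r,
        noise_fraction = noise_fraction,
        orientation_deg = draws[[i]]$orient,
        seed = draws[[i]]$seed)
      out[[i]] <- generate_image(sp)
    }
  }
  out
}
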