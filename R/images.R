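#' dermatex: texture and lesion-area based skin disease recognition
#'
#' Implements a full recognition pipeline for colour skin images:
#' median-filter denoising, rotation of the epithelium to the horizontal,
#' medial-axis based division into ten vertical regions, gray-level
#' co-occurrence matrix (GLCM) texture statistics, marker-controlled
#' watershed extraction of the lesion pixel area, and one-vs-one RBF-kernel
#' SVM classification of herpes vs. paederus dermatitis vs. psoriasis.
#' A synthetic-image generator with exact ground truth supports testing
#' and benchmarking without clinical images.
#'
#' Images are plain R structures throughout: a grayscale image is a numeric
#' matrix with intensities in \[0, 255\] (rows = image rows), a colour image
#' is a `height x width x 3` numeric array on the same scale, and a binary
#' mask is a logical matrix.
#'
#' @name dermatex-package
#' @keywords internal
"_PACKAGE"

#' Convert a colour image to grayscale luminance
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B, the standard
#' photometric reduction for 8-bit imagery.
#'
#' @param img a `height x width x 3` numeric array in \[0, 255\], or a
#'   numeric matrix (returned unchanged).
#' @return a numeric matrix in \[0, 255\].
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_gray_image <- function(img) {
  is.matrix(img) && is.numeric(img)
}

is_color_image <- function(img) {
  is.array(img) && !is.matrix(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

assert_image <- function(img, arg = "img") {
  if (!is_gray_image(img) && !is_color_image(img))
    stop(sprintf("`%s` must be a numeric matrix or a height x width x 3 array", arg))
  invisible(img)
}

#' Read an image file into the package's array convention
#'
#' Reads PNG (via the png package) or TIFF/JPEG via EBImage, returning
#' intensities on the \[0, 255\] scale. Grayscale files come back as a
#' matrix, colour files as a `height x width x 3` array (any alpha channel
#' is dropped).
#'
#' @param path file path.
#' @return numeric matrix or array in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    e <- EBImage::readImage(path)
    a <- if (length(dim(e)) == 2L) t(e@.Data) else aperm(e@.Data, c(2, 1, 3))
  }
  if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  a * 255
}

#' Write an image in the package's array convention to a PNG file
#'
#' @param img numeric matrix or `height x width x 3` array in \[0, 255\].
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  png::writePNG(clamp255(img) / 255, target = path)
  invisible(path)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}

# EBImage interop. EBImage stores images x-major; all operations used here
# (distance map, blur, morphology, watershed) commute with transposition,
# so matrices are passed through as-is and read back from @.Data.
as_ebimage <- function(m, scale = 255) EBImage::Image(m / scale)
from_ebimage <- function(e, scale = 255) e@.Data * scale
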