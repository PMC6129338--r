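#' Gray-level co-occurrence matrices and texture statistics
#'
#' A GLCM is an `L x L` table `G(i, j)` counting how often a pixel of
#' quantized level `i` co-occurs with a pixel of level `j` at a fixed
#' spatial offset. Five scalar statistics summarise the texture: contrast
#' (depth of the texture grooves), correlation (linear dependence of row
#' and column levels), entropy (information content), uniformity (inverse
#' difference moment, high for smooth texture) and energy (sum of squared
#' table entries, describing texture thickness).
#'
#' @name glcm
NULL

#' GLCM configuration
#'
#' @param levels number of gray-level quantization bins `L` (>= 2);
#'   intensities in \[0, 255\] are binned uniformly.
#' @param offsets integer matrix with columns `(dRow, dCol)`, one
#'   displacement per row; defaults to distance 1 at 0, 45, 90 and 135
#'   degrees, the standard orientation-averaged choice.
#' @param symmetric count each pair in both directions (default TRUE).
#' @param normalize divide by the pair total so entries sum to 1
#'   (default TRUE).
#' @param log_base base of the entropy logarithm, 2 or `exp(1)`.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L,
                        offsets = rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)),
                        symmetric = TRUE,
                        normalize = TRUE,
                        log_base = 2) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("invalid `levels`: need >= 2")
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (any(rowSums(abs(offsets)) == 0L)) stop("invalid `offsets`: zero offset")
  if (!log_base %in% c(2, exp(1))) stop("invalid `log_base`: must be 2 or exp(1)")
  structure(list(levels = levels, offsets = offsets, symmetric = symmetric,
                 normalize = normalize, log_base = log_base),
            class = "glcm_config")
}

# uniform quantization of [0,255] into L bins, returning levels 0..L-1
quantize_levels <- function(img, levels) {
  q <- floor(clamp255(img) * levels / 256)
  matrix(pmin(q, levels - 1L), nrow(img), ncol(img))
}

#' Compute a gray-level co-occurrence matrix
#'
#' Intensities are quantized to `cfg$levels` uniform bins of \[0, 255\];
#' `G(i, j)` accumulates ordered pixel pairs `(p, p + offset)` with both
#' endpoints inside `region` (or anywhere in the image when `region` is
#' NULL), over all configured offsets; the table is then symmetrized
#' and/or normalized per the configuration.
#'
#' @param img grayscale matrix in \[0, 255\].
#' @param region optional logical mask restricting both pair endpoints.
#' @param cfg a [glcm_config()].
#' @return an object of class `glcm`: list with `table` (L x L matrix),
#'   `config` and `total_pairs` (raw directed pair count).
#' @export
compute_glcm <- function(img, region = NULL, cfg = glcm_config()) {
  stopifnot(is.matrix(img))
  if (length(img) == 0L) stop("empty image")
  L <- cfg$levels
  q <- quantize_levels(img, L)
  h <- nrow(q); w <- ncol(q)
  if (is.null(region)) region <- matrix(TRUE, h, w)
  stopifnot(all(dim(region) == dim(img)))
  G <- matrix(0, L, L)
  total <- 0L
  for (k in seq_len(nrow(cfg$offsets))) {
    dr <- cfg$offsets[k, 1]; dc <- cfg$offsets[k, 2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    if (!length(r1) || !length(c1)) next
    ok <- region[r1, c1, drop = FALSE] & region[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    i <- q[r1, c1, drop = FALSE][ok]
    j <- q[r1 + dr, c1 + dc, drop = FALSE][ok]
    counts <- tabulate(i * L + j + 1L, nbins = L * L)
    G <- G + matrix(counts, L, L, byrow = TRUE)
    total <- total + length(i)
  }
  if (total == 0L) stop("region has no valid pixel pairs")
  if (cfg$symmetric) {
    G <- G + t(G)
    total <- 2L * total
  }
  if (cfg$normalize) G <- G / sum(G)
  structure(list(table = G, config = cfg, total_pairs = total), class = "glcm")
}

glcm_table <- function(g) if (inherits(g, "glcm")) g$table else g

#' GLCM contrast
#'
#' `sum_ij (i - j)^2 G(i, j)`: the mean squared level difference of
#' co-occurring pixels, describing the depth of the texture grooves.
#'
#' @param g a `glcm` object or a plain GLCM matrix.
#' @return non-negative scalar.
#' @export
glcm_contrast <- function(g) {
  G <- glcm_table(g)
  L <- nrow(G)
  d <- outer(0:(L - 1), 0:(L - 1), "-")
  sum(d * d * G)
}

#' GLCM correlation
#'
#' `sum_ij (i - mx)(j - my) G(i, j) / (sx sy)` with `mx, my, sx, sy` the
#' marginal means and standard deviations of the normalized table: the
#' linear dependence between co-occurring levels, in \[-1, 1\]. A table
#' with zero marginal spread (constant texture) has no defined linear
#' dependence; 0 is returned with a warning.
#'
#' @inheritParams glcm_contrast
#' @return scalar in \[-1, 1\] (0 with a warning for degenerate tables).
#' @export
glcm_correlation <- function(g) {
  G <- glcm_table(g)
  G <- G / sum(G)
  L <- nrow(G)
  lev <- 0:(L - 1)
  px <- rowSums(G); py <- colSums(G)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  if (sx < 1e-12 || sy < 1e-12) {
    warning("degenerate GLCM (zero marginal spread): correlation set to 0")
    return(0)
  }
  (sum(outer(lev, lev) * G) - mx * my) / (sx * sy)
}

#' GLCM entropy
#'
#' `-sum_ij G(i, j) log G(i, j)` with the convention `0 log 0 = 0`;
#' logarithm base from the configuration (2 for a `glcm` object built with
#' the default config, natural log optional). Zero entropy means a single
#' co-occurrence pattern, i.e. no texture.
#'
#' @inheritParams glcm_contrast
#' @param log_base logarithm base when `g` is a plain matrix; ignored for
#'   `glcm` objects (taken from their config).
#' @return non-negative scalar.
#' @export
glcm_entropy <- function(g, log_base = 2) {
  if (inherits(g, "glcm")) log_base <- g$config$log_base
  G <- glcm_table(g)
  nz <- G > 0
  -sum(G[nz] * log(G[nz], base = log_base))
}

#' GLCM uniformity (inverse difference moment)
#'
#' `sum_ij G(i, j) / ((i - j)^2 + 1)`: large when co-occurring levels are
#' similar, i.e. for smooth/rough-homogeneous texture.
#'
#' @inheritParams glcm_contrast
#' @return scalar in (0, 1\] for a normalized table.
#' @export
glcm_uniformity <- function(g) {
  G <- glcm_table(g)
  L <- nrow(G)
  d <- outer(0:(L - 1), 0:(L - 1), "-")
  sum(G / (d * d + 1))
}

#' GLCM energy
#'
#' `sum_ij G(i, j)^2`, computed on the table as configured: on the
#' probability-normalized table by default (values in (0, 1\]), or on raw
#' counts when the GLCM was built with `normalize = FALSE`, which yields
#' the large magnitudes sometimes reported for this statistic.
#'
#' @inheritParams glcm_contrast
#' @return non-negative scalar.
#' @export
glcm_energy <- function(g) {
  G <- glcm_table(g)
  sum(G * G)
}

#' All five texture statistics of a GLCM
#'
#' @inheritParams glcm_contrast
#' @return named numeric vector `contrast`, `correlation`, `entropy`,
#'   `uniformity`, `energy`.
#' @export
texture_features <- function(g) {
  c(contrast = glcm_contrast(g),
    correlation = suppressWarnings(glcm_correlation(g)),
    entropy = glcm_entropy(g),
    uniformity = glcm_uniformity(g),
    energy = glcm_energy(g))
}

#' Texture statistics for each of the ten vertical regions
#'
#' Computes a GLCM restricted to each region L1..L10 of the rotated image
#' and returns the five statistics per region. A region without any valid
#' pixel pair falls back to the whole-image statistics with a warning.
#'
#' @param img the rotated grayscale image the segments refer to.
#' @param segs a `vertical_segments` object from [split_ten_segments()].
#' @param cfg a [glcm_config()].
#' @return a 10 x 5 numeric matrix, rows L01..L10, columns the five
#'   statistics.
#' @export
features_for_segments <- function(img, segs, cfg = glcm_config()) {
  stopifnot(inherits(segs, "vertical_segments"))
  whole <- NULL
  out <- matrix(NA_real_, 10, 5,
                dimnames = list(names(segs$regions),
                                c("contrast", "correlation", "entropy",
                                  "uniformity", "energy")))
  for (k in 1:10) {
    feats <- tryCatch(
      texture_features(compute_glcm(img, segs$regions[[k]], cfg)),
      error = function(e) {
        warning(sprintf("region %d has no valid pixel pairs: using whole-image features", k))
        if (is.null(whole))
          whole <<- texture_features(compute_glcm(img, NULL, cfg))
        whole
      })
    out[k, ] <- feats
  }
  out
}
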