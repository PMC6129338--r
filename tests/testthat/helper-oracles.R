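# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive per-pixel / double-loop computation and share
# no code with the package internals.

# per-pixel sort-and-pick-middle median filter with edge replication
oracle_median_filter <- function(img, window = 3L) {
  h <- nrow(img); w <- ncol(img)
  k <- (window - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    vals <- numeric(0)
    for (dr in -k:k) for (dc in -k:k) {
      rr <- min(max(r + dr, 1L), h)
      cc <- min(max(c + dc, 1L), w)
      vals <- c(vals, img[rr, cc])
    }
    out[r, c] <- sort(vals)[(length(vals) + 1L) %/% 2L]
  }
  out
}

# exhaustive nearest-background-pixel search
oracle_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, h, w)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(out)
  for (i in seq_len(nrow(fg))) {
    r <- fg[i, 1]; c <- fg[i, 2]
    out[r, c] <- sqrt(min((r - bg[, 1])^2 + (c - bg[, 2])^2))
  }
  out
}

# naive directed pair counting over pixels and offsets
oracle_glcm <- function(img, region, levels, offsets, symmetric, normalize) {
  q <- floor(pmin(pmax(img, 0), 255) * levels / 256)
  q <- matrix(pmin(q, levels - 1L), nrow(img), ncol(img))
  h <- nrow(q); w <- ncol(q)
  if (is.null(region)) region <- matrix(TRUE, h, w)
  G <- matrix(0, levels, levels)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (r in 1:h) for (c in 1:w) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      if (!region[r, c] || !region[r2, c2]) next
      G[q[r, c] + 1L, q[r2, c2] + 1L] <- G[q[r, c] + 1L, q[r2, c2] + 1L] + 1
    }
  }
  if (symmetric) G <- G + t(G)
  if (normalize) G <- G / sum(G)
  G
}

# double-loop texture statistics on a GLCM table
oracle_features <- function(G, log_base = 2) {
  L <- nrow(G)
  P <- G / sum(G)
  ctr <- 0; ent <- 0; uni <- 0; ene <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    ctr <- ctr + (i - j)^2 * p
    if (p > 0) ent <- ent - p * log(p, base = log_base)
    uni <- uni + p / ((i - j)^2 + 1)
    ene <- ene + G[i + 1, j + 1]^2
  }
  mx <- 0; my <- 0
  for (i in 0:(L - 1)) { mx <- mx + i * sum(P[i + 1, ]); my <- my + i * sum(P[, i + 1]) }
  sx <- 0; sy <- 0; cov <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    sx <- sx + (i - mx)^2 * P[i + 1, j + 1]
    sy <- sy + (j - my)^2 * P[i + 1, j + 1]
    cov <- cov + (i - mx) * (j - my) * P[i + 1, j + 1]
  }
  corr <- if (sx > 0 && sy > 0) cov / sqrt(sx * sy) else 0
  c(contrast = ctr, correlation = corr, entropy = ent, uniformity = uni, energy = ene)
}

# preprocess a generated image and return its per-segment texture matrix
features_for_segments_of <- function(g) {
  pre <- preprocess_image(g$image)
  features_for_segments(pre$gray_rotated, pre$segments)
}

# random normalized GLCM for property tests
random_glcm <- function(L, seed) {
  set.seed(seed)
  G <- matrix(stats::rexp(L * L), L, L)
  G / sum(G)
}
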