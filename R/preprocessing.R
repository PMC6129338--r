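#' Image preprocessing: denoising, rotation and vertical segmentation
#'
#' The preprocessing chain takes a raw skin image to the representation
#' the texture stage consumes: median filtering removes salt-and-pepper
#' noise, the binarized epithelium's principal axis is estimated and the
#' image rotated so that axis is horizontal, the Euclidean distance
#' transform of the foreground yields the medial axis ("brightest pixel
#' line" of the distance map), and the epithelium is divided into ten
#' vertical regions of equal arclength along that axis.
#'
#' @name preprocessing
NULL

# replicate-pad a matrix by k pixels on every side
pad_replicate <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, k), 1:h, rep(h, k))
  ci <- c(rep(1L, k), 1:w, rep(w, k))
  m[ri, ci]
}

# vectorised 9-element median via the classic 19-exchange sorting network
median9 <- function(v) {
  p <- function(i, j) { lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]]); v[[i]] <<- lo; v[[j]] <<- hi }
  p(2, 3); p(5, 6); p(8, 9); p(1, 2); p(4, 5); p(7, 8); p(2, 3); p(5, 6)
  p(8, 9); p(1, 4); p(6, 9); p(5, 8); p(4, 7); p(2, 5); p(3, 6); p(5, 8)
  p(5, 3); p(7, 5); p(5, 3)
  v[[5]]
}

#' Median filter with edge replication
#'
#' Replaces each pixel by the median of its `window x window` neighbourhood
#' (element `(N+1)/2` of the sorted neighbourhood), the standard remedy for
#' salt-and-pepper noise that preserves edges. Image borders are handled by
#' edge replication. Colour images are filtered channel-wise.
#'
#' @param img grayscale matrix or colour array in \[0, 255\].
#' @param window odd window size >= 3 (default 3).
#' @return filtered image, same shape as `img`.
#' @export
median_filter <- function(img, window = 3L) {
  assert_image(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("invalid `window`: must be an odd integer >= 3")
  if (is_color_image(img)) {
    out <- img
    for (ch in 1:3) out[, , ch] <- median_filter(img[, , ch], window)
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  k <- (window - 1L) %/% 2L
  pm <- pad_replicate(img, k)
  shifts <- vector("list", window * window)
  s <- 0L
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L)) {
    s <- s + 1L
    shifts[[s]] <- pm[(1 + dr):(h + dr), (1 + dc):(w + dc)]
  }
  if (window == 3L) {
    res <- median9(shifts)
  } else {
    stacked <- vapply(shifts, as.numeric, numeric(h * w))
    res <- matrix(apply(stacked, 1L, function(r) sort(r)[(length(r) + 1L) %/% 2L]), h, w)
  }
  matrix(res, h, w)
}

#' Canvas size of a rotated image
#'
#' Tight bounding-box dimensions of a `width x height` image rotated by
#' `theta_deg`: `ceil(w|cos| + h|sin|)` by `ceil(h|cos| + w|sin|)`.
#' A small tolerance absorbs floating-point residue at right angles.
#'
#' @param width,height source dimensions in px, >= 1.
#' @param theta_deg rotation angle in degrees.
#' @return integer vector `(width_new, height_new)`.
#' @export
rotated_canvas_size <- function(width, height, theta_deg) {
  stopifnot(width >= 1, height >= 1)
  th <- theta_deg * pi / 180
  wn <- ceiling(width * abs(cos(th)) + height * abs(sin(th)) - 1e-9)
  hn <- ceiling(height * abs(cos(th)) + width * abs(sin(th)) - 1e-9)
  c(as.integer(wn), as.integer(hn))
}

#' Rotate an image about its centre with nearest-neighbour sampling
#'
#' Every destination pixel is mapped back to the source through the
#' rotation about the two image centres (source centre
#' `((h-1)/2, (w-1)/2)`, destination centre likewise on the enlarged
#' canvas); the nearest source pixel supplies the value and pixels mapping
#' outside the source are set to 0. At multiples of 90 degrees the map is
#' an exact bijection on pixels.
#'
#' @param img grayscale matrix or colour array.
#' @param theta_deg rotation angle in degrees (positive rotates image
#'   content counter-clockwise on screen).
#' @return list with `image` (rotated) and `params` (list: `theta_deg`,
#'   `center_src`, `center_dst`, `new_size` as `(width, height)`).
#' @export
rotate_image <- function(img, theta_deg) {
  assert_image(img)
  if (!is.finite(theta_deg)) stop("invalid `theta_deg`: must be finite")
  h <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  sz <- rotated_canvas_size(w, h, theta_deg)
  wn <- sz[1]; hn <- sz[2]
  th <- theta_deg * pi / 180
  xr1 <- (w - 1) / 2; yr1 <- (h - 1) / 2
  xr2 <- (wn - 1) / 2; yr2 <- (hn - 1) / 2
  x1 <- matrix(rep(0:(wn - 1), each = hn), hn, wn)
  y1 <- matrix(rep(0:(hn - 1), times = wn), hn, wn)
  x0 <- round((x1 - xr2) * cos(th) - (y1 - yr2) * sin(th) + xr1)
  y0 <- round((x1 - xr2) * sin(th) + (y1 - yr2) * cos(th) + yr1)
  ok <- x0 >= 0 & x0 < w & y0 >= 0 & y0 < h
  idx <- y0[ok] + 1L + x0[ok] * h
  fill_plane <- function(plane) {
    out <- matrix(0, hn, wn)
    out[ok] <- plane[idx]
    out
  }
  rot <- if (is.matrix(img)) fill_plane(img) else {
    out <- array(0, c(hn, wn, 3))
    for (ch in 1:3) out[, , ch] <- fill_plane(img[, , ch])
    out
  }
  list(image = rot,
       params = list(theta_deg = theta_deg,
                     center_src = c(yr1, xr1),
                     center_dst = c(yr2, xr2),
                     new_size = c(wn, hn)))
}

#' Orientation of a binary foreground from second-order moments
#'
#' Returns the angle (degrees) of the foreground's principal axis measured
#' from the horizontal, derived from the second-order central moments.
#' Rotating the image by this angle with [rotate_image()] brings the long
#' axis to the horizontal.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return angle in degrees, in (-90, 90\].
#' @export
estimate_orientation <- function(mask) {
  if (!any(mask)) stop("empty mask: cannot estimate orientation")
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - mean(idx[, 1])
  x <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
}

#' Binarize a grayscale image with Otsu's threshold
#'
#' Foreground = pixels strictly above the between-class-variance-maximising
#' global threshold computed on a 256-bin histogram. A constant image
#' yields an all-background mask with a warning.
#'
#' @param img grayscale matrix in \[0, 255\] (colour input is converted
#'   via [to_gray()]).
#' @return logical matrix (TRUE = foreground).
#' @export
binarize <- function(img) {
  assert_image(img)
  img <- to_gray(img)
  if (length(img) == 0L) stop("empty image")
  if (max(img) - min(img) < .Machine$double.eps^0.5) {
    warning("constant image: returning all-background mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  th <- EBImage::otsu(as_ebimage(clamp255(img)), range = c(0, 1), levels = 256) * 255
  img > th
}

#' Exact Euclidean distance transform of a binary mask
#'
#' Each foreground pixel receives the shortest Euclidean distance to any
#' background pixel; background pixels hold 0. The transform is exact
#' (computed via EBImage's Euclidean distance map).
#'
#' @param mask logical matrix; must contain at least one background pixel.
#' @return numeric matrix of distances.
#' @export
euclidean_distance_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  if (all(mask)) stop("all-foreground mask: background set is empty")
  from_ebimage(EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean"), 1)
}

#' Medial axis of a horizontal foreground via the distance-map ridge
#'
#' For every column of the foreground's bounding rectangle, the row with
#' the maximal distance-transform value is taken, giving the "brightest
#' pixel line" of the distance map. Near blunt shape ends the distance
#' ridge plateaus across many rows; ties are therefore resolved to the
#' middle of the maximal plateau (lower median), which keeps the axis on
#' the shape's midline there.
#' The row path is smoothed with a running median of window 5 and snapped
#' back to the nearest foreground row where smoothing leaves the mask.
#'
#' @param dist distance map from [euclidean_distance_transform()].
#' @param mask the corresponding foreground mask (image already rotated so
#'   the long axis is horizontal).
#' @return an object of class `medial_axis`: list with `points` (n x 2
#'   matrix of (row, col), ordered by column) and `bounding_box`
#'   (`c(top, left, bottom, right)`).
#' @export
extract_medial_axis <- function(dist, mask) {
  stopifnot(is.matrix(dist), is.matrix(mask), all(dim(dist) == dim(mask)))
  if (!any(mask)) stop("empty foreground")
  idx <- which(mask, arr.ind = TRUE)
  box <- c(top = min(idx[, 1]), left = min(idx[, 2]),
           bottom = max(idx[, 1]), right = max(idx[, 2]))
  cols <- box["left"]:box["right"]
  if (length(cols) < 10L)
    stop("foreground narrower than 10 columns: cannot support ten segments")
  rows <- vapply(cols, function(cc) {
    col_d <- dist[, cc]
    col_d[!mask[, cc]] <- -Inf
    at_max <- which(col_d >= max(col_d) - 1e-9)
    at_max[(length(at_max) + 1L) %/% 2L]  # middle of the maximal plateau
  }, integer(1))
  sm <- as.integer(round(stats::runmed(rows, k = 5, endrule = "median")))
  # snap to foreground if the smoothed row left the mask in that column
  for (i in seq_along(cols)) {
    if (!mask[sm[i], cols[i]]) {
      fr <- which(mask[, cols[i]])
      if (length(fr)) sm[i] <- fr[which.min(abs(fr - sm[i]))] else sm[i] <- rows[i]
    }
  }
  structure(list(points = cbind(row = sm, col = as.integer(cols)),
                 bounding_box = box),
            class = "medial_axis")
}

#' Divide the epithelium into ten vertical regions along the medial axis
#'
#' The axis polyline's arclength is split into ten equal spans; every
#' foreground pixel inside the bounding rectangle is assigned to the span
#' holding its perpendicular projection onto the axis (implemented as the
#' nearest axis vertex; ties and pixels projecting exactly onto a division
#' point go to the lower-indexed segment).
#'
#' @param axis a `medial_axis` from [extract_medial_axis()].
#' @param mask the foreground mask.
#' @return an object of class `vertical_segments`: list with `regions`
#'   (list of 10 logical masks L1..L10) and `axis`.
#' @export
split_ten_segments <- function(axis, mask) {
  stopifnot(inherits(axis, "medial_axis"), is.matrix(mask))
  pts <- axis$points
  if (nrow(pts) < 10L) stop("axis spans fewer than 10 columns")
  steps <- sqrt(diff(pts[, "row"])^2 + diff(pts[, "col"])^2)
  s <- c(0, cumsum(steps))
  S <- s[length(s)]
  if (S <= 0) stop("degenerate axis: zero arclength")
  bb <- axis$bounding_box
  inbox <- matrix(FALSE, nrow(mask), ncol(mask))
  inbox[bb["top"]:bb["bottom"], bb["left"]:bb["right"]] <- TRUE
  sel <- which(mask & inbox)
  pr <- ((sel - 1L) %% nrow(mask)) + 1L
  pc <- ((sel - 1L) %/% nrow(mask)) + 1L
  # nearest axis vertex (first minimum -> lower index on ties)
  best_d <- rep(Inf, length(sel))
  best_i <- rep(1L, length(sel))
  for (j in seq_len(nrow(pts))) {
    d <- (pr - pts[j, "row"])^2 + (pc - pts[j, "col"])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- j
  }
  seg_of <- pmin(pmax(ceiling(10 * s[best_i] / S), 1L), 10L)
  regions <- lapply(1:10, function(k) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[sel[seg_of == k]] <- TRUE
    m
  })
  names(regions) <- sprintf("L%02d", 1:10)
  structure(list(regions = regions, axis = axis), class = "vertical_segments")
}

# largest connected foreground component with holes filled; the working
# definition of "the epithelium" for downstream stages
largest_component_filled <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab@.Data))
  if (!length(tab)) return(mask)
  keep <- which.max(tab)
  comp <- lab@.Data == keep
  EBImage::fillHull(EBImage::Image(comp * 1))@.Data > 0
}

#' Full preprocessing chain for one image
#'
#' Runs median filtering, binarization, orientation estimation, rotation
#' to the horizontal, re-binarization on the rotated image (keeping the
#' largest foreground component with holes filled), the Euclidean distance
#' transform, medial-axis extraction and the ten-segment vertical split.
#'
#' @param img grayscale matrix or colour array in \[0, 255\].
#' @param window median-filter window (odd, default 3).
#' @return list with `filtered` (colour/gray, unrotated), `gray_rotated`,
#'   `mask` (rotated foreground), `dist`, `axis`, `segments`, and
#'   `theta_deg` (the rotation applied).
#' @export
preprocess_image <- function(img, window = 3L) {
  assert_image(img)
  filtered <- median_filter(img, window)
  gray <- to_gray(filtered)
  mask0 <- largest_component_filled(binarize(gray))
  theta <- estimate_orientation(mask0)
  rot <- rotate_image(gray, theta)
  mask <- largest_component_filled(binarize(rot$image))
  dist <- euclidean_distance_transform(mask)
  axis <- extract_medial_axis(dist, mask)
  segments <- split_ten_segments(axis, mask)
  list(filtered = filtered, gray_rotated = rot$image, mask = mask,
       dist = dist, axis = axis, segments = segments, theta_deg = theta)
}
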