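#' Lesion segmentation and pixel-area quantification
#'
#' Most skin lesions present as roughly circular patches, so the lesion is
#' extracted by region-based segmentation rather than thresholding: a
#' marker-controlled watershed of the smoothed colour-gradient magnitude
#' over-segments the image into small homogeneous zones, k-means on
#' per-zone colour/intensity/size features merges the zones into four
#' clusters (background, normal skin, lesion, mis-segmented), mis-segmented
#' zones are reassigned by colour distance, and the lesion mask is smoothed
#' morphologically before its pixel area is counted.
#'
#' @name lesion-area
NULL

# smoothed gradient magnitude (max over planes). Colour images are mapped
# to chroma (saturation-scaled hue) + value planes first: lesion erythema
# differs from skin chromatically even where luminance matches, and
# intra-lesion texture shares one hue, so chroma gradients ridge exactly
# at tissue boundaries.
gradient_magnitude <- function(img, sigma = 1.5) {
  planes <- if (is.matrix(img)) list(img) else {
    h <- dim(img)[1]; w <- dim(img)[2]
    ch <- rgb_chroma(cbind(as.numeric(img[, , 1]),
                           as.numeric(img[, , 2]),
                           as.numeric(img[, , 3])))
    lapply(1:3, function(k) matrix(ch[, k] * 255, h, w))
  }
  mags <- lapply(planes, function(p) {
    sm <- from_ebimage(EBImage::gblur(as_ebimage(p), sigma = sigma))
    h <- nrow(sm); w <- ncol(sm)
    gx <- cbind(sm[, -1], sm[, w]) - sm
    gy <- rbind(sm[-1, ], sm[h, ]) - sm
    sqrt(gx^2 + gy^2)
  })
  Reduce(pmax, mags)
}

#' Marker-controlled watershed partition of an image
#'
#' Floods the smoothed gradient magnitude from its regional minima; minima
#' shallower than `marker_threshold` (gray levels on the \[0, 255\] scale)
#' are merged with their neighbours, which curbs the over-segmentation
#' watershed is prone to. Every pixel receives exactly one region label.
#'
#' @param img colour array or grayscale matrix in \[0, 255\].
#' @param marker_threshold minimum basin depth `h` for an independent
#'   marker (default 10).
#' @param sigma Gaussian pre-smoothing of the gradient, px.
#' @return an object of class `region_partition`: list with `label_map`
#'   (integer matrix, labels 1..W), `n_regions`, and `features` (data frame
#'   with per-region mean colour, mean intensity and size in px).
#' @export
watershed_partition <- function(img, marker_threshold = 10, sigma = 1.5) {
  assert_image(img)
  gray <- to_gray(img)
  if (max(gray) - min(gray) < .Machine$double.eps^0.5) {
    warning("constant image: single watershed region")
    lab <- matrix(1L, nrow(gray), ncol(gray))
  } else {
    grad <- gradient_magnitude(img, sigma = sigma)
    relief <- max(grad) - grad + 1
    ws <- EBImage::watershed(EBImage::Image(relief / max(relief)),
                             tolerance = marker_threshold / max(relief),
                             ext = 1)
    lab <- matrix(as.integer(ws@.Data), nrow(gray), ncol(gray))
    if (any(lab == 0L)) {
      # boundary pixels left unlabeled by flooding: give each the label of
      # its nearest labelled neighbour (majority of the 8-neighbourhood)
      lab <- fill_unlabeled(lab)
    }
    # compact labels to 1..W
    u <- sort(unique(as.integer(lab)))
    lab <- matrix(match(lab, u), nrow(gray), ncol(gray))
  }
  W <- max(lab)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(gray), 3))
  feats <- data.frame(
    region = seq_len(W),
    mean_r = as.numeric(tapply(img[, , 1], lab, mean)),
    mean_g = as.numeric(tapply(img[, , 2], lab, mean)),
    mean_b = as.numeric(tapply(img[, , 3], lab, mean)),
    mean_intensity = as.numeric(tapply(gray, lab, mean)),
    size_px = as.integer(tabulate(lab, nbins = W))
  )
  structure(list(label_map = lab, n_regions = W, features = feats),
            class = "region_partition")
}

# assign zero-labeled pixels to the nearest nonzero label (iterative
# 4-neighbour dilation of labels; terminates because labels only grow)
fill_unlabeled <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  while (any(lab == 0L)) {
    z <- which(lab == 0L)
    up    <- ifelse(z %% h == 1L, 0L, lab[pmax(z - 1L, 1L)])
    down  <- ifelse(z %% h == 0L, 0L, lab[pmin(z + 1L, h * w)])
    left  <- ifelse(z <= h, 0L, lab[pmax(z - h, 1L)])
    right <- ifelse(z > h * (w - 1L), 0L, lab[pmin(z + h, h * w)])
    cand <- pmax(up, down, left, right)
    if (all(cand == 0L)) { lab[z] <- 1L; break }
    lab[z] <- cand
  }
  lab
}

# saturation-scaled hue coordinates (chroma) of RGB rows on [0,255] scale;
# circular hue is embedded as (sat cos h, sat sin h), which is stable under
# brightness changes and so separates erythema from skin tone
rgb_chroma <- function(rgbm) {
  rgb <- rgbm / 255
  mx <- pmax(rgb[, 1], rgb[, 2], rgb[, 3])
  mn <- pmin(rgb[, 1], rgb[, 2], rgb[, 3])
  d <- mx - mn
  hdeg <- ifelse(d == 0, 0,
    ifelse(mx == rgb[, 1], ((rgb[, 2] - rgb[, 3]) / d) %% 6,
    ifelse(mx == rgb[, 2], (rgb[, 3] - rgb[, 1]) / d + 2,
                           (rgb[, 1] - rgb[, 2]) / d + 4))) * 60
  sat <- ifelse(mx == 0, 0, d / mx)
  cbind(c1 = sat * cos(hdeg * pi / 180),
        c2 = sat * sin(hdeg * pi / 180),
        v = mx)
}

# hue/saturation/value features for clustering, weighted so chromatic
# differences (erythema vs. skin) dominate over brightness
region_cluster_features <- function(feats, hue_weight = 2) {
  ch <- rgb_chroma(as.matrix(feats[, c("mean_r", "mean_g", "mean_b")]))
  cbind(h1 = hue_weight * ch[, "c1"],
        h2 = hue_weight * ch[, "c2"],
        v = ch[, "v"],
        logsize = log10(feats$size_px) / 6)
}

# deterministic farthest-point seeding for k-means
farthest_point_centers <- function(X, k) {
  n <- nrow(X)
  ctr <- integer(k)
  ctr[1] <- which.min(rowSums(X))  # deterministic anchor
  d <- colSums((t(X) - X[ctr[1], ])^2)
  for (i in seq_len(k - 1L)) {
    ctr[i + 1L] <- which.max(d)
    d <- pmin(d, colSums((t(X) - X[ctr[i + 1L], ])^2))
  }
  X[ctr, , drop = FALSE]
}

#' Cluster watershed regions into semantic roles
#'
#' k-means (k = 4 by default) on per-region hue/value/size features,
#' initialised with deterministic farthest-point seeding and iterated
#' until the centres no longer move. Clusters are mapped to roles:
#' the darkest cluster is the background, the most populous remaining
#' cluster is normal skin, the remaining cluster chromatically farthest
#' from the skin centre is the lesion, and any leftover cluster is marked
#' mis-segmented and its regions reassigned to lesion or normal skin by
#' colour distance.
#'
#' @param part a `region_partition` from [watershed_partition()].
#' @param k number of clusters (reduced to the region count with a warning
#'   if there are fewer regions).
#' @param min_chroma_dist minimum chromatic (saturation-scaled hue)
#'   distance from the normal-skin cluster for a cluster to qualify as a
#'   lesion; sub-clusters of plain skin differ only in brightness and fall
#'   below it, so lesion-free images yield no lesion cluster.
#' @return an object of class `cluster_assignment`: list with
#'   `cluster_of_region` (integer vector over regions 1..W),
#'   `cluster_roles` (character vector per cluster),
#'   `region_roles` (final role per region after reassignment), and
#'   `lesion_regions` (region ids whose final role is lesion).
#' @export
cluster_regions <- function(part, k = 4L, min_chroma_dist = 0.08) {
  stopifnot(inherits(part, "region_partition"))
  W <- part$n_regions
  k <- as.integer(k)
  if (W < k) {
    warning(sprintf("only %d regions: reducing k from %d", W, k))
    k <- W
  }
  X <- region_cluster_features(part$features)
  if (k == 1L) {
    cl <- rep(1L, W)
  } else {
    centers <- farthest_point_centers(X, k)
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 300L, algorithm = "Lloyd"))
    cl <- km$cluster
  }
  sizes_px <- tapply(part$features$size_px, cl, sum)
  mean_v <- tapply(part$features$mean_intensity * part$features$size_px, cl, sum) / sizes_px
  ids <- as.integer(names(sizes_px))
  roles <- rep("mis_segmented", length(ids))
  names(roles) <- ids
  bg <- ids[which.min(mean_v)]
  roles[as.character(bg)] <- "background"
  rest <- setdiff(ids, bg)
  chroma_of <- function(cc) rgb_chroma(rbind(cluster_mean_rgb(part, cl, cc)))[1, 1:2]
  if (length(rest)) {
    skin <- rest[which.max(sizes_px[as.character(rest)])]
    roles[as.character(skin)] <- "normal_skin"
    rest2 <- setdiff(rest, skin)
    if (length(rest2)) {
      skin_ch <- chroma_of(skin)
      dch <- vapply(rest2, function(cc)
        sqrt(sum((chroma_of(cc) - skin_ch)^2)), numeric(1))
      if (max(dch) >= min_chroma_dist)
        roles[as.character(rest2[which.max(dch)])] <- "lesion"
    }
  }
  # reassign mis-segmented regions to lesion or normal skin by chroma
  role_of_region <- roles[as.character(cl)]
  mis <- which(role_of_region == "mis_segmented")
  if (length(mis)) {
    if ("lesion" %in% roles) {
      lesion_ch <- chroma_of(as.integer(names(roles)[roles == "lesion"]))
      skin_ch <- chroma_of(as.integer(names(roles)[roles == "normal_skin"]))
      rch <- rgb_chroma(as.matrix(part$features[mis, c("mean_r", "mean_g", "mean_b"), drop = FALSE]))[, 1:2, drop = FALSE]
      dl <- rowSums((rch - rep(lesion_ch, each = length(mis)))^2)
      ds <- rowSums((rch - rep(skin_ch, each = length(mis)))^2)
      role_of_region[mis] <- ifelse(dl < ds, "lesion", "normal_skin")
    } else {
      role_of_region[mis] <- "normal_skin"
    }
  }
  structure(list(cluster_of_region = cl,
                 cluster_roles = roles,
                 region_roles = unname(role_of_region),
                 lesion_regions = which(role_of_region == "lesion")),
            class = "cluster_assignment")
}

cluster_mean_rgb <- function(part, cl, cluster_id) {
  sel <- cl == cluster_id
  sz <- part$features$size_px[sel]
  colSums(as.matrix(part$features[sel, c("mean_r", "mean_g", "mean_b")]) * sz) / sum(sz)
}

#' Morphological cleanup of a binary mask
#'
#' Closing followed by opening with a disk structuring element: the
#' closing fills pinholes and black flecks smaller than the element before
#' the opening can enlarge them, and the opening then removes isolated
#' specks and smooths the lesion boundary. Idempotent.
#'
#' @param mask logical matrix.
#' @param radius disk radius in px (default 3).
#' @return cleaned logical matrix.
#' @export
morphological_cleanup <- function(mask, radius = 3L) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  e <- EBImage::Image(mask * 1)
  e <- EBImage::opening(EBImage::closing(e, brush), brush)
  e@.Data > 0
}

#' Lesion pixel area and area fraction
#'
#' @param mask logical lesion mask.
#' @return list with `lesion_area_px` (pixel count) and `area_fraction`
#'   (count / total pixels).
#' @export
pixel_area <- function(mask) {
  stopifnot(is.matrix(mask))
  n <- sum(mask)
  list(lesion_area_px = as.integer(n), area_fraction = n / length(mask))
}

#' End-to-end lesion segmentation
#'
#' Watershed partition, region clustering, lesion-role mask extraction,
#' morphological cleanup and area statistics: the colour-feature branch
#' the classifier consumes.
#'
#' @param img colour array in \[0, 255\] (ideally median-filtered).
#' @param marker_threshold watershed basin depth (gray levels).
#' @param se_radius cleanup disk radius, px.
#' @param k number of region clusters.
#' @return an object of class `lesion_segmentation`: list with
#'   `lesion_mask`, `lesion_area_px`, `area_fraction`, `partition`,
#'   `assignment`.
#' @export
segment_lesion <- function(img, marker_threshold = 10, se_radius = 3L, k = 4L) {
  assert_image(img)
  part <- watershed_partition(img, marker_threshold = marker_threshold)
  asg <- cluster_regions(part, k = k)
  mask <- matrix(FALSE, nrow(part$label_map), ncol(part$label_map))
  if (length(asg$lesion_regions))
    mask <- matrix(part$label_map %in% asg$lesion_regions,
                   nrow(part$label_map), ncol(part$label_map))
  mask <- morphological_cleanup(mask, radius = se_radius)
  area <- pixel_area(mask)
  structure(list(lesion_mask = mask,
                 lesion_area_px = area$lesion_area_px,
                 area_fraction = area$area_fraction,
                 partition = part, assignment = asg),
            class = "lesion_segmentation")
}
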