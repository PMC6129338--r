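test_that("watershed partition labels every pixel with contiguous labels", {
  # two flat patches with a step edge
  img <- matrix(60, 40, 40); img[, 21:40] <- 200
  part <- watershed_partition(img)
  expect_equal(sort(unique(as.integer(part$label_map))), seq_len(part$n_regions))
  expect_gte(part$n_regions, 2L)
  expect_equal(sum(part$features$size_px), length(img))
  expect_warning(p1 <- watershed_partition(matrix(5, 16, 16)), "constant")
  expect_equal(p1$n_regions, 1L)
  # synthetic lesion image: some region overlaps the true lesion by >= 50%
  g <- generate_image(synth_spec("psoriasis", seed = 10, orientation_deg = 10))
  pp <- watershed_partition(median_filter(g$image))
  expect_gt(pp$n_regions, 1L)
  truth <- g$ground_truth$lesion_mask
  overlaps <- vapply(seq_len(pp$n_regions), function(r) {
    reg <- pp$label_map == r
    sum(reg & truth) / sum(reg)
  }, 1)
  expect_gte(max(overlaps), 0.5)
})

test_that("region clustering recovers constructed groups and is deterministic", {
  # four well-separated colour groups painted as flat stripes
  img <- array(0, c(40, 40, 3))
  cols <- list(c(10, 10, 10), c(200, 170, 150), c(200, 110, 100), c(60, 180, 60))
  for (k in 1:4) for (ch in 1:3) img[, (k - 1) * 10 + 1:10, ch] <- cols[[k]][ch]
  part <- watershed_partition(img)
  a1 <- cluster_regions(part)
  a2 <- cluster_regions(part)
  expect_identical(a1, a2)
  # partition identity up to label permutation: regions in the same stripe
  # share a cluster, regions in different stripes do not
  stripe_of <- vapply(seq_len(part$n_regions), function(r) {
    px <- which(part$label_map == r, arr.ind = TRUE)
    1 + (round(mean(px[, 2])) - 1) %/% 10
  }, 1)
  if (part$n_regions >= 4) {
    cl <- a1$cluster_of_region
    expect_equal(length(unique(paste(stripe_of, cl))), length(unique(stripe_of)))
  }
  expect_warning(cluster_regions(watershed_partition(matrix(c(0, 255), 16, 16))),
                 "reducing k")
})

test_that("lesion role lands on the erythematous cluster on generated images", {
  hits <- 0L
  for (s in 1:10) {
    g <- generate_image(synth_spec("herpes", seed = 400 + s, orientation_deg = 3 * s - 15))
    seg <- suppressWarnings(segment_lesion(median_filter(g$image)))
    truth <- g$ground_truth$lesion_mask
    iou <- sum(seg$lesion_mask & truth) / sum(seg$lesion_mask | truth)
    if (is.finite(iou) && iou > 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("morphological cleanup removes specks, fills pinholes, and is idempotent", {
  m <- matrix(FALSE, 30, 30); m[15, 15] <- TRUE
  expect_false(any(morphological_cleanup(m)))
  expect_false(any(morphological_cleanup(matrix(FALSE, 10, 10))))
  # disk with 50 random single-pixel holes: restored to within 2%
  disk <- outer((1:50 - 25.5)^2, (1:50 - 25.5)^2, "+") <= 20^2
  set.seed(8)
  holey <- disk
  holey[sample(which(disk), 50)] <- FALSE
  clean <- morphological_cleanup(holey)
  expect_lt(abs(sum(clean) - sum(disk)) / sum(disk), 0.02)
  expect_identical(morphological_cleanup(clean), clean)
})

test_that("pixel area counts and normalises", {
  pa <- pixel_area(matrix(FALSE, 10, 10))
  expect_equal(pa$lesion_area_px, 0L)
  expect_equal(pa$area_fraction, 0)
  pa2 <- pixel_area(matrix(TRUE, 10, 10))
  expect_equal(pa2$lesion_area_px, 100L)
  expect_equal(pa2$area_fraction, 1)
})

test_that("end-to-end segmentation: clean on normals, ordered across diseases", {
  gn <- generate_image(synth_spec("normal", seed = 31, noise_fraction = 0.02))
  segn <- suppressWarnings(segment_lesion(median_filter(gn$image)))
  expect_lt(segn$area_fraction, 0.01)
  gp <- generate_image(synth_spec("psoriasis", lesion_radius_px = 60, seed = 32))
  gd <- generate_image(synth_spec("paederus_dermatitis", lesion_radius_px = 25, seed = 32))
  ap <- suppressWarnings(segment_lesion(median_filter(gp$image)))$lesion_area_px
  ad <- suppressWarnings(segment_lesion(median_filter(gd$image)))$lesion_area_px
  expect_gt(ap, ad)
  g <- generate_image(synth_spec("herpes", seed = 33, noise_fraction = 0.02))
  f <- median_filter(g$image)
  s1 <- suppressWarnings(segment_lesion(f))
  s2 <- suppressWarnings(segment_lesion(f))
  expect_identical(s1$lesion_mask, s2$lesion_mask)
})
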