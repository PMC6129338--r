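test_that("median filter removes impulses, keeps constants, matches the naive oracle", {
  expect_error(median_filter(matrix(0, 8, 8), window = 4), "window")
  const <- matrix(42, 10, 10)
  expect_equal(median_filter(const), const)
  patch <- matrix(10, 5, 5); patch[3, 3] <- 255
  expect_equal(median_filter(patch)[3, 3], 10)
  set.seed(31)
  for (w in c(3L, 5L)) {
    img <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
    expect_equal(median_filter(img, w), oracle_median_filter(img, w))
  }
  # output range never leaves input range
  img <- matrix(runif(400, 50, 60), 20, 20)
  out <- median_filter(img)
  expect_gte(min(out), 50); expect_lte(max(out), 60)
})

test_that("rotated canvas size matches the closed form and right-angle cases", {
  expect_equal(rotated_canvas_size(100, 50, 0), c(100L, 50L))
  expect_equal(rotated_canvas_size(100, 50, 90), c(50L, 100L))
  expect_equal(rotated_canvas_size(100, 50, 180), c(100L, 50L))
  expect_equal(rotated_canvas_size(100, 50, 30), c(112L, 94L))
})

test_that("rotation is identity at 0, a pixel bijection at right angles, and center-reflects at 180", {
  set.seed(5)
  img <- matrix(sample(0:255, 30 * 20, TRUE), 20, 30)
  expect_equal(rotate_image(img, 0)$image, img)
  r90 <- rotate_image(img, 90)$image
  expect_equal(dim(r90), c(30, 20))
  expect_equal(sort(as.numeric(r90)), sort(as.numeric(img)))  # bijection
  back <- rotate_image(r90, -90)$image
  expect_equal(back, img)
  # single bright pixel reflects through the centre at 180 degrees
  one <- matrix(0, 11, 11); one[3, 4] <- 200
  r180 <- rotate_image(one, 180)$image
  expect_equal(which(r180 == 200, arr.ind = TRUE)[1, ], c(row = 9, col = 8))
})

test_that("principal-axis orientation recovers the generated angle", {
  expect_error(estimate_orientation(matrix(FALSE, 5, 5)), "empty")
  mk <- function(deg) {
    g <- generate_image(synth_spec("normal", orientation_deg = deg, seed = 2))
    g$ground_truth$foreground_mask
  }
  expect_lt(abs(estimate_orientation(mk(0))), 1)
  expect_lt(abs(estimate_orientation(mk(30)) - 30), 1)
  expect_lt(abs(estimate_orientation(mk(-20)) + 20), 1)
})

test_that("Otsu binarization separates bimodal images and flags constants", {
  img <- matrix(c(20, 200)[1 + (row(matrix(0, 20, 20)) > 10)], 20, 20)
  m <- binarize(img)
  expect_identical(m, img > 100)
  expect_warning(b <- binarize(matrix(7, 8, 8)), "constant")
  expect_false(any(b))
  g <- generate_image(synth_spec("normal", seed = 4))
  mask <- binarize(to_gray(g$image))
  fg <- g$ground_truth$foreground_mask
  expect_gt(sum(mask & fg) / sum(fg), 0.95)
})

test_that("Euclidean distance transform equals the exhaustive oracle exactly", {
  expect_error(euclidean_distance_transform(matrix(TRUE, 4, 4)), "background")
  # 3-4-5 structure: lone background pixel offset (3,4) from a probe
  m <- matrix(TRUE, 12, 12); m[2, 3] <- FALSE
  d <- euclidean_distance_transform(m)
  expect_equal(d[5, 7], 5)
  # full-width strip of height 7: centre row distance 4 (pixel steps to off-strip)
  s <- matrix(FALSE, 15, 9); s[5:11, ] <- TRUE
  ds <- euclidean_distance_transform(s)
  expect_equal(unique(ds[8, ]), 4)
  set.seed(77)
  for (i in 1:6) {
    mm <- matrix(runif(48 * 48) > 0.35, 48, 48)
    if (all(mm)) mm[1, 1] <- FALSE
    expect_identical(euclidean_distance_transform(mm), oracle_edt(mm))
  }
})

test_that("medial axis follows the ridge with one point per bounding-box column", {
  strip <- matrix(FALSE, 30, 40); strip[10:20, ] <- TRUE
  d <- euclidean_distance_transform(strip)
  ax <- extract_medial_axis(d, strip)
  expect_equal(nrow(ax$points), 40L)
  expect_true(all(ax$points[, "row"] == 15))
  expect_true(!is.unsorted(ax$points[, "col"]))
  narrow <- matrix(FALSE, 20, 20); narrow[5:15, 8:12] <- TRUE
  expect_error(extract_medial_axis(euclidean_distance_transform(narrow), narrow),
               "10 columns")
  # synthetic epithelium: axis within 2 px of the known midline over the
  # central 80% of columns
  g <- generate_image(synth_spec("normal", seed = 8))
  fg <- g$ground_truth$foreground_mask
  axe <- extract_medial_axis(euclidean_distance_transform(fg), fg)
  ctr <- (nrow(fg) - 1) / 2 + 1
  cols <- axe$points[, "col"]
  core <- cols > quantile(cols, 0.1) & cols < quantile(cols, 0.9)
  expect_true(all(abs(axe$points[core, "row"] - ctr) <= 2))
  expect_true(all(fg[axe$points]))
})

test_that("ten-segment split partitions the foreground into equal-arclength spans", {
  strip <- matrix(FALSE, 30, 100); strip[10:20, ] <- TRUE
  ax <- extract_medial_axis(euclidean_distance_transform(strip), strip)
  segs <- split_ten_segments(ax, strip)
  widths <- vapply(segs$regions, function(m) length(unique(which(m, arr.ind = TRUE)[, 2])), 1L)
  expect_equal(unname(widths), rep(10L, 10))
  # 105-column straight axis: span widths differ by at most one column
  s2 <- matrix(FALSE, 30, 105); s2[10:20, ] <- TRUE
  ax2 <- extract_medial_axis(euclidean_distance_transform(s2), s2)
  w2 <- vapply(split_ten_segments(ax2, s2)$regions,
               function(m) length(unique(which(m, arr.ind = TRUE)[, 2])), 1L)
  expect_lte(diff(range(w2)), 1L)
  # contract: 10 pairwise-disjoint regions covering the boxed foreground
  g <- generate_image(synth_spec("herpes", orientation_deg = 15, seed = 6))
  pre <- preprocess_image(g$image)
  regs <- pre$segments$regions
  expect_length(regs, 10L)
  overlap <- Reduce(`+`, lapply(regs, function(m) m * 1L))
  expect_lte(max(overlap), 1L)
  expect_equal(sum(overlap), sum(pre$mask))
  expect_true(all(vapply(regs, any, TRUE)))
})

test_that("full preprocessing is deterministic and straightens the epithelium", {
  g <- generate_image(synth_spec("paederus_dermatitis", orientation_deg = -18,
                                 noise_fraction = 0.02, seed = 13))
  p1 <- preprocess_image(g$image)
  p2 <- preprocess_image(g$image)
  expect_identical(p1$segments$regions, p2$segments$regions)
  expect_lt(abs(estimate_orientation(p1$mask)), 2)
})
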