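test_that("filters preserve constants and 'none' is the identity", {
  m <- matrix(7, 16, 16)
  for (f in c("gaussian", "median")) {
    expect_equal(apply_filter(m, f), m, tolerance = 1e-10)
  }
  r <- matrix(runif(256, 0, 100), 16, 16)
  expect_identical(apply_filter(r, "none"), r)
})

test_that("median filter removes an isolated bright pixel and matches the brute-force oracle", {
  m <- matrix(0, 9, 9); m[5, 5] <- 100
  expect_equal(apply_filter(m, "median", radius = 1), matrix(0, 9, 9))

  set.seed(11)
  for (radius in 1:2) {
    r <- matrix(sample(0:50, 12 * 10, replace = TRUE) * 1.0, 12, 10)
    expect_equal(apply_filter(r, "median", radius = radius),
                 brute_median_filter(r, radius))
  }
})

test_that("filter parameter validation rejects bad values", {
  m <- matrix(0, 8, 8)
  expect_error(apply_filter(m, "gaussian", sigma = 0), "sigma")
  expect_error(apply_filter(m, "median", radius = 0.5), "radius")
})

test_that("thresholding keeps only strictly-above-threshold pixels", {
  m <- matrix(10, 10, 10)
  expect_equal(nrow(threshold_segment(m, threshold = 10, min_area = 1)), 0)

  m <- matrix(0, 10, 10); m[3:7, 4:8] <- 100
  rois <- threshold_segment(m, threshold = 50, min_area = 1)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$area, 25L)
  expect_equal(unlist(rois[1, c("rmin", "cmin", "rmax", "cmax")],
                      use.names = FALSE), c(2L, 3L, 7L, 8L))
})

test_that("separated blocks give distinct components; diagonal contact depends on connectivity", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 100
  m[7:9, 2:4] <- 100   # 2-pixel background gap
  expect_equal(nrow(threshold_segment(m, 50, min_area = 1, connectivity = 8)), 2)

  d <- matrix(0, 8, 8)
  d[2:3, 2:3] <- 100
  d[4:5, 4:5] <- 100   # touching at one corner only
  expect_equal(nrow(threshold_segment(d, 50, min_area = 1, connectivity = 8)), 1)
  expect_equal(nrow(threshold_segment(d, 50, min_area = 1, connectivity = 4)), 2)
})

test_that("min_area discards small components and ROI pixels partition the above-threshold set", {
  set.seed(4)
  m <- matrix(runif(400), 20, 20)
  rois <- threshold_segment(m, 0.7, min_area = 3)
  expect_true(all(rois$area >= 3))
  all_px <- do.call(rbind, rois$pixels)
  if (!is.null(all_px)) {
    expect_true(all(m[all_px] > 0.7))
    expect_equal(nrow(all_px), nrow(unique(all_px)))  # pairwise disjoint
  }
  # with min_area = 1 the union equals the above-threshold set
  rois1 <- threshold_segment(m, 0.7, min_area = 1)
  expect_equal(sum(rois1$area), sum(m > 0.7))
})

test_that("labelling agrees with a flood-fill oracle on random rasters", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(4:24, 1); nc <- sample(4:24, 1)
    mask <- matrix(runif(nr * nc) < runif(1, 0.2, 0.7), nr, nc)
    for (conn in c(4L, 8L)) {
      expect_identical(partition_of(label_components(mask, conn)),
                       partition_of(flood_fill_label(mask, conn)))
    }
  }
})

test_that("segmenting a label-map rendering reproduces the same partition", {
  set.seed(9)
  m <- matrix(runif(900, 0, 100), 30, 30)
  for (conn in c(4L, 8L)) {
    rois <- threshold_segment(m, 60, min_area = 1, connectivity = conn)
    lab <- as_label_map(rois, dim(m))
    rois2 <- threshold_segment(lab * 1.0, 0, min_area = 1,
                               connectivity = conn)
    p1 <- lapply(rois$pixels, function(px) sort((px[, 2] - 1L) * 30L + px[, 1]))
    p2 <- lapply(rois2$pixels, function(px) sort((px[, 2] - 1L) * 30L + px[, 1]))
    expect_setequal(p1, p2)
  }
})

test_that("raising the threshold never increases the above-threshold pixel count", {
  set.seed(5)
  m <- matrix(runif(625, 0, 100), 25, 25)
  counts <- vapply(seq(0, 100, by = 10), function(thr) {
    sum(threshold_segment(m, thr, min_area = 1)$area)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate inputs raise structural errors", {
  expect_error(threshold_segment(numeric(0), 1), "structural")
  expect_error(compute_features(
    tibble::tibble(roi_id = 1L, channel = "total_dna", area = 1L,
                   rmin = 50L, cmin = 50L, rmax = 51L, cmax = 51L,
                   pixels = list(cbind(row = 51L, col = 51L))),
    matrix(0, 10, 10), matrix(0, 10, 10)), "bounds")
})
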