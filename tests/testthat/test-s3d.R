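test_that("ROI pattern extraction is the per-band arithmetic mean", {
  cube <- array(0.5, c(6, 6, 4))
  expect_equal(extract_pattern_from_roi(cube, c(2, 4, 2, 4))$values, rep(0.5, 4))

  vals <- array(0, c(2, 2, 1))
  vals[, , 1] <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(extract_pattern_from_roi(vals, c(1, 2, 1, 2))$values, 0.5)

  expect_error(extract_pattern_from_roi(cube, c(4, 2, 1, 2)), "empty")
  expect_error(extract_pattern_from_roi(cube, c(1, 7, 1, 2)), "bounds")
})

test_that("a whole-image ROI recovers the generator spectrum within sampling error", {
  ph <- render_phantom(phantom_spec(
    rows = 48L, cols = 48L, bands = 16L,
    objects = list(list(shape = shape_rectangle(1L, 48L, 1L, 48L),
                        spectrum = default_object_model())),
    artifact_count = 0L))
  lc <- calibrate(ph$raw, ph$dark, ph$white)
  pat <- extract_pattern_from_roi(lc, c(1, 48, 1, 48))
  # per-band standard error of the ROI mean, in reflectance units
  span <- round(0.92 * 4095) - round(0.03 * 4095)
  sigma <- band_edge_noise_profile(16, 0.008, 3) * 4095 / span
  se <- sigma / sqrt(48 * 48)
  expect_true(all(abs(pat$values - ph$spectra[[1]]$values) < 3 * se + 1 / span))
})

test_that("difference volumes subtract the pattern with strict locality", {
  pat <- c(0.2, 0.5, 0.8)
  cube <- aperm(array(pat, c(3, 4, 4)), c(2, 3, 1))
  expect_equal(difference_volume(cube, pat), array(0, c(4, 4, 3)))
  cube[2, 3, 1] <- cube[2, 3, 1] + 0.3
  dv <- difference_volume(cube, pat)
  expect_equal(dv[2, 3, 1], 0.3)
  dv[2, 3, 1] <- 0
  expect_equal(dv, array(0, c(4, 4, 3)))
  expect_equal(difference_volume(2 * cube, 2 * pat),
               2 * difference_volume(cube, pat))
  expect_error(difference_volume(cube, c(0.2, 0.5)), "2 bands")
})

test_that("volume filtering delegates to the 3x3x3 median", {
  set.seed(30)
  vol <- array(rnorm(6 * 6 * 5), c(6, 6, 5))
  expect_equal(median_filter_volume(vol), median3d(vol, c(3, 3, 3)))
})

test_that("error aggregation reproduces its defining cases", {
  pat <- c(0.2, 0.4, 0.6)
  expect_equal(aggregate_error(array(0, c(4, 4, 3)), pat, window = 1),
               matrix(0, 4, 4))
  vol <- array(0.1 * mean(pat), c(4, 4, 3))
  expect_equal(aggregate_error(vol, pat, window = 1), matrix(10, 4, 4))
  expect_error(aggregate_error(vol, c(-1, 0, 1)), "zero mean")
})

test_that("error aggregation matches the double-loop mean-abs + windowed-median oracle", {
  set.seed(31)
  pat <- runif(5, 0.3, 0.8)
  for (rep in 1:3) {
    vol <- array(rnorm(7 * 6 * 5, sd = 0.1), c(7, 6, 5))
    expect_equal(aggregate_error(vol, pat, window = 3),
                 oracle_aggregate(vol, pat, 3))
  }
})

test_that("threshold levels nest and a noiseless stripe segments exactly", {
  ph <- stripe_phantom()
  lc <- calibrate(ph$raw, ph$dark, ph$white)
  lev <- s3d_segment(lc, roi = c(20, 28, 10, 30))
  truth <- matrix(as.integer(ph$truth == 1L), 48)
  for (k in 1:3)
    expect_identical(matrix(as.integer(lev >= k), 48), truth)

  # nesting on a noisy phantom, including at intermediate L_S values
  phn <- small_noisy_phantom()
  lcn <- calibrated_of(phn)
  levn <- s3d_segment(lcn, roi = c(18, 28, 20, 30))
  expect_true(all((levn >= 3) <= (levn >= 2)))
  expect_true(all((levn >= 2) <= (levn >= 1)))
  expect_error(s3d_segment(lcn, c(20, 25, 20, 25), thresholds = c(10, 20)),
               "decreasing")
  expect_error(s3d_segment(lcn, c(20, 25, 20, 25), thresholds = c(120, 20)),
               "0, 100")
})

test_that("with zero noise every ROI pixel lands in the mask at any threshold", {
  ph <- stripe_phantom()
  lc <- calibrate(ph$raw, ph$dark, ph$white)
  roi <- c(18, 30, 5, 44)
  lev <- s3d_segment(lc, roi = roi, thresholds = c(5, 2, 1))
  expect_true(all(lev[roi[1]:roi[2], roi[3]:roi[4]] == 3L))
})

test_that("segmentation is equivariant to 90-degree rotation", {
  ph <- small_noisy_phantom()
  lc <- calibrated_of(ph)
  roi <- c(18, 28, 20, 30)
  lev <- s3d_segment(lc, roi = roi)
  lev_rot <- s3d_segment(rot90_cube(lc), roi = rot90_roi(roi, ncol(ph$truth)))
  strip <- function(x) { attr(x, "thresholds") <- NULL; x }
  expect_identical(strip(lev_rot), rot90_mat(strip(lev)))
})

test_that("default-phantom recovery at the 20 percent bound is near-perfect", {
  ph <- small_noisy_phantom()
  lc <- calibrated_of(ph)
  lev <- s3d_segment(lc, roi = c(18, 28, 20, 30))
  expect_gte(acc_of((lev >= 2) * 1L, ph$truth), 95)
})
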