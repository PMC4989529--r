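test_that("block-mean downsampling pools exactly", {
  set.seed(40)
  x <- rand_cube_array(c(8, 8, 2))
  expect_identical(downsample_cube(x, 1), x)
  const <- array(0.7, c(8, 8, 1))
  expect_equal(downsample_cube(const, 8), array(0.7, c(1, 1, 1)))
  halves <- array(rep(c(0, 1), each = 8 * 8), c(16, 16, 1))
  halves[, , 1] <- rbind(matrix(0, 8, 16), matrix(1, 8, 16))
  expect_equal(downsample_cube(halves, 8)[, , 1], matrix(c(0, 1, 0, 1), 2, 2))
  # trailing partial blocks average over their actual extent
  y <- array(rep(seq_len(5), 2), c(5, 2, 1))
  expect_equal(downsample_cube(y, 2)[, 1, 1], c(1.5, 3.5, 5))
  expect_error(downsample_cube(x, 9), "exceeds")
})

test_that("local maxima are ranked by height and returned in band order", {
  expect_identical(find_local_maxima(c(0, 1, 0, 2, 0), 2), c(2L, 4L))
  expect_identical(find_local_maxima(c(0, 3, 0, 2, 0, 1, 0), 3), c(2L, 4L, 6L))
  expect_identical(find_local_maxima(c(0, 2, 2, 1, 0), 1), 2L)  # plateau -> leftmost
  expect_error(find_local_maxima(1:10), "no interior local maximum")
  expect_warning(got <- find_local_maxima(c(0, 1, 0), 3), "only 1")
  expect_identical(got, 2L)
})

test_that("features are absolute deviations at the peak bands", {
  pat <- c(0.2, 0.6, 0.3, 0.8, 0.4)
  cube <- aperm(array(pat, c(5, 2, 2)), c(2, 3, 1))
  fs <- extract_features(cube, pat, c(2L, 4L))
  expect_equal(fs$features, matrix(0, 4, 2))
  cube[1, 1, 2] <- pat[2] + 0.2
  cube[2, 2, 4] <- pat[4] - 0.15
  fs <- extract_features(cube, pat, c(2L, 4L))
  expect_equal(fs$features[1, ], c(0.2, 0))
  expect_equal(fs$features[4, ], c(0, 0.15))     # sign-invariant
  expect_error(extract_features(cube, pat, c(0L, 4L)), "range")
})

test_that("clustering splits point masses perfectly with zero dispersion", {
  f <- rbind(matrix(0, 40, 3), matrix(0.8, 60, 3))
  cl <- cluster_pixels(f, 2)
  expect_equal(cl$dispersion, 0)
  expect_equal(length(unique(cl$labels[1:40])), 1L)
  expect_equal(length(unique(cl$labels[41:100])), 1L)
  expect_error(cluster_pixels(matrix(0.5, 50, 3), 2), "degenerate")
  expect_error(cluster_pixels(f, 6), "K")
})

test_that("well-separated blobs are recovered almost perfectly", {
  centers <- rbind(c(0.05, 0.05, 0.05), c(0.7, 0.1, 0.1), c(0.1, 0.65, 0.6))
  bf <- blob_features(centers)
  cl <- cluster_pixels(bf$features, 3)
  expect_gte(match_rate(cl$labels, bf$truth), 0.99)
})

test_that("the dispersion-minimal class count recovers the true blob count", {
  centers3 <- rbind(c(0.05, 0.05, 0.05), c(0.7, 0.1, 0.1), c(0.1, 0.65, 0.6))
  bf <- blob_features(centers3)
  best <- select_class_count(bf$features)
  expect_equal(best$K, 3L)
  disp <- attr(best, "dispersions")
  expect_equal(unname(disp["3"]), best$dispersion)
  expect_true(all(best$dispersion <= disp))   # direct assertion of the rule

  centers2 <- rbind(c(0.05, 0.05, 0.05), c(0.6, 0.5, 0.4))
  bf2 <- blob_features(centers2, seed = 77)
  expect_equal(select_class_count(bf2$features)$K, 2L)
})

test_that("class-count selection is invariant to pixel order up to relabeling", {
  centers <- rbind(c(0.05, 0.05, 0.05), c(0.7, 0.1, 0.1), c(0.1, 0.65, 0.6))
  bf <- blob_features(centers)
  set.seed(41)
  perm <- sample.int(nrow(bf$features))
  a <- select_class_count(bf$features)
  b <- select_class_count(bf$features[perm, ])
  expect_equal(b$K, a$K)
  expect_equal(b$dispersion, a$dispersion)
  expect_gte(match_rate(b$labels, a$labels[perm]), 0.999)
})

test_that("label upsampling is blockwise nearest-neighbour", {
  labs <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  up <- upsample_labels(labs, c(16, 16), factor = 8)
  expect_identical(dim(up), c(16L, 16L))
  expect_true(all(up[1:8, 1:8] == 1L))
  expect_true(all(up[9:16, 9:16] == 4L))
  expect_identical(upsample_labels(labs, c(2, 2), factor = 1), labs)
  # majority (here: any) block reduction inverts the expansion
  down <- (downsample_cube(array(up, c(16, 16, 1)), 8)[, , 1])
  expect_equal(down, matrix(as.numeric(labs), 2, 2))
})

test_that("a noiseless block-aligned two-object phantom segments exactly", {
  ph <- two_object_phantom()
  lc <- calibrate(ph$raw, ph$dark, ph$white)
  seg <- sh_segment(lc, pattern = ph$spectra[[1]], factor = 4)
  expect_identical(seg$mask, matrix(as.integer(ph$truth == 1L), 48))
  # 3 distinct materials -> 3 classes, chosen automatically
  expect_equal(seg$clustering$K, 3L)
})

test_that("noisy phantom recovery is accurate and stabilization does not hurt", {
  ph <- default_noisy_phantom()
  lc <- calibrated_of(ph)
  seg <- sh_segment(lc, pattern = ph$spectra[[1]])
  expect_gte(acc_of(seg$mask, ph$truth), 95)

  phe <- edge_noise_phantom()
  lce <- calibrated_of(phe)
  with_st <- sh_segment(lce, pattern = phe$spectra[[1]])
  without <- sh_segment(lce, pattern = phe$spectra[[1]], stabilize = FALSE)
  expect_gte(acc_of(with_st$mask, phe$truth), acc_of(without$mask, phe$truth))
})

test_that("an ROI can stand in for the reference spectrum", {
  ph <- default_noisy_phantom()
  lc <- calibrated_of(ph)
  seg <- sh_segment(lc, roi = c(40, 55, 42, 57))
  expect_gte(acc_of(seg$mask, ph$truth), 95)
  expect_error(sh_segment(lc), "pattern.*roi|roi")
})
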