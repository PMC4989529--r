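#' Region of interest rectangles
#'
#' An ROI is a rectangle given by 1-based inclusive bounds
#' `c(row_start, row_end, col_start, col_end)`.
#'
#' @noRd
validate_roi <- function(roi, d) {
  roi <- as.integer(roi)
  if (length(roi) != 4L)
    stop("`roi` must be c(row_start, row_end, col_start, col_end)")
  if (roi[1] > roi[2] || roi[3] > roi[4])
    stop("`roi` is empty")
  if (roi[1] < 1L || roi[2] > d[1] || roi[3] < 1L || roi[4] > d[2])
    stop("`roi` exceeds cube bounds")
  roi
}

#' Average a reference spectrum over a region of interest
#'
#' Builds the reference waveform as the per-band arithmetic mean of the
#' pixels in the rectangle:
#' `L_PAT(i) = (1 / (M_R * N_R)) * sum_{(m,n) in ROI} L(m, n, i)`.
#'
#' @param cube a [hypercube()] or 3D array (typically the calibrated `L_C`).
#' @param roi integer vector `c(row_start, row_end, col_start, col_end)`,
#'   1-based inclusive, marking a patch inside the object to segment.
#' @return A [ref_spectrum()].
#' @export
extract_pattern_from_roi <- function(cube, roi) {
  v <- cube_values(cube)
  roi <- validate_roi(roi, dim(v))
  patch <- v[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  ref_spectrum(apply(patch, 3, mean),
               if (inherits(cube, "hypercube")) cube$wavelengths else NULL)
}

#' Signed difference volume against a reference spectrum
#'
#' `L_V(m, n, i) = L(m, n, i) - L_PAT(i)`, the per-voxel signed mismatch
#' that feeds the 3D median filtering stage of [s3d_segment()].
#'
#' @inheritParams relative_difference
#' @return 3D array of signed differences.
#' @export
difference_volume <- function(cube, pattern) {
  v <- cube_values(cube)
  p <- pattern_values(pattern, dim(v)[3])
  sweep(v, 3, p, "-")
}

#' 3D median filtering of a difference volume
#'
#' Filters the signed difference volume over the full 3x3x3 neighbourhood of
#' each voxel (the in-plane 8-neighbourhood extended to the adjacent bands),
#' suppressing the artifacts contributed by the noisy border bands.
#' Delegates to [median3d()] with a `(3, 3, 3)` mask.
#'
#' @param vol 3D array from [difference_volume()].
#' @return Filtered 3D array.
#' @export
median_filter_volume <- function(vol) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("`vol` must be a 3D array")
  median3d(vol, c(3, 3, 3))
}

#' Aggregate a difference volume to a percent-scale error map
#'
#' Collapses the (filtered) difference volume to the 2D error image
#' `L_S(m, n) = 100 * mean_i |vol(m, n, i)| / mean_i L_PAT(i)` — the mean
#' absolute spectral deviation of each pixel, expressed as a percentage of
#' the mean reference level so that thresholds like 30/20/10 percent are
#' dimensionally meaningful — and then smooths `L_S` with a plane median
#' filter (replicate padding).
#'
#' The default window scales with the image: a 30 x 30 plane filter suits a
#' 696 x 520 line-scan frame, so the default is the nearest odd integer to
#' `30 * sqrt(rows * cols) / sqrt(696 * 520)` — 29 at full acquisition
#' scale, 5 on a 96 x 96 test cube.  A fixed window would dominate (and
#' erode) any object on a spatially downscaled cube.  Note the plane median
#' rounds object corners by about half the window size; pass `window = 1`
#' to skip the smoothing.
#'
#' @inheritParams difference_volume
#' @param vol 3D array, normally the output of [median_filter_volume()].
#' @param window odd size of the 2D plane median window, or `NULL`
#'   (default) for the geometry-proportional size above.
#' @return Numeric matrix of per-pixel errors in percent.
#' @export
aggregate_error <- function(vol, pattern, window = NULL) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("`vol` must be a 3D array")
  p <- pattern_values(pattern, dim(vol)[3])
  pbar <- mean(p)
  if (pbar == 0) stop("reference spectrum has zero mean; percent scale undefined")
  if (is.null(window)) window <- plane_window_auto(dim(vol))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and >= 1")
  ls <- 100 * rowMeans(abs(vol), dims = 2L) / abs(pbar)
  d2 <- dim(ls)
  w <- min(window, if (d2[1] %% 2L) d2[1] else d2[1] - 1L,
           if (d2[2] %% 2L) d2[2] else d2[2] - 1L)
  half <- (w - 1L) %/% 2L
  out <- .median3d_cpp(array(ls, c(d2, 1L)), c(d2, 1L), half, half, 0L)
  out[, , 1]
}

# Geometry-proportional plane median window: 30 x 30 at the 696 x 520
# acquisition frame, scaled by the geometric-mean frame size (symmetric in
# rows/cols, so 90-degree rotations see the same window), rounded to odd.
plane_window_auto <- function(d) {
  round_to_odd(30 * sqrt(as.numeric(d[1]) * d[2]) / sqrt(696 * 520))
}

#' Whole-sequence 3D segmentation (S3D)
#'
#' Segments a cube from a user-marked region of interest: the reference
#' spectrum is averaged over the ROI, the signed difference volume is
#' 3D-median-filtered, aggregated to the percent-scale error map `L_S`, and
#' binarized from above at each requested threshold (upper-threshold
#' binarization: a pixel is accepted where its spectral error is *below* the
#' bound).  Decreasing thresholds give nested, stricter masks.
#'
#' @inheritParams extract_pattern_from_roi
#' @param thresholds strictly decreasing percentages in `(0, 100)`;
#'   default `c(30, 20, 10)`.
#' @param window plane median window passed to [aggregate_error()];
#'   `NULL` (default) for the geometry-proportional size.
#' @return Integer matrix of nested levels: a pixel's value is the number of
#'   thresholds it satisfies (0 = background, `length(thresholds)` = error
#'   below the strictest bound).  The binary mask at threshold `k` is
#'   `result >= k`.  Attribute `"thresholds"` records the bounds.
#' @examples
#' ph <- render_phantom(phantom_spec(rows = 48, cols = 48, bands = 16))
#' lc <- calibrate(median3d(ph$raw), ph$dark, ph$white)
#' lev <- s3d_segment(lc, roi = c(20, 27, 20, 27))
#' seg_scores(confusion(lev >= 2, ph$truth))   # mask at the 20 % bound
#' @export
s3d_segment <- function(cube, roi, thresholds = c(30, 20, 10), window = NULL) {
  if (length(thresholds) < 1L || any(thresholds <= 0) || any(thresholds >= 100))
    stop("`thresholds` must lie in (0, 100)")
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0))
    stop("`thresholds` must be strictly decreasing, e.g. c(30, 20, 10)")
  pattern <- extract_pattern_from_roi(cube, roi)
  vol <- median_filter_volume(difference_volume(cube, pattern))
  ls <- aggregate_error(vol, pattern, window = window)
  levels <- matrix(0L, nrow(ls), ncol(ls))
  for (k in seq_along(thresholds))
    levels <- levels + (ls <= thresholds[k])
  storage.mode(levels) <- "integer"
  structure(levels, thresholds = thresholds)
}
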