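#' Per-band relative difference against a reference spectrum
#'
#' For every pixel the measured emissivity curve is compared with the
#' reference waveform `L_PAT(i)` band by band:
#' `L_D(m, n, i) = (L(m, n, i) - L_PAT(i)) / L_PAT(i)`.
#' The cube and the reference must live in the same radiometric space (both
#' raw counts or both calibrated reflectance).
#'
#' @param cube a [hypercube()] or 3D array.
#' @param pattern a [ref_spectrum()] or numeric vector, one value per band,
#'   all values non-zero.
#' @return 3D array of signed relative differences.
#' @export
relative_difference <- function(cube, pattern) {
  v <- cube_values(cube)
  p <- pattern_values(pattern, dim(v)[3])
  zero <- which(p == 0)
  if (length(zero))
    stop("reference spectrum is zero at band(s) ",
         paste(utils::head(zero, 5L), collapse = ", "),
         "; cannot form relative differences")
  sweep(sweep(v, 3, p, "-"), 3, p, "/")
}

#' Count per-pixel tolerance exceedances
#'
#' Counts, for each pixel, the number of bands at which the relative
#' difference exceeds the tolerance `p_r`:
#' `L_R(m, n) = sum_i [ |L_D(m, n, i)| >= p_r ]`.
#'
#' The comparison is symmetric (absolute value) so under- and over-emission
#' both count as mismatch.  `rule = "literal"` instead flags bands with the
#' signed test `L_D < p_r`; it is provided for comparison but inverts the
#' error scale and is not recommended.
#'
#' @param diff 3D array of relative differences from [relative_difference()].
#' @param p_r positive tolerance on the relative difference (dimensionless;
#'   0.1 means a 10 percent deviation).
#' @param rule `"exceedance"` (default) or `"literal"` (see Details).
#' @return An object of class `"mismatch_map"`: list with integer matrix
#'   `counts`, the `p_r` used, and `bands_used`.
#' @export
count_mismatches <- function(diff, p_r, rule = c("exceedance", "literal")) {
  rule <- match.arg(rule)
  if (!is.numeric(p_r) || length(p_r) != 1L || p_r <= 0)
    stop("`p_r` must be a single positive tolerance")
  if (!is.array(diff) || length(dim(diff)) != 3L)
    stop("`diff` must be a 3D array")
  flags <- if (rule == "exceedance") abs(diff) >= p_r else diff < p_r
  counts <- rowSums(flags, dims = 2L)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, p_r = p_r, bands_used = dim(diff)[3]),
            class = "mismatch_map")
}

#' @export
print.mismatch_map <- function(x, ...) {
  cat(sprintf("<mismatch_map> %d x %d pixels, %d bands, p_r = %g; counts in [%d, %d]\n",
              nrow(x$counts), ncol(x$counts), x$bands_used, x$p_r,
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Convert mismatch counts to a grey-level error map
#'
#' Normalizes the mismatch counts to grey levels:
#' `L_V(m, n) = 1 - |L_R(m, n)| / max |L_R|`.
#' A value of 1 means a perfect match to the reference curve and 0 the
#' maximum observed error.  When no pixel has any mismatch the map is
#' identically 1.
#'
#' @param counts a `mismatch_map` from [count_mismatches()] (or a bare
#'   non-negative integer matrix).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
error_to_grey <- function(counts) {
  cmat <- if (inherits(counts, "mismatch_map")) counts$counts else as.matrix(counts)
  mx <- max(abs(cmat))
  if (mx == 0) return(array(1, dim(cmat)))
  1 - abs(cmat) / mx
}

#' Fast segmentation by emissivity-curve matching (SKE)
#'
#' Per-pixel screening segmentation: the relative difference against the
#' reference spectrum is computed at every band, tolerance exceedances are
#' counted, normalized to the grey-level error map `L_V`, and pixels with
#' `L_V >= bin_threshold` (good spectral match) become foreground.  The
#' method is purely per-pixel, so it can run on a cube holding only the
#' leading image rows obtained with [read_partial_rows()] — the fast
#' screening mode that needs only the start of a raw BIL file.
#'
#' @inheritParams relative_difference
#' @inheritParams count_mismatches
#' @param bin_threshold binarization threshold on the grey-level error map,
#'   in `(0, 1]`.  Larger values keep only better-matching pixels, so masks
#'   shrink (nest) as the threshold grows.
#' @return Integer 0/1 matrix, 1 = pixels matching the reference spectrum.
#' @examples
#' ph <- render_phantom(phantom_spec(rows = 48, cols = 48, bands = 16))
#' lc <- calibrate(median3d(ph$raw), ph$dark, ph$white)
#' mask <- ske_segment(lc, ph$spectra[[1]], p_r = 0.1, bin_threshold = 0.6)
#' seg_scores(confusion(mask, ph$truth))
#' @export
ske_segment <- function(cube, pattern, p_r = 0.1, bin_threshold = 0.6,
                        rule = c("exceedance", "literal")) {
  if (!is.numeric(bin_threshold) || length(bin_threshold) != 1L ||
      bin_threshold <= 0 || bin_threshold > 1)
    stop("`bin_threshold` must lie in (0, 1]")
  lv <- error_to_grey(count_mismatches(relative_difference(cube, pattern),
                                       p_r, rule = match.arg(rule)))
  mask <- lv >= bin_threshold
  storage.mode(mask) <- "integer"
  mask
}
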