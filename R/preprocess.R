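#' 3D median filtering of a hyperspectral cube
#'
#' Replaces each voxel by the median of its `mask[1] x mask[2] x mask[3]`
#' neighbourhood (rows x cols x bands), with replicate padding at all
#' borders.  The default 3x3x3 mask is sized to remove single-voxel artifacts
#' no larger than about 4 pixels, the typical speck size of line-scan
#' acquisitions; the filtered cube is the `L_MED` stage that precedes
#' calibration.
#'
#' @param cube a [hypercube()] or 3D array.
#' @param mask integer triple of odd window sizes `(rows, cols, bands)`,
#'   each `>= 1` and no larger than the corresponding cube dimension.
#' @return A filtered cube of the same class and dimensions as the input.
#' @seealso [adaptive_median()] for a band-dependent in-plane mask,
#'   [calibrate()] for the subsequent reflectance normalization.
#' @examples
#' x <- array(10, c(5, 5, 5)); x[3, 3, 3] <- 4000   # isolated spike
#' f <- median3d(x)
#' f[3, 3, 3]   # spike removed
#' @export
median3d <- function(cube, mask = c(3, 3, 3)) {
  v <- cube_values(cube)
  mask <- as.integer(mask)
  if (length(mask) != 3L) stop("`mask` must be a triple (rows, cols, bands)")
  if (any(mask < 1L) || any(mask %% 2L == 0L))
    stop("median mask dimensions must be odd and >= 1, got (",
         paste(mask, collapse = ", "), ")")
  d <- dim(v)
  if (any(mask > d))
    stop("median mask exceeds cube dimensions")
  out <- .median3d_cpp(v, d,
                       rep((mask[1] - 1L) %/% 2L, d[3]),
                       rep((mask[2] - 1L) %/% 2L, d[3]),
                       (mask[3] - 1L) %/% 2L)
  cube_like(out, cube)
}

round_to_odd <- function(x) {
  k <- 2L * as.integer(round((x - 1) / 2)) + 1L
  pmax(k, 1L)
}

# Per-band in-plane window sizes: edge_size at the first and last band,
# mid_size at the central band, linear in |i - center|, rounded to odd.
adaptive_sizes <- function(bands, edge_size, mid_size) {
  if (bands == 1L) return(as.integer(mid_size))
  centre <- (bands - 1) / 2
  frac <- abs(seq_len(bands) - 1 - centre) / centre
  round_to_odd(mid_size + (edge_size - mid_size) * frac)
}

#' Band-adaptive median filtering
#'
#' Line-scan hyperspectral cameras are noisiest in the 2D images at the
#' extremes of their spectral range.  This filter therefore enlarges the
#' in-plane median window from `mid_size x mid_size` at the central band up
#' to `edge_size x edge_size` at the first and last band, interpolating
#' linearly in band index and rounding to the nearest odd size; the spectral
#' extent of the window is fixed.
#'
#' @inheritParams median3d
#' @param edge_size odd in-plane window size at the band extremes (default 7).
#' @param mid_size odd in-plane window size at the central band (default 3).
#' @param spectral_extent odd number of bands included in every window
#'   (default 3).
#' @return A filtered cube of the same class and dimensions as the input.
#' @export
adaptive_median <- function(cube, edge_size = 7L, mid_size = 3L,
                            spectral_extent = 3L) {
  edge_size <- as.integer(edge_size); mid_size <- as.integer(mid_size)
  spectral_extent <- as.integer(spectral_extent)
  if (edge_size < mid_size || mid_size < 1L)
    stop("need edge_size >= mid_size >= 1")
  if (any(c(edge_size, mid_size, spectral_extent) %% 2L == 0L))
    stop("mask sizes must be odd")
  v <- cube_values(cube)
  d <- dim(v)
  sizes <- adaptive_sizes(d[3], edge_size, mid_size)
  if (max(sizes) > min(d[1], d[2]) || spectral_extent > d[3])
    stop("adaptive mask exceeds cube dimensions")
  half <- (sizes - 1L) %/% 2L
  out <- .median3d_cpp(v, d, half, half, (spectral_extent - 1L) %/% 2L)
  cube_like(out, cube)
}

#' Dark/white reflectance calibration
#'
#' Conventional normalization of a (denoised) raw cube between a shuttered
#' dark reference and a uniform-reflectance white reference:
#' `L_C = (L - L_DARK) / (L_WHITE - L_DARK)`, clipped to `[0, 1]`.  Where the
#' white and dark references coincide the ratio is undefined; those voxels
#' are set to 0 and counted in a single warning.
#'
#' @param cube cube to calibrate (typically the output of [median3d()] or
#'   [adaptive_median()]).
#' @param dark,white reference cubes of the same dimensions.
#' @return The calibrated reflectance cube `L_C`, values in `[0, 1]`
#'   (`dtype` becomes `"float32"` for [hypercube()] input).
#' @export
calibrate <- function(cube, dark, white) {
  v <- cube_values(cube); dk <- cube_values(dark, "dark"); wt <- cube_values(white, "white")
  if (!identical(dim(v), dim(dk)) || !identical(dim(v), dim(wt)))
    stop("cube, dark and white must share dimensions")
  den <- wt - dk
  bad <- den == 0
  den[bad] <- 1
  out <- (v - dk) / den
  if (any(bad)) {
    out[bad] <- 0
    warning(sum(bad), " voxel(s) had white == dark; set to 0")
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  cube_like(out, cube, dtype = "float32")
}
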