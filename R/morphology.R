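#' Parameters for conditional morphology
#'
#' The stabilization stage corrects each band's binary mask with erosion and
#' dilation gated by the local mean brightness of that band.  The
#' structuring element and the mean window share the same `mask_rows x
#' mask_cols` size (default 17x17); `p_ec` and `p_dc` are the brightness
#' gates in `[0, 1]`, set once per camera (default 0.5 for a visible/NIR
#' line-scan system).
#'
#' @param mask_rows,mask_cols odd positive window sizes; default 17.
#' @param p_ec dilation gate: dilation is applied only where the local mean
#'   is `<= p_ec` (dark surroundings).
#' @param p_dc erosion gate: erosion is applied only where the local mean is
#'   `>= p_dc` (bright surroundings).
#' @return A list of class `"morph_params"`.
#' @export
morph_params <- function(mask_rows = 17L, mask_cols = mask_rows,
                         p_ec = 0.5, p_dc = 0.5) {
  mask_rows <- as.integer(mask_rows); mask_cols <- as.integer(mask_cols)
  if (mask_rows < 1L || mask_cols < 1L ||
      mask_rows %% 2L == 0L || mask_cols %% 2L == 0L)
    stop("structuring element dimensions must be odd and positive")
  if (p_ec < 0 || p_ec > 1 || p_dc < 0 || p_dc > 1)
    stop("`p_ec` and `p_dc` must lie in [0, 1]")
  structure(list(mask_rows = mask_rows, mask_cols = mask_cols,
                 p_ec = p_ec, p_dc = p_dc),
            class = "morph_params")
}

as_binary_matrix <- function(mask, arg = "mask") {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1, FALSE, TRUE)))
    stop("`", arg, "` must be binary (0/1)")
  storage.mode(mask) <- "integer"
  mask
}

#' Windowed local mean of a band image
#'
#' `p_c(m, n) = (1 / (M_S * N_S)) * sum` of the band values over the
#' `M_S x N_S` window centred at `(m, n)`, replicate padding.  The band must
#' be normalized to `[0, 1]` (12-bit raw counts divided by `2^bits - 1`, or
#' already-calibrated reflectance); the result gates the conditional
#' morphology.
#'
#' @param band 2D numeric matrix with values in `[0, 1]`.
#' @param params a [morph_params()].
#' @return Numeric matrix of local means.
#' @export
local_mean <- function(band, params = morph_params()) {
  band <- as.matrix(band)
  if (min(band) < 0 || max(band) > 1)
    stop("`band` must be normalized to [0, 1]; divide raw counts by 2^bits - 1")
  .local_mean_cpp(band, (params$mask_rows - 1L) %/% 2L,
                  (params$mask_cols - 1L) %/% 2L)
}

#' Conditional erosion and dilation
#'
#' Morphological min/max over the structuring element applied only where a
#' local-mean brightness gate holds, the pixel being copied unchanged
#' elsewhere:
#'
#' * erosion: `out(m, n) = mask(m, n)` where `p_c(m, n) < p_dc`, otherwise
#'   the minimum of the mask over the structuring element — erosion acts
#'   only in bright surroundings, removing spurious specks there;
#' * dilation: `out(m, n) = mask(m, n)` where `p_c(m, n) > p_ec`, otherwise
#'   the maximum over the structuring element — dilation acts only in dark
#'   surroundings, filling drop-outs of the (darker) object.
#'
#' With `p_dc = 0` conditional erosion reduces to plain erosion and with
#' `p_ec = 1` conditional dilation reduces to plain dilation; with
#' `p_dc = 1` / `p_ec = 0` they are the identity.
#'
#' @param mask binary 0/1 matrix.
#' @param p_c local-mean gate image from [local_mean()], same shape.
#' @param params a [morph_params()].
#' @return Binary integer matrix of the same shape.
#' @export
conditional_erosion <- function(mask, p_c, params = morph_params()) {
  mask <- as_binary_matrix(mask)
  p_c <- as.matrix(p_c)
  if (!identical(dim(mask), dim(p_c)))
    stop("`mask` and `p_c` must share dimensions")
  eroded <- .morph_cpp(mask, (params$mask_rows - 1L) %/% 2L,
                       (params$mask_cols - 1L) %/% 2L, FALSE)
  out <- mask
  act <- p_c >= params$p_dc
  out[act] <- eroded[act]
  out
}

#' @rdname conditional_erosion
#' @export
conditional_dilation <- function(mask, p_c, params = morph_params()) {
  mask <- as_binary_matrix(mask)
  p_c <- as.matrix(p_c)
  if (!identical(dim(mask), dim(p_c)))
    stop("`mask` and `p_c` must share dimensions")
  dilated <- .morph_cpp(mask, (params$mask_rows - 1L) %/% 2L,
                        (params$mask_cols - 1L) %/% 2L, TRUE)
  out <- mask
  act <- p_c <= params$p_ec
  out[act] <- dilated[act]
  out
}

#' Stabilize a stack of per-band masks with conditional morphology
#'
#' The object segmented from a spectral sequence should keep a consistent
#' shape from band to band, but the noisy border bands add spurious
#' components and punch holes into the true object.  For each band `i` in
#' order this routine computes the local-mean gate `p_c` from band `i` of the
#' (normalized) cube and applies conditional erosion then conditional
#' dilation (order configurable) to mask `i`: specks in bright surroundings
#' are eroded away and drop-outs in dark surroundings are filled, while
#' pixels whose gate does not fire are copied bit-exactly.
#'
#' @param masks binary 3D array `(rows, cols, bands)` of per-band masks.
#' @param cube the cube the masks came from, same dimensions.  Raw integer
#'   cubes are normalized by `2^bits - 1` before the gate is computed;
#'   calibrated cubes in `[0, 1]` are used as-is.
#' @param params a [morph_params()].
#' @param order `"erode_dilate"` (default, equation order) or
#'   `"dilate_erode"`.
#' @return Binary 3D array of corrected masks.
#' @seealso [sh_segment()], which applies this stage before its across-band
#'   majority vote.
#' @export
stabilize_stack <- function(masks, cube, params = morph_params(),
                            order = c("erode_dilate", "dilate_erode")) {
  order <- match.arg(order)
  v <- cube_values(cube)
  if (!is.array(masks) || length(dim(masks)) != 3L)
    stop("`masks` must be a 3D array of per-band masks")
  if (!identical(dim(masks), dim(v)))
    stop("mask stack has ", dim(masks)[3], " band(s) but the cube has ",
         dim(v)[3])
  if (max(v) > 1) {
    bits <- if (inherits(cube, "hypercube")) cube$bits else 12L
    v <- v / (2^bits - 1)
  }
  out <- array(0L, dim(masks))
  for (i in seq_len(dim(v)[3])) {
    p_c <- local_mean(v[, , i], params)
    m <- as_binary_matrix(masks[, , i])
    m <- if (order == "erode_dilate") {
      conditional_dilation(conditional_erosion(m, p_c, params), p_c, params)
    } else {
      conditional_erosion(conditional_dilation(m, p_c, params), p_c, params)
    }
    out[, , i] <- m
  }
  out
}
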