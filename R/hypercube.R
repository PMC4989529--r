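#' Hyperspectral cube objects
#'
#' A `hypercube` wraps a numeric 3D array `values[m, n, i]` (rows x columns x
#' bands) together with its wavelength axis and storage metadata (on-disk
#' element type, byte order, interleave, detector dynamic range).  It is the
#' in-memory form of the raw `L_GRAY`, denoised `L_MED` and calibrated `L_C`
#' cubes.
#'
#' @param values numeric 3D array, dimensions `(rows, cols, bands)`.  All
#'   values must be finite; for integer storage types they must lie in
#'   `[0, 2^bits - 1]`.
#' @param wavelengths numeric vector of band-center wavelengths in micrometres,
#'   strictly increasing, one per band.  Defaults to an evenly spaced axis
#'   over 0.4–1.0 um, the range of a visible/NIR line-scan camera.
#' @param dtype on-disk element type: `"uint16"` (default; a 12-bit detector
#'   stored in 16-bit words), `"uint8"` or `"float32"`.
#' @param byte_order `"little"` (default) or `"big"`.
#' @param interleave canonical file layout, `"bil"` (default) or `"bsq"`.
#' @param bits detector dynamic range in bits, in `[8, 16]`; default 12.
#' @return An object of class `"hypercube"`.
#' @examples
#' cube <- hypercube(array(100, c(4, 5, 3)))
#' dim(cube)
#' @export
hypercube <- function(values, wavelengths = NULL, dtype = "float32",
                      byte_order = "little", interleave = "bil", bits = 12L) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (rows x cols x bands)")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("cube values must all be finite")
  d <- dim(values)
  dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
  byte_order <- match.arg(byte_order, c("little", "big"))
  interleave <- match.arg(tolower(interleave), c("bil", "bsq"))
  bits <- as.integer(bits)
  if (bits < 8L || bits > 16L)
    stop("`bits` must lie in [8, 16]")
  if (is.null(wavelengths))
    wavelengths <- seq(0.4, 1.0, length.out = d[3])
  if (length(wavelengths) != d[3])
    stop("`wavelengths` must have one entry per band (", d[3], ")")
  if (d[3] > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (dtype != "float32") {
    full <- 2^bits - 1
    if (min(values) < 0 || max(values) > full)
      stop("integer cube values must lie in [0, ", full, "]")
  }
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths),
         dtype = dtype, byte_order = byte_order, interleave = interleave,
         bits = bits),
    class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d x %d (rows x cols x bands), %s %s-endian %s\n",
              d[1], d[2], d[3], x$dtype, x$byte_order, toupper(x$interleave)))
  cat(sprintf("  wavelengths: %.3f-%.3f um; dynamic range %d bit; values in [%.4g, %.4g]\n",
              min(x$wavelengths), max(x$wavelengths), x$bits,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.array.hypercube <- function(x, ...) x$values

#' Display one band of a cube as an image
#'
#' @param x a [hypercube()].
#' @param band band index (1-based); defaults to the middle band.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted band matrix.
#' @export
plot.hypercube <- function(x, band = NULL, ...) {
  if (is.null(band)) band <- max(1L, dim(x$values)[3] %/% 2L)
  b <- x$values[, , band]
  # flip rows so the first image row appears at the top
  graphics::image(t(b[nrow(b):1, , drop = FALSE]), asp = nrow(b) / ncol(b),
                  axes = FALSE, useRaster = TRUE,
                  col = grDevices::gray.colors(256, 0, 1),
                  main = sprintf("band %d (%.3f um)", band, x$wavelengths[band]),
                  ...)
  invisible(b)
}

# Accept a hypercube or a bare 3D array; return the values array.
cube_values <- function(x, arg = "cube") {
  if (inherits(x, "hypercube")) return(x$values)
  if (is.array(x) && length(dim(x)) == 3L) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop("`", arg, "` must be a hypercube or a 3D array")
}

# Rebuild a cube like `template` with new values (dtype switches to float32
# when values are no longer integral counts).
cube_like <- function(values, template, dtype = NULL) {
  if (inherits(template, "hypercube")) {
    hypercube(values, wavelengths = template$wavelengths,
              dtype = dtype %||% template$dtype,
              byte_order = template$byte_order,
              interleave = template$interleave, bits = template$bits)
  } else values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference emissivity spectra
#'
#' A reference spectrum `L_PAT(i)` holds the expected per-band emissivity of
#' the target material, sampled on the same wavelength grid as the cube it is
#' compared against.
#'
#' @param values numeric vector of per-band reference values, finite.
#' @param wavelengths optional numeric vector of wavelengths in micrometres,
#'   strictly increasing, same length as `values`.
#' @return An object of class `"ref_spectrum"`.
#' @seealso [extract_pattern_from_roi()] to average a reference over a region
#'   of interest, [read_spectrum()]/[write_spectrum()] for CSV interchange.
#' @export
ref_spectrum <- function(values, wavelengths = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values)))
    stop("reference spectrum values must be finite and non-empty")
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != length(values))
      stop("`wavelengths` and `values` must have the same length")
    if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
      stop("`wavelengths` must be strictly increasing")
  }
  structure(list(values = values, wavelengths = wavelengths),
            class = "ref_spectrum")
}

#' @export
print.ref_spectrum <- function(x, ...) {
  cat(sprintf("<ref_spectrum> %d bands, values in [%.4g, %.4g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.ref_spectrum <- function(x) length(x$values)

# Accept a ref_spectrum or bare numeric vector; check length against bands.
pattern_values <- function(pattern, bands = NULL) {
  v <- if (inherits(pattern, "ref_spectrum")) pattern$values else as.numeric(pattern)
  if (!all(is.finite(v))) stop("reference spectrum must be finite")
  if (!is.null(bands) && length(v) != bands)
    stop("reference spectrum has ", length(v), " bands but the cube has ", bands)
  v
}

#' Read and write reference spectra as two-column CSV
#'
#' The interchange format is a CSV with columns `wavelength_um` and `value`.
#'
#' @param path file path.
#' @return `read_spectrum()` returns a [ref_spectrum()]; `write_spectrum()`
#'   invisibly returns `path`.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_um", "value") %in% names(df)))
    stop("spectrum CSV must have columns `wavelength_um` and `value`")
  ref_spectrum(df$value, df$wavelength_um)
}

#' @param spectrum a [ref_spectrum()] with a wavelength axis.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  if (!inherits(spectrum, "ref_spectrum") || is.null(spectrum$wavelengths))
    stop("`spectrum` must be a ref_spectrum with wavelengths")
  utils::write.csv(data.frame(wavelength_um = spectrum$wavelengths,
                              value = spectrum$values),
                   path, row.names = FALSE)
  invisible(path)
}
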