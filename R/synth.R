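#' Analytic spectrum models for phantoms
#'
#' A spectrum model is a positive baseline plus a sum of Gaussian peaks:
#' `curve(lambda) = baseline + sum_k amp_k * exp(-(lambda - c_k)^2 / (2 w_k^2))`.
#' Gaussian mixtures give smooth emissivity-like curves whose local maxima
#' exist at known positions and are therefore controllable — which matters
#' when the curve serves as the reference waveform of the hierarchical
#' method, where at least three distinct local maxima are needed.
#'
#' @param baseline constant reflectance offset.
#' @param centers,widths,amplitudes equal-length numeric vectors of peak
#'   centres (um), widths (um, Gaussian sigma) and amplitudes (may be
#'   negative for absorption-like dips, as long as the curve stays positive).
#' @return A list of class `"spectrum_model"`.
#' @export
spectrum_model <- function(baseline, centers = numeric(), widths = numeric(),
                           amplitudes = numeric()) {
  if (length(centers) != length(widths) ||
      length(centers) != length(amplitudes))
    stop("`centers`, `widths` and `amplitudes` must have equal length")
  if (any(widths <= 0)) stop("peak widths must be positive")
  structure(list(baseline = baseline, centers = as.numeric(centers),
                 widths = as.numeric(widths),
                 amplitudes = as.numeric(amplitudes)),
            class = "spectrum_model")
}

#' Sample a spectrum model on a wavelength grid
#'
#' @param model a [spectrum_model()].
#' @param wavelengths numeric vector of band wavelengths in micrometres.
#' @return A [ref_spectrum()].  The sampled curve must be strictly positive.
#' @export
make_spectrum <- function(model, wavelengths) {
  stopifnot(inherits(model, "spectrum_model"))
  v <- rep(model$baseline, length(wavelengths))
  for (k in seq_along(model$centers))
    v <- v + model$amplitudes[k] *
      exp(-(wavelengths - model$centers[k])^2 / (2 * model$widths[k]^2))
  if (any(v <= 0))
    stop("spectrum model is non-positive at some sampled wavelength")
  ref_spectrum(v, wavelengths)
}

#' Band-edge-amplified noise profile
#'
#' Hyperspectral cameras are noisiest at the extremes of their spectral
#' range.  The per-band noise standard deviation ramps linearly from
#' `sigma_mid * edge_gain` at the first and last band down to `sigma_mid`
#' at the central band.
#'
#' @param bands number of bands.
#' @param sigma_mid mid-band noise SD, as a fraction of full scale.
#' @param edge_gain multiplier at the band extremes, `>= 1`.
#' @return Numeric vector of per-band standard deviations.
#' @export
band_edge_noise_profile <- function(bands, sigma_mid, edge_gain) {
  if (edge_gain < 1) stop("`edge_gain` must be >= 1")
  if (sigma_mid < 0) stop("`sigma_mid` must be >= 0")
  bands <- as.integer(bands)
  if (bands == 1L) return(sigma_mid)
  centre <- (bands - 1) / 2
  frac <- abs(seq_len(bands) - 1 - centre) / centre
  sigma_mid * (1 + (edge_gain - 1) * frac)
}

#' Phantom object shapes
#'
#' Shapes are rasterized on the phantom grid: `shape_ellipse()` an axis-
#' aligned ellipse, `shape_rectangle()` an axis-aligned rectangle (1-based
#' inclusive bounds), and `shape_blob()` a hand-like blob (a palm ellipse
#' with three finger lobes).
#'
#' @param center_row,center_col,radius_row,radius_col ellipse geometry in
#'   pixels.
#' @return A list of class `"phantom_shape"`.
#' @export
shape_ellipse <- function(center_row, center_col, radius_row, radius_col) {
  structure(list(type = "ellipse", cr = center_row, cc = center_col,
                 rr = radius_row, rc = radius_col),
            class = "phantom_shape")
}

#' @param row_start,row_end,col_start,col_end rectangle bounds, 1-based
#'   inclusive.
#' @rdname shape_ellipse
#' @export
shape_rectangle <- function(row_start, row_end, col_start, col_end) {
  structure(list(type = "rectangle", r1 = row_start, r2 = row_end,
                 c1 = col_start, c2 = col_end),
            class = "phantom_shape")
}

#' @param scale overall blob size in pixels (palm radius).
#' @rdname shape_ellipse
#' @export
shape_blob <- function(center_row, center_col, scale) {
  structure(list(type = "blob", cr = center_row, cc = center_col, s = scale),
            class = "phantom_shape")
}

rasterize_shape <- function(shape, rows, cols) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ellipse <- function(cr, cc, rr, rc)
    ((r - cr) / rr)^2 + ((c - cc) / rc)^2 <= 1
  m <- switch(shape$type,
    ellipse = ellipse(shape$cr, shape$cc, shape$rr, shape$rc),
    rectangle = r >= shape$r1 & r <= shape$r2 & c >= shape$c1 & c <= shape$c2,
    blob = {
      palm <- ellipse(shape$cr, shape$cc, shape$s, 0.8 * shape$s)
      f <- shape$s
      fingers <- ellipse(shape$cr - 1.1 * f, shape$cc - 0.45 * f, 0.55 * f, 0.16 * f) |
        ellipse(shape$cr - 1.25 * f, shape$cc, 0.65 * f, 0.16 * f) |
        ellipse(shape$cr - 1.1 * f, shape$cc + 0.45 * f, 0.55 * f, 0.16 * f)
      palm | fingers
    },
    stop("unknown shape type: ", shape$type))
  m * 1L
}

#' Phantom specifications
#'
#' Describes a synthetic hyperspectral phantom: geometry, wavelength range,
#' object shapes and spectra, background spectrum, the band-edge-amplified
#' noise model, artifact injection and detector dynamic range.  The default
#' is a 96 x 96 x 32 cube spanning 0.4–1.0 um — a test-scale cut-down of a
#' 696 x 520 x 128 12-bit line-scan acquisition (set `rows`, `cols` and
#' `bands` to those values to reproduce the full geometry) — containing one
#' elliptical object of moderate reflectance (mean about 0.30) with three
#' spectral peaks, on a bright background with the complementary spectrum
#' (`1 - object`, mean about 0.70).  The complementary pair keeps the
#' mid-brightness 0.5 contour on the true object boundary at every band,
#' the regime the conditional-morphology gates `p_ec = p_dc = 0.5` presume.
#'
#' @param rows,cols,bands cube geometry; defaults 96, 96, 32.
#' @param wavelength_range two-element range in micrometres; default
#'   `c(0.4, 1.0)`.
#' @param objects list of `list(shape = , spectrum = )` entries
#'   ([shape_ellipse()] etc. and [spectrum_model()]); shapes must be
#'   disjoint.  Default: one ellipse.
#' @param background_spectrum [spectrum_model()] for the background.
#' @param noise_sigma_mid mid-band Gaussian noise SD as a fraction of full
#'   scale; default 0.008 (about 33 counts of a 12-bit range).
#' @param noise_edge_gain noise multiplier at the band extremes; default 3.
#' @param artifact_count number of small specks injected into the raw cube;
#'   default 10.
#' @param artifact_max_px maximum in-plane artifact size in pixels;
#'   default 4.
#' @param bits detector dynamic range; default 12.
#' @param seed RNG seed making the phantom deterministic; default 1.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(rows = 96L, cols = 96L, bands = 32L,
                         wavelength_range = c(0.4, 1.0),
                         objects = NULL, background_spectrum = NULL,
                         noise_sigma_mid = 0.008, noise_edge_gain = 3,
                         artifact_count = 10L, artifact_max_px = 4L,
                         bits = 12L, seed = 1L) {
  if (is.null(objects)) {
    obj_model <- spectrum_model(0.26,
                                centers = c(0.52, 0.68, 0.86),
                                widths = c(0.04, 0.04, 0.04),
                                amplitudes = c(0.09, 0.11, 0.08))
    objects <- list(list(
      shape = shape_ellipse(round(rows * 0.48), round(cols * 0.52),
                            round(rows * 0.31), round(cols * 0.25)),
      spectrum = obj_model))
  }
  if (is.null(background_spectrum)) {
    ob <- objects[[1]]$spectrum
    background_spectrum <- spectrum_model(1 - ob$baseline, ob$centers,
                                          ob$widths, -ob$amplitudes)
  }
  if (noise_sigma_mid < 0 || noise_edge_gain < 1)
    stop("invalid noise parameters")
  if (artifact_max_px < 1L || artifact_max_px > 4L)
    stop("`artifact_max_px` must lie in [1, 4]")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 bands = as.integer(bands),
                 wavelength_range = wavelength_range,
                 objects = objects,
                 background_spectrum = background_spectrum,
                 noise_sigma_mid = noise_sigma_mid,
                 noise_edge_gain = noise_edge_gain,
                 artifact_count = as.integer(artifact_count),
                 artifact_max_px = as.integer(artifact_max_px),
                 bits = as.integer(bits), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render a synthetic phantom acquisition
#'
#' Builds the reflectance field from the object and background spectra,
#' pushes it through a linear camera model (dark offset at 3 percent and
#' white response at 92 percent of full scale, both quantized to whole
#' counts), adds per-band Gaussian noise following
#' [band_edge_noise_profile()], injects small saturated-or-dead specks into
#' the raw cube, and quantizes to the detector's dynamic range.  The dark
#' and white reference cubes carry one quarter of the scene noise,
#' emulating references averaged over repeated acquisitions.  Output is
#' deterministic for a fixed `seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with [hypercube()]s `raw`, `dark` and `white`, the
#'   integer ground-truth `truth` (0 = background, k = k-th object), the
#'   per-object reference `spectra` (list of [ref_spectrum()]), the
#'   `background` spectrum, and `wavelengths`.
#' @examples
#' ph <- render_phantom(phantom_spec(rows = 32, cols = 32, bands = 8))
#' table(ph$truth)
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$rows; N <- spec$cols; I <- spec$bands
  wl <- seq(spec$wavelength_range[1], spec$wavelength_range[2], length.out = I)
  full <- 2^spec$bits - 1

  truth <- matrix(0L, M, N)
  spectra <- vector("list", length(spec$objects))
  for (k in seq_along(spec$objects)) {
    m <- rasterize_shape(spec$objects[[k]]$shape, M, N)
    if (any(truth[m == 1L] != 0L)) stop("phantom objects overlap")
    truth[m == 1L] <- k
    spectra[[k]] <- make_spectrum(spec$objects[[k]]$spectrum, wl)
  }
  background <- make_spectrum(spec$background_spectrum, wl)

  refl <- array(0, c(M, N, I))
  for (i in seq_len(I)) {
    plane <- matrix(background$values[i], M, N)
    for (k in seq_along(spectra))
      plane[truth == k] <- spectra[[k]]$values[i]
    refl[, , i] <- plane
  }

  dark_dn <- round(0.03 * full)
  white_dn <- round(0.92 * full)
  sigma <- band_edge_noise_profile(I, spec$noise_sigma_mid, spec$noise_edge_gain)

  with_seed(spec$seed, {
    noise_of <- function(scale) {
      e <- array(stats::rnorm(M * N * I), c(M, N, I))
      sweep(e, 3, sigma * full * scale, "*")
    }
    raw <- dark_dn + refl * (white_dn - dark_dn) + noise_of(1)
    dark <- dark_dn + noise_of(0.25)
    white <- white_dn + noise_of(0.25)

    if (spec$artifact_count > 0L) {
      offs <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))  # within a 2x2 tile
      for (a in seq_len(spec$artifact_count)) {
        m0 <- sample.int(M - 1L, 1L); n0 <- sample.int(N - 1L, 1L)
        i0 <- sample.int(I, 1L)
        npx <- sample.int(spec$artifact_max_px, 1L)
        val <- if (stats::runif(1) < 0.5) 0 else full
        for (j in seq_len(npx))
          raw[m0 + offs[j, 1], n0 + offs[j, 2], i0] <- val
      }
    }
    NULL
  })

  quantize <- function(x) {
    x <- round(x)
    x[x < 0] <- 0; x[x > full] <- full
    x
  }
  as_cube <- function(x)
    hypercube(quantize(x), wavelengths = wl, dtype = "uint16",
              byte_order = "little", interleave = "bil", bits = spec$bits)

  list(raw = as_cube(raw), dark = as_cube(dark), white = as_cube(white),
       truth = truth, spectra = spectra, background = background,
       wavelengths = wl)
}
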