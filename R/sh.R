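#' Reduce a cube's spatial resolution by block-mean pooling
#'
#' Averages each band over `factor x factor` in-plane blocks (an M x N image
#' becomes roughly M/8 x N/8 at the default factor), suppressing noise at
#' the same time as shrinking the clustering problem.  Trailing partial
#' blocks are averaged over their actual extent.
#'
#' @param cube a [hypercube()] or 3D array.
#' @param factor positive integer block size; default 8.
#' @return A reduced cube of the same class.
#' @export
downsample_cube <- function(cube, factor = 8L) {
  v <- cube_values(cube)
  factor <- as.integer(factor)
  d <- dim(v)
  if (factor < 1L) stop("`factor` must be >= 1")
  if (factor > min(d[1], d[2]))
    stop("`factor` exceeds the in-plane cube dimensions")
  if (factor == 1L) return(cube)
  gr <- as.integer(ceiling(seq_len(d[1]) / factor))
  gc <- as.integer(ceiling(seq_len(d[2]) / factor))
  nr <- max(gr); nc <- max(gc)
  out <- array(0, c(nr, nc, d[3]))
  for (i in seq_len(d[3])) {
    s <- rowsum(v[, , i], gr)                      # sum rows into blocks
    s <- t(rowsum(t(s), gc))                       # then columns
    out[, , i] <- s / outer(tabulate(gr, nr), tabulate(gc, nc))
  }
  cube_like(out, cube)
}

#' Locate the principal local maxima of a reference spectrum
#'
#' Finds interior local maxima of the reference waveform (bands `i` with
#' `pattern[i-1] < pattern[i] >= pattern[i+1]`; a flat-topped peak is
#' reported at its leftmost band), ranks them by height and returns the top
#' `count` in ascending band order.  These are the bands at which spectral
#' mismatch features are extracted for clustering.
#'
#' @param pattern a [ref_spectrum()] or numeric vector with at least 3 bands.
#' @param count number of maxima requested; default 3.  If fewer exist, all
#'   are returned with a warning.
#' @return Integer vector of band indices (1-based), strictly increasing.
#' @export
find_local_maxima <- function(pattern, count = 3L) {
  p <- pattern_values(pattern)
  if (length(p) < 3L) stop("pattern needs at least 3 bands")
  i <- 2:(length(p) - 1L)
  is_max <- p[i - 1L] < p[i] & p[i] >= p[i + 1L]
  peaks <- i[is_max]
  if (length(peaks) == 0L)
    stop("pattern has no interior local maximum (monotone waveform); ",
         "select feature bands manually")
  count <- as.integer(count)
  if (length(peaks) < count) {
    warning("only ", length(peaks), " local maxima available (requested ",
            count, ")")
    count <- length(peaks)
  }
  sort(peaks[order(p[peaks], decreasing = TRUE)][seq_len(count)])
}

#' Extract spectral mismatch features at peak bands
#'
#' For each pixel the features are the absolute deviations from the
#' reference waveform at the selected bands:
#' `w_k(m, n) = |L(m, n, i_k) - L_PAT(i_k)|`.  A pixel of the target
#' material sits near the origin of feature space; other materials are
#' pushed away along one or more axes.
#'
#' @param cube a [hypercube()] or 3D array (normally the downsampled cube).
#' @param pattern a [ref_spectrum()] or numeric vector, one value per band.
#' @param peak_bands integer band indices from [find_local_maxima()].
#' @return An object of class `"feature_stack"`: list with `features`
#'   (pixels x F matrix), `dim` (rows, cols) and `peak_bands`.
#' @export
extract_features <- function(cube, pattern, peak_bands) {
  v <- cube_values(cube)
  p <- pattern_values(pattern, dim(v)[3])
  peak_bands <- as.integer(peak_bands)
  if (any(peak_bands < 1L) || any(peak_bands > dim(v)[3]))
    stop("`peak_bands` out of range")
  f <- vapply(peak_bands,
              function(i) as.vector(abs(v[, , i] - p[i])),
              numeric(dim(v)[1] * dim(v)[2]))
  structure(list(features = f, dim = dim(v)[1:2], peak_bands = peak_bands),
            class = "feature_stack")
}

feature_matrix <- function(features) {
  if (inherits(features, "feature_stack")) features$features
  else as.matrix(features)
}

# Dispersion criterion of a k-means partition.  "sem" is the standard error
# of the class means (mean over classes of sd_k / sqrt(n_k)): it penalizes
# both merged clusters (large sd) and needlessly split ones (small n), so it
# attains its minimum at the true class count on separated groups.  "sd"
# (mean within-class standard deviation) and "mse" (mean within-class mean
# squared deviation) are provided for comparison; both decrease essentially
# monotonically with K.
partition_dispersion <- function(km, criterion) {
  sd_k <- sqrt(km$withinss / km$size)
  switch(criterion,
         sem = mean(sd_k / sqrt(km$size)),
         sd  = mean(sd_k),
         mse = mean(km$withinss / km$size))
}

#' Cluster pixels in mismatch-feature space
#'
#' Centroid-based (k-means) partition of the per-pixel feature vectors into
#' `K` classes, with multiple restarts under a fixed seed for a
#' deterministic result; the restart with the smallest within-class sum of
#' squares is kept.  The reported `dispersion` is the class-count selection
#' criterion (see [select_class_count()]).
#'
#' @param features a `feature_stack` from [extract_features()] (or a bare
#'   pixels x F matrix).
#' @param K number of classes, 2–5.
#' @param nstart k-means restarts; default 10.
#' @param seed RNG seed for the restarts; default 1.
#' @param criterion dispersion criterion: `"sem"` (default; standard error
#'   of the class means), `"sd"` or `"mse"`.
#' @return An object of class `"hs_clustering"`: list with `labels`
#'   (integer matrix of classes 1..K when the input carries image
#'   dimensions, otherwise a vector), `K`, `dispersion`, `centers` and
#'   `criterion`.
#' @export
cluster_pixels <- function(features, K, nstart = 10L, seed = 1L,
                           criterion = c("sem", "sd", "mse")) {
  criterion <- match.arg(criterion)
  f <- feature_matrix(features)
  K <- as.integer(K)
  if (K < 2L || K > 5L) stop("`K` must lie in [2, 5]")
  ndistinct <- nrow(unique(f))
  if (ndistinct < K)
    stop("only ", ndistinct, " distinct feature vector(s) for K = ", K,
         " classes (degenerate input)")
  # restarts draw their initial centres from the distinct feature vectors,
  # so heavily duplicated inputs (flat phantom regions) cannot abort a start
  uf <- unique(f)
  km <- with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      fit <- stats::kmeans(f, centers = uf[sample.int(nrow(uf), K), , drop = FALSE],
                           iter.max = 100L)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  labels <- km$cluster
  if (inherits(features, "feature_stack"))
    labels <- matrix(labels, features$dim[1], features$dim[2])
  structure(list(labels = labels, K = K,
                 dispersion = partition_dispersion(km, criterion),
                 centers = km$centers, criterion = criterion),
            class = "hs_clustering")
}

#' @export
print.hs_clustering <- function(x, ...) {
  cat(sprintf("<hs_clustering> K = %d classes, dispersion (%s) = %.4g\n",
              x$K, x$criterion, x$dispersion))
  invisible(x)
}

#' Select the number of classes by minimal dispersion
#'
#' Runs [cluster_pixels()] for each candidate class count (default 2–5) and
#' keeps the partition whose dispersion criterion is smallest, breaking ties
#' toward fewer classes.  Candidate counts exceeding the number of distinct
#' feature vectors are skipped.
#'
#' @inheritParams cluster_pixels
#' @param k_range candidate class counts; default `2:5`.
#' @return The winning `"hs_clustering"`, with attribute `"dispersions"`
#'   holding the criterion value for every candidate tried.
#' @export
select_class_count <- function(features, k_range = 2:5, nstart = 10L,
                               seed = 1L, criterion = c("sem", "sd", "mse")) {
  criterion <- match.arg(criterion)
  k_range <- sort(unique(as.integer(k_range)))
  f <- feature_matrix(features)
  feasible <- k_range[k_range <= nrow(unique(f))]
  if (length(feasible) == 0L)
    stop("no candidate class count is feasible (too few distinct feature vectors)")
  fits <- lapply(feasible, function(K)
    cluster_pixels(features, K, nstart = nstart, seed = seed,
                   criterion = criterion))
  disp <- vapply(fits, `[[`, numeric(1), "dispersion")
  best <- fits[[which.min(disp)]]   # which.min takes the first, i.e. smallest K, on ties
  attr(best, "dispersions") <- stats::setNames(disp, feasible)
  best
}

#' Expand reduced-resolution labels to full resolution
#'
#' Nearest-neighbour expansion inverse to [downsample_cube()]: target pixel
#' `(r, c)` takes the label of block `(ceiling(r/factor), ceiling(c/factor))`.
#'
#' @param labels integer matrix of reduced-resolution labels.
#' @param target_shape integer pair `(rows, cols)` of the full image.
#' @param factor block size used when downsampling; by default inferred as
#'   `ceiling(target / reduced)`.
#' @return Integer matrix of shape `target_shape`.
#' @export
upsample_labels <- function(labels, target_shape, factor = NULL) {
  labels <- as.matrix(labels)
  target_shape <- as.integer(target_shape)
  if (is.null(factor))
    factor <- max(ceiling(target_shape / dim(labels)))
  factor <- as.integer(factor)
  if (any(ceiling(target_shape / factor) != dim(labels)))
    stop("`target_shape` is incompatible with the reduced grid at factor ",
         factor)
  src_r <- pmin(nrow(labels), ceiling(seq_len(target_shape[1]) / factor))
  src_c <- pmin(ncol(labels), ceiling(seq_len(target_shape[2]) / factor))
  labels[src_r, src_c, drop = FALSE]
}

#' Hierarchical segmentation (SH)
#'
#' Segments a cube hierarchically: the cube is reduced by block-mean pooling
#' ([downsample_cube()]), spectral mismatch features against the reference
#' waveform are extracted at the principal local maxima of that waveform,
#' the reduced pixels are clustered with the class count chosen by minimal
#' dispersion ([select_class_count()]), and the class whose centroid is
#' nearest the origin of feature space — the best match to the reference
#' curve — becomes the object.  The object mask is upsampled to full
#' resolution, replicated into a per-band binary stack, corrected band by
#' band with conditional erosion/dilation ([stabilize_stack()]), and
#' collapsed by a majority vote across bands.
#'
#' @inheritParams extract_pattern_from_roi
#' @param pattern reference spectrum ([ref_spectrum()] or numeric vector);
#'   if `NULL`, it is averaged over `roi`.
#' @param roi region of interest used when `pattern` is `NULL`.
#' @param factor spatial reduction factor; default 8.
#' @param n_features number of peak-band features; default 3.
#' @param k_range candidate class counts; default `2:5`.
#' @param params [morph_params()] for the stabilization stage.
#' @param stabilize apply conditional morphology before the majority vote
#'   (default `TRUE`).
#' @param nstart,seed,criterion passed to the clustering stage.
#' @return An object of class `"sh_segmentation"`: list with the final
#'   binary `mask`, the reduced-resolution `clustering`, `peak_bands`,
#'   `pattern` and the settings used.
#' @examples
#' ph <- render_phantom(phantom_spec(rows = 48, cols = 48, bands = 16))
#' lc <- calibrate(median3d(ph$raw), ph$dark, ph$white)
#' seg <- sh_segment(lc, pattern = ph$spectra[[1]], factor = 4)
#' seg_scores(confusion(seg$mask, ph$truth))
#' @export
sh_segment <- function(cube, pattern = NULL, roi = NULL, factor = 8L,
                       n_features = 3L, k_range = 2:5,
                       params = morph_params(), stabilize = TRUE,
                       nstart = 10L, seed = 1L,
                       criterion = c("sem", "sd", "mse")) {
  criterion <- match.arg(criterion)
  v <- cube_values(cube)
  if (is.null(pattern)) {
    if (is.null(roi)) stop("supply either `pattern` or `roi`")
    pattern <- extract_pattern_from_roi(cube, roi)
  }
  p <- pattern_values(pattern, dim(v)[3])
  peaks <- find_local_maxima(p, n_features)
  small <- downsample_cube(cube, factor)
  feats <- extract_features(small, p, peaks)
  cl <- select_class_count(feats, k_range = k_range, nstart = nstart,
                           seed = seed, criterion = criterion)
  object_class <- which.min(rowSums(cl$centers^2))
  mask_small <- (cl$labels == object_class) * 1L
  mask_full <- upsample_labels(mask_small, dim(v)[1:2], factor = factor)
  stack <- array(mask_full, dim(v))          # replicated per band
  if (stabilize)
    stack <- stabilize_stack(stack, cube, params)
  mask <- (rowMeans(stack, dims = 2L) >= 0.5) * 1L
  structure(list(mask = mask, clustering = cl, peak_bands = peaks,
                 pattern = p, object_class = object_class,
                 factor = factor, stabilized = stabilize, params = params),
            class = "sh_segmentation")
}

#' @export
print.sh_segmentation <- function(x, ...) {
  cat(sprintf("<sh_segmentation> %d x %d mask, %d foreground pixel(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  cat(sprintf("  K = %d classes (dispersion %.4g), object class %d, peak bands %s, %s\n",
              x$clustering$K, x$clustering$dispersion, x$object_class,
              paste(x$peak_bands, collapse = "/"),
              if (x$stabilized) "stabilized" else "not stabilized"))
  invisible(x)
}
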