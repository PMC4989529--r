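# Brute-force reference implementations: explicit loops over pixels and
# windows with clamp-to-edge indexing.  These stay deliberately independent
# of the package's kernels.

clampi <- function(v, lo, hi) pmin(pmax(v, lo), hi)

oracle_median3d <- function(arr, mask) {
  d <- dim(arr)
  h <- (mask - 1L) %/% 2L
  out <- array(0, d)
  for (i in seq_len(d[3])) for (n in seq_len(d[2])) for (m in seq_len(d[1])) {
    mm <- clampi((m - h[1]):(m + h[1]), 1L, d[1])
    nn <- clampi((n - h[2]):(n + h[2]), 1L, d[2])
    ii <- clampi((i - h[3]):(i + h[3]), 1L, d[3])
    out[m, n, i] <- median(arr[mm, nn, ii])
  }
  out
}

oracle_median2d <- function(mat, window) {
  d <- dim(mat)
  h <- (window - 1L) %/% 2L
  out <- matrix(0, d[1], d[2])
  for (n in seq_len(d[2])) for (m in seq_len(d[1])) {
    mm <- clampi((m - h):(m + h), 1L, d[1])
    nn <- clampi((n - h):(n + h), 1L, d[2])
    out[m, n] <- median(mat[mm, nn])
  }
  out
}

oracle_local_mean <- function(mat, rows, cols) {
  d <- dim(mat)
  hr <- (rows - 1L) %/% 2L; hc <- (cols - 1L) %/% 2L
  out <- matrix(0, d[1], d[2])
  for (n in seq_len(d[2])) for (m in seq_len(d[1])) {
    mm <- clampi((m - hr):(m + hr), 1L, d[1])
    nn <- clampi((n - hc):(n + hc), 1L, d[2])
    out[m, n] <- mean(mat[mm, nn])
  }
  out
}

oracle_morph <- function(mask, rows, cols, dilate) {
  d <- dim(mask)
  hr <- (rows - 1L) %/% 2L; hc <- (cols - 1L) %/% 2L
  out <- matrix(0L, d[1], d[2])
  for (n in seq_len(d[2])) for (m in seq_len(d[1])) {
    mm <- clampi((m - hr):(m + hr), 1L, d[1])
    nn <- clampi((n - hc):(n + hc), 1L, d[2])
    w <- mask[mm, nn]
    out[m, n] <- if (dilate) max(w) else min(w)
  }
  out
}

# Scalar per-pixel reference for the whole emissivity-matching chain.
oracle_ske <- function(arr, pattern, p_r, bin_threshold) {
  d <- dim(arr)
  counts <- matrix(0L, d[1], d[2])
  for (n in seq_len(d[2])) for (m in seq_len(d[1])) {
    k <- 0L
    for (i in seq_len(d[3])) {
      ld <- (arr[m, n, i] - pattern[i]) / pattern[i]
      if (abs(ld) >= p_r) k <- k + 1L
    }
    counts[m, n] <- k
  }
  mx <- max(counts)
  lv <- if (mx == 0) matrix(1, d[1], d[2]) else 1 - counts / mx
  (lv >= bin_threshold) * 1L
}

# Per-pixel mean-absolute aggregation followed by the windowed median.
oracle_aggregate <- function(vol, pattern, window) {
  d <- dim(vol)
  ls <- matrix(0, d[1], d[2])
  for (n in seq_len(d[2])) for (m in seq_len(d[1]))
    ls[m, n] <- 100 * mean(abs(vol[m, n, ])) / mean(pattern)
  oracle_median2d(ls, window)
}

# 90-degree counterclockwise rotation: pixel (r, c) of an R x C image maps
# to (C + 1 - c, r).
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rot90_cube <- function(cube) {
  v <- as.array(cube)
  d <- dim(v)
  out <- array(0, c(d[2], d[1], d[3]))
  for (i in seq_len(d[3])) out[, , i] <- rot90_mat(v[, , i])
  if (inherits(cube, "hypercube"))
    hypercube(out, wavelengths = cube$wavelengths, dtype = cube$dtype,
              byte_order = cube$byte_order, interleave = cube$interleave,
              bits = cube$bits)
  else out
}

rot90_roi <- function(roi, ncol_orig) {
  c(ncol_orig + 1L - roi[4], ncol_orig + 1L - roi[3], roi[1], roi[2])
}
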