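#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// All kernels use replicate (clamp-to-edge) padding so that border voxels are
// filtered over a full-sized window drawn from existing samples.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Rank (median) filter over a 3D volume stored column-major with dims
// (rows, cols, bands).  In-plane window half-widths may vary per output band
// (band-adaptive denoising); the spectral half-extent is fixed.
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dims,
                           IntegerVector row_half, IntegerVector col_half,
                           int band_half) {
  const int M = dims[0], N = dims[1], I = dims[2];
  NumericVector out(no_init(vol.size()));
  std::vector<double> buf;
  for (int i = 0; i < I; ++i) {
    const int rh = row_half[i], ch = col_half[i];
    const std::size_t wlen =
        (std::size_t)(2 * rh + 1) * (2 * ch + 1) * (2 * band_half + 1);
    buf.resize(wlen);
    for (int n = 0; n < N; ++n) {
      for (int m = 0; m < M; ++m) {
        std::size_t k = 0;
        for (int di = -band_half; di <= band_half; ++di) {
          const int ii = clampi(i + di, 0, I - 1);
          const std::size_t off_i = (std::size_t)ii * M * N;
          for (int dn = -ch; dn <= ch; ++dn) {
            const int nn = clampi(n + dn, 0, N - 1);
            const std::size_t off_n = off_i + (std::size_t)nn * M;
            for (int dm = -rh; dm <= rh; ++dm) {
              const int mm = clampi(m + dm, 0, M - 1);
              buf[k++] = vol[off_n + mm];
            }
          }
        }
        // window volume is a product of odd numbers, hence odd
        std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.begin() + wlen);
        out[(std::size_t)i * M * N + (std::size_t)n * M + m] = buf[wlen / 2];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Windowed arithmetic mean of a 2D image, window (2*rh+1) x (2*ch+1).
// [[Rcpp::export(name = ".local_mean_cpp")]]
NumericMatrix local_mean_cpp(NumericMatrix x, int rh, int ch) {
  const int M = x.nrow(), N = x.ncol();
  NumericMatrix out(M, N);
  const double denom = (double)(2 * rh + 1) * (2 * ch + 1);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int dn = -ch; dn <= ch; ++dn) {
        const int nn = clampi(n + dn, 0, N - 1);
        for (int dm = -rh; dm <= rh; ++dm) {
          s += x(clampi(m + dm, 0, M - 1), nn);
        }
      }
      out(m, n) = s / denom;
    }
  }
  return out;
}

// Plain binary erosion (min) / dilation (max) over a rectangular structuring
// element, replicate padding.
// [[Rcpp::export(name = ".morph_cpp")]]
IntegerMatrix morph_cpp(IntegerMatrix mask, int rh, int ch, bool dilate) {
  const int M = mask.nrow(), N = mask.ncol();
  IntegerMatrix out(M, N);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      int v = dilate ? 0 : 1;
      for (int dn = -ch; dn <= ch && v == (dilate ? 0 : 1); ++dn) {
        const int nn = clampi(n + dn, 0, N - 1);
        for (int dm = -rh; dm <= rh; ++dm) {
          const int e = mask(clampi(m + dm, 0, M - 1), nn);
          if (dilate) { if (e != 0) { v = 1; break; } }
          else        { if (e == 0) { v = 0; break; } }
        }
      }
      out(m, n) = v;
    }
  }
  return out;
}
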