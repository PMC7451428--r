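#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D or 4D array (x fastest), one pass per
// axis. The kernel is truncated at +/- 4 SD and renormalised over the
// in-grid support, matching a row-normalised dense Gaussian band matrix.
//
// smooth_axis views the array as (d0, n, d2) with the smoothed axis in the
// middle; d0 is the contiguous inner block size.
static void smooth_axis(std::vector<double>& a, std::vector<double>& buf,
                        const R_xlen_t d0, const int n, const R_xlen_t d2,
                        const double sd) {
  if (sd <= 0.0) return;
  const int half = std::max(1, (int)std::ceil(4.0 * sd));
  std::vector<double> w(2 * half + 1);
  for (int k = -half; k <= half; ++k)
    w[k + half] = std::exp(-0.5 * (double)(k * k) / (sd * sd));

  // normalised weights per output position
  std::vector<int> lo(n), hi(n);
  std::vector<double> wn((size_t)n * (2 * half + 1));
  for (int j = 0; j < n; ++j) {
    lo[j] = std::max(0, j - half);
    hi[j] = std::min(n - 1, j + half);
    double norm = 0.0;
    for (int q = lo[j]; q <= hi[j]; ++q) norm += w[q - j + half];
    for (int q = lo[j]; q <= hi[j]; ++q)
      wn[(size_t)j * (2 * half + 1) + (q - lo[j])] = w[q - j + half] / norm;
  }

  const R_xlen_t plane = d0 * n;
  if (d0 == 1) {
    for (R_xlen_t z = 0; z < d2; ++z) {
      const double* in = a.data() + z * plane;
      double* out = buf.data() + z * plane;
      for (int j = 0; j < n; ++j) {
        const double* wj = wn.data() + (size_t)j * (2 * half + 1);
        double s = 0.0;
        for (int q = lo[j]; q <= hi[j]; ++q) s += wj[q - lo[j]] * in[q];
        out[j] = s;
      }
    }
  } else {
    for (R_xlen_t z = 0; z < d2; ++z) {
      const double* in = a.data() + z * plane;
      double* out = buf.data() + z * plane;
      for (int j = 0; j < n; ++j) {
        const double* wj = wn.data() + (size_t)j * (2 * half + 1);
        double* oj = out + (R_xlen_t)j * d0;
        std::fill(oj, oj + d0, 0.0);
        for (int q = lo[j]; q <= hi[j]; ++q) {
          const double wq = wj[q - lo[j]];
          const double* iq = in + (R_xlen_t)q * d0;
          for (R_xlen_t i = 0; i < d0; ++i) oj[i] += wq * iq[i];
        }
      }
    }
  }
  std::swap(a, buf);
}

// [[Rcpp::export(name = ".gaussian_smooth_cpp")]]
NumericVector gaussian_smooth_cpp(NumericVector data, IntegerVector dim,
                                  NumericVector sd_vox) {
  if (dim.size() < 3 || dim.size() > 4) stop("dim must have length 3 or 4");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nt = dim.size() == 4 ? dim[3] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz * nt;
  if (data.size() != n) stop("data length does not match dim");

  std::vector<double> a(data.begin(), data.end()), buf(n);
  smooth_axis(a, buf, 1, nx, (R_xlen_t)ny * nz * nt, sd_vox[0]);
  smooth_axis(a, buf, nx, ny, (R_xlen_t)nz * nt, sd_vox[1]);
  smooth_axis(a, buf, (R_xlen_t)nx * ny, nz, nt, sd_vox[2]);

  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
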