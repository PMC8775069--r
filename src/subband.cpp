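// Fast path for build_epoch_tensor(): five-level DB4 wavedec + per-band
// wrcoef reconstruction for every (epoch, channel) series, all in one pass.
// Mirrors the R-level dwt_decompose()/reconstruct_subband() pair exactly
// (symmetric half-point extension, MATLAB-style coefficient counts); the two
// routes are cross-checked in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

const int FLEN = 8;

void dwt_step_vec(const std::vector<double>& x,
                  const double* lo, const double* hi,
                  std::vector<double>& ca, std::vector<double>& cd) {
  int n = static_cast<int>(x.size());
  int p = FLEN - 1;
  std::vector<double> xe(n + 2 * p);
  for (int i = 0; i < p; ++i) xe[i] = x[p - 1 - i];
  std::copy(x.begin(), x.end(), xe.begin() + p);
  for (int i = 0; i < p; ++i) xe[p + n + i] = x[n - 1 - i];
  int nc = (n + FLEN - 1) / 2;
  ca.assign(nc, 0.0);
  cd.assign(nc, 0.0);
  // valid convolution, then keep odd outputs (0-based index 1, 3, ...)
  for (int c = 0; c < nc; ++c) {
    int start = 2 * c + 1;
    double sl = 0.0, sh = 0.0;
    for (int j = 0; j < FLEN; ++j) {
      double v = xe[start + j];
      sl += v * lo[FLEN - 1 - j];
      sh += v * hi[FLEN - 1 - j];
    }
    ca[c] = sl;
    cd[c] = sh;
  }
}

void idwt_step_vec(const std::vector<double>& ca, const std::vector<double>& cd,
                   const double* rlo, const double* rhi, int out_len,
                   std::vector<double>& y) {
  int n = static_cast<int>(ca.size());
  int up_len = 2 * n - 1;
  int full = up_len + FLEN - 1;  // full convolution length
  std::vector<double> acc(full, 0.0);
  for (int i = 0; i < n; ++i) {
    double a = ca[i], d = cd[i];
    int base = 2 * i;
    if (a != 0.0 || d != 0.0)
      for (int j = 0; j < FLEN; ++j)
        acc[base + j] += a * rlo[j] + d * rhi[j];
  }
  // trim FLEN-2 from each side, then truncate to out_len
  y.assign(out_len, 0.0);
  for (int i = 0; i < out_len; ++i) y[i] = acc[FLEN - 2 + i];
}

}  // namespace

// epochs: (ne, nch, ns) array; returns (ne, nch, ns, level+1) with bands
// ordered d1, d2, ..., d<level>, a<level>.
// [[Rcpp::export(rng = false)]]
NumericVector subband_tensor_cpp(NumericVector epochs, IntegerVector dim,
                                 int level,
                                 NumericVector dec_lo, NumericVector dec_hi,
                                 NumericVector rec_lo, NumericVector rec_hi) {
  int ne = dim[0], nch = dim[1], ns = dim[2];
  if (dec_lo.size() != FLEN) stop("expected an 8-tap filter bank");
  NumericVector out(static_cast<R_xlen_t>(ne) * nch * ns * (level + 1));
  out.attr("dim") = IntegerVector::create(ne, nch, ns, level + 1);
  const double* lo = REAL(dec_lo);
  const double* hi = REAL(dec_hi);
  const double* rlo = REAL(rec_lo);
  const double* rhi = REAL(rec_hi);
  double* op = REAL(out);
  const double* ep = REAL(epochs);

  std::vector<int> alen(level + 1);
  alen[0] = ns;
  for (int j = 1; j <= level; ++j) alen[j] = (alen[j - 1] + FLEN - 1) / 2;

  std::vector<double> x(ns);
  std::vector<std::vector<double>> details(level + 1);
  std::vector<double> ca, cd, cur, zero_d, tmp;
  size_t plane = static_cast<size_t>(ne) * nch;

  for (int e = 0; e < ne; ++e) {
    for (int ch = 0; ch < nch; ++ch) {
      for (int s = 0; s < ns; ++s)
        x[s] = ep[e + static_cast<size_t>(ne) * ch + plane * s];
      // analysis cascade
      cur = x;
      for (int j = 1; j <= level; ++j) {
        dwt_step_vec(cur, lo, hi, ca, cd);
        details[j] = cd;
        cur = ca;  // approximation at level j
      }
      // band-by-band synthesis: band index 0..level-1 = d1..d<level>,
      // band index level = a<level>
      for (int band = 0; band <= level; ++band) {
        int start_level = (band < level) ? band + 1 : level;
        bool is_approx = (band == level);
        if (is_approx) {
          zero_d.assign(alen[level], 0.0);
          idwt_step_vec(cur, zero_d, rlo, rhi, alen[level - 1], tmp);
        } else {
          zero_d.assign(alen[start_level], 0.0);
          idwt_step_vec(zero_d, details[start_level], rlo, rhi,
                        alen[start_level - 1], tmp);
        }
        for (int j = start_level - 1; j >= 1; --j) {
          zero_d.assign(alen[j], 0.0);
          idwt_step_vec(tmp, zero_d, rlo, rhi, alen[j - 1], tmp);
        }
        double* dst = op + static_cast<size_t>(e) +
          static_cast<size_t>(ne) * ch;
        size_t bandoff = plane * static_cast<size_t>(ns) * band;
        for (int s = 0; s < ns; ++s)
          dst[plane * s + bandoff] = tmp[s];
      }
    }
  }
  return out;
}
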