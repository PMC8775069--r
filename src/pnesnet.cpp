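// Numerical kernels for the CNN engine, the DWT cascade and permutation
// entropy. Arrays follow R's column-major layout throughout; batched tensors
// are (batch, channel, time, feature).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col_1x(const double* x, int B, int H, int T, int Cin,
                                  int k, int stride, int pad_left, int Tout) {
  // rows ordered b fastest, then h, then t_out -> matches the column-major
  // layout of the (B, H, Tout, Cout) output array after the GEMM.
  arma::mat A(static_cast<size_t>(B) * H * Tout, static_cast<size_t>(k) * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int i = 0; i < k; ++i) {
      double* col = A.colptr(i + k * ci);
      for (int t = 0; t < Tout; ++t) {
        int tin = t * stride - pad_left + i;
        size_t off = static_cast<size_t>(t) * B * H;
        if (tin < 0 || tin >= T) {
          std::fill(col + off, col + off + static_cast<size_t>(B) * H, 0.0);
        } else {
          const double* src = x + static_cast<size_t>(B) * H * (tin + static_cast<size_t>(T) * ci);
          std::copy(src, src + static_cast<size_t>(B) * H, col + off);
        }
      }
    }
  }
  return A;
}

// Convolution with 1 x k kernels applied along the time axis of every channel
// row, stride 1 x s, explicit left padding ("same" is computed R-side).
// x: (B,H,T,Cin), w: (k,Cin,Cout), bias: length Cout. Returns (B,H,Tout,Cout).
// [[Rcpp::export(rng = false)]]
NumericVector conv1x_forward(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, int stride, int pad_left,
                             int t_out) {
  int B = xdim[0], H = xdim[1], T = xdim[2], Cin = xdim[3];
  int k = wdim[0], Cout = wdim[2];
  arma::mat A = im2col_1x(REAL(x), B, H, T, Cin, k, stride, pad_left, t_out);
  arma::mat W(REAL(w), static_cast<size_t>(k) * Cin, Cout, false, true);
  arma::mat Y = A * W;
  Y.each_row() += arma::rowvec(REAL(bias), Cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(B, H, t_out, Cout);
  return out;
}

// Backward pass; dy: (B,H,Tout,Cout). Returns list(dx, dw, db).
// [[Rcpp::export(rng = false)]]
List conv1x_backward(NumericVector x, IntegerVector xdim,
                     NumericVector w, IntegerVector wdim,
                     NumericVector dy, int stride, int pad_left, int t_out) {
  int B = xdim[0], H = xdim[1], T = xdim[2], Cin = xdim[3];
  int k = wdim[0], Cout = wdim[2];
  size_t nrow = static_cast<size_t>(B) * H * t_out;
  arma::mat A = im2col_1x(REAL(x), B, H, T, Cin, k, stride, pad_left, t_out);
  arma::mat W(REAL(w), static_cast<size_t>(k) * Cin, Cout, false, true);
  arma::mat dY(REAL(dy), nrow, Cout, false, true);

  arma::mat dW = A.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dA = dY * W.t();

  NumericVector dx(x.size());
  double* dxp = REAL(dx);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int i = 0; i < k; ++i) {
      const double* col = dA.colptr(i + k * ci);
      for (int t = 0; t < t_out; ++t) {
        int tin = t * stride - pad_left + i;
        if (tin < 0 || tin >= T) continue;
        double* dst = dxp + static_cast<size_t>(B) * H * (tin + static_cast<size_t>(T) * ci);
        const double* src = col + static_cast<size_t>(t) * B * H;
        for (size_t j = 0; j < static_cast<size_t>(B) * H; ++j) dst[j] += src[j];
      }
    }
  }
  dx.attr("dim") = xdim;
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling 1 x 2, stride 1 x 2 along time. x: (B,H,T,C), T even or odd
// (trailing sample dropped). Returns list(y, argmax) with argmax the linear
// index into x for the winning element of every pooled cell.
// [[Rcpp::export(rng = false)]]
List maxpool1x2_forward(NumericVector x, IntegerVector xdim) {
  int B = xdim[0], H = xdim[1], T = xdim[2], C = xdim[3];
  int Tout = T / 2;
  size_t plane = static_cast<size_t>(B) * H;
  NumericVector y(plane * Tout * C);
  IntegerVector amax(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(amax);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Tout; ++t) {
      size_t o0 = plane * (2 * t + static_cast<size_t>(T) * c);
      size_t o1 = o0 + plane;
      size_t oy = plane * (t + static_cast<size_t>(Tout) * c);
      for (size_t j = 0; j < plane; ++j) {
        if (xp[o0 + j] >= xp[o1 + j]) {
          yp[oy + j] = xp[o0 + j];
          ap[oy + j] = static_cast<int>(o0 + j);
        } else {
          yp[oy + j] = xp[o1 + j];
          ap[oy + j] = static_cast<int>(o1 + j);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, H, Tout, C);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool1x2_backward(NumericVector dy, IntegerVector argmax,
                                  IntegerVector xdim) {
  size_t n = static_cast<size_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ap = INTEGER(argmax);
  for (R_xlen_t j = 0; j < dy.size(); ++j) dxp[ap[j]] += dyp[j];
  dx.attr("dim") = xdim;
  return dx;
}

// Valid-mode convolution of a signal with a short filter (direct form),
// used by the Mallat cascade. Returns length(x) - length(f) + 1 samples.
// [[Rcpp::export(rng = false)]]
NumericVector conv_valid(NumericVector x, NumericVector f) {
  int n = x.size(), m = f.size();
  if (n < m) stop("signal shorter than filter");
  NumericVector y(n - m + 1);
  for (int i = 0; i <= n - m; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += x[i + j] * f[m - 1 - j];
    y[i] = s;
  }
  return y;
}

// Permutation entropy (bits) of every column of X (columns are time series).
// Ordinal patterns of `order` consecutive values spaced `delay` apart; ties
// broken by order of appearance (the earlier sample ranks lower), which keeps
// the value well defined on rectified feature maps containing runs of zeros.
// [[Rcpp::export(rng = false)]]
NumericVector pe_cols(NumericMatrix X, int order, int delay) {
  if (order < 2 || order > 7) stop("order must be in 2..7");
  if (delay < 1) stop("delay must be >= 1");
  int nser = X.ncol(), len = X.nrow();
  int span = (order - 1) * delay;
  if (len < span + 1) stop("series shorter than (order-1)*delay + 1");
  int nwin = len - span;
  // encode pattern as sum(rank_j * order^j); order <= 7 -> at most 7^7 codes
  int ncode = 1;
  for (int j = 0; j < order; ++j) ncode *= order;
  std::vector<int> counts(ncode);
  std::vector<int> touched;
  touched.reserve(nwin);
  NumericVector out(nser);
  std::vector<double> v(order);
  for (int r = 0; r < nser; ++r) {
    std::fill(counts.begin(), counts.end(), 0);
    touched.clear();
    const double* col = &X(0, r);
    for (int w = 0; w < nwin; ++w) {
      for (int j = 0; j < order; ++j) v[j] = col[w + j * delay];
      int code = 0, mult = 1;
      for (int j = 0; j < order; ++j) {
        int rank = 0;
        for (int kk = 0; kk < order; ++kk) {
          if (kk == j) continue;
          if (v[kk] < v[j] || (v[kk] == v[j] && kk < j)) ++rank;
        }
        code += rank * mult;
        mult *= order;
      }
      if (counts[code] == 0) touched.push_back(code);
      ++counts[code];
    }
    double h = 0.0;
    for (size_t ti = 0; ti < touched.size(); ++ti) {
      double p = static_cast<double>(counts[touched[ti]]) / nwin;
      h -= p * std::log2(p);
    }
    out[r] = h;
  }
  return out;
}

// Direct-form II transposed IIR filter (a[0] assumed 1 after normalisation).
// [[Rcpp::export(rng = false)]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Six summary statistics per column of M (rows = time samples):
// min, max, energy (sum of squares), mean, population sd, Fisher skewness
// (bias-uncorrected; 0 for zero-variance columns).
// [[Rcpp::export(rng = false)]]
NumericMatrix col_stats6(NumericMatrix M) {
  int n = M.nrow(), K = M.ncol();
  NumericMatrix S(6, K);
  for (int cidx = 0; cidx < K; ++cidx) {
    const double* col = &M(0, cidx);
    double mn = col[0], mx = col[0], sum = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = col[i];
      if (x < mn) mn = x;
      if (x > mx) mx = x;
      sum += x;
      ss += x * x;
    }
    double mean = sum / n;
    double m2 = 0.0, m3 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = col[i] - mean;
      m2 += d * d;
      m3 += d * d * d;
    }
    m2 /= n;
    m3 /= n;
    S(0, cidx) = mn;
    S(1, cidx) = mx;
    S(2, cidx) = ss;
    S(3, cidx) = mean;
    S(4, cidx) = std::sqrt(m2);
    S(5, cidx) = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0.0;
  }
  return S;
}
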