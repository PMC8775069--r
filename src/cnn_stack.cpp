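// Fused forward/backward pass of the convolutional front of the epoch
// classifier (Conv1+ReLU -> MaxPool1 -> Conv2+ReLU -> MaxPool2 -> Dense1
// pre-activation).
//
// Two deliberate engineering choices, both standard for DL runtimes and both
// forced here by the memory system (R re-mmaps large vectors, so re-allocating
// ~100 MB activations every mini-batch costs more in page faults than the
// arithmetic itself):
//   * all large intermediates are float32 and live in persistent buffers;
//   * the cohort tensor is loaded once per session into a transposed
//     (channel, time, band, epoch) float copy, so that a mini-batch gather is
//     a handful of contiguous copies rather than millions of strided reads.
// The R-level generic engine (nn.R) computes the same network in double
// precision; the two routes are cross-checked in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct StackState {
  // loaded cohort tensor, layout (H, T, C0, N), float
  std::vector<float> Xf;
  const double* x_ptr = nullptr;  // identity of the loaded R array
  double x_sum = 0.0;             // full-content checksums guarding reuse
  double x_sum2 = 0.0;
  double gain = 1.0;
  int N = 0, H = 0, T = 0, C0 = 0;

  // per-batch buffers; layouts noted per buffer
  std::vector<float> Xb;             // (H, T, C0, B)
  std::vector<float> A1, Z1, P1;     // A1: rows (h,t,b) x (k1*C0); Z1/P1: (H,T1,B,f1)/(H,Tp1,B,f1)
  std::vector<float> A2, Z2, P2;     // A2: rows (h,t,b) x (k2*f1); Z2/P2: (H,T2,B,f2)/(H,Tp2,B,f2)
  std::vector<float> Pm;             // repacked (flat, B), flat = H*Tp2*f2 in (h,t,c) order
  std::vector<float> dPm, dZ2, dA2, dP1, dZ1;
  std::vector<int> am1, am2;
  std::vector<float> w1f, w2f, wd1f;
  int B = -1;
  int k1, f1, s1, pl1, T1, Tp1, k2, f2, s2, pl2, T2, Tp2, nd1, flat;
};
StackState st;

template <typename T>
inline void ensure(std::vector<T>& v, size_t n) {
  if (v.size() < n) v.resize(n);
}

inline int conv_tout(int T, int s) { return (T + s - 1) / s; }
inline int conv_padl(int T, int k, int s) {
  int tout = conv_tout(T, s);
  int tot = std::max((tout - 1) * s + k - T, 0);
  return tot / 2;
}

void to_float(const double* src, size_t n, std::vector<float>& dst) {
  ensure(dst, n);
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

// im2col on a (H, T, Cin, B) source into A with rows ordered (h, t, b),
// columns (i + k * ci).
void im2col_htb(const float* src, int H, int T, int Cin, int B,
                int k, int stride, int pad_left, int Tout, float* A,
                size_t rows) {
  for (int ci = 0; ci < Cin; ++ci)
    for (int b = 0; b < B; ++b) {
      const float* slab = src + static_cast<size_t>(H) * T * (ci + static_cast<size_t>(Cin) * b);
      for (int i = 0; i < k; ++i) {
        float* col = A + rows * (i + static_cast<size_t>(k) * ci);
        float* dstb = col + static_cast<size_t>(H) * Tout * b;
        for (int t = 0; t < Tout; ++t) {
          int tin = t * stride - pad_left + i;
          float* dst = dstb + static_cast<size_t>(H) * t;
          if (tin < 0 || tin >= T) std::fill(dst, dst + H, 0.0f);
          else std::copy(slab + static_cast<size_t>(H) * tin,
                         slab + static_cast<size_t>(H) * tin + H, dst);
        }
      }
    }
}

// transposed col2im: scatter-add dA (rows (h,t,b) x k*Cin) into a
// (H, Tin, Cin, B) gradient buffer.
void col2im_htb(const float* dA, int H, int Tin, int Cin, int B,
                int k, int stride, int pad_left, int Tout, float* dX,
                size_t rows) {
  std::fill(dX, dX + static_cast<size_t>(H) * Tin * Cin * B, 0.0f);
  for (int ci = 0; ci < Cin; ++ci)
    for (int b = 0; b < B; ++b) {
      float* slab = dX + static_cast<size_t>(H) * Tin * (ci + static_cast<size_t>(Cin) * b);
      for (int i = 0; i < k; ++i) {
        const float* col = dA + rows * (i + static_cast<size_t>(k) * ci);
        const float* srcb = col + static_cast<size_t>(H) * Tout * b;
        for (int t = 0; t < Tout; ++t) {
          int tin = t * stride - pad_left + i;
          if (tin < 0 || tin >= Tin) continue;
          float* dst = slab + static_cast<size_t>(H) * tin;
          const float* s2 = srcb + static_cast<size_t>(H) * t;
          for (int h = 0; h < H; ++h) dst[h] += s2[h];
        }
      }
    }
}

// max pooling 1x2 stride 2 along t of a (H, T, B, F) buffer.
void pool_fwd(const float* z, int H, int T, int B, int F, float* p, int* am) {
  int Tout = T / 2;
  for (int f = 0; f < F; ++f)
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tout; ++t) {
        size_t o0 = static_cast<size_t>(H) * (2 * t + static_cast<size_t>(T) * (b + static_cast<size_t>(B) * f));
        size_t o1 = o0 + H;
        size_t oy = static_cast<size_t>(H) * (t + static_cast<size_t>(Tout) * (b + static_cast<size_t>(B) * f));
        for (int h = 0; h < H; ++h) {
          if (z[o0 + h] >= z[o1 + h]) { p[oy + h] = z[o0 + h]; am[oy + h] = static_cast<int>(o0 + h); }
          else { p[oy + h] = z[o1 + h]; am[oy + h] = static_cast<int>(o1 + h); }
        }
      }
}

}  // namespace

// Load (or re-use) the cohort tensor: x is (N, H, T, C0) double, converted
// once to the internal float layout (H, T, C0, N), scaled by the model's
// fixed input gain.
// [[Rcpp::export(rng = false)]]
void cnn_stack_load(NumericVector x, IntegerVector xdim, double gain) {
  const double* xp = REAL(x);
  size_t ntot = static_cast<size_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  // Full-content checksum: R reuses freed addresses, and any *strided* probe
  // can resonate with the cohort's (epoch, channel) block structure -- two
  // cohorts from the same seed differ only in (ES subject, designated
  // channel) entries, which a fixed stride can systematically miss. Summing
  // everything costs ~2% of a reload and cannot alias that way.
  double sum = 0.0, sum2 = 0.0;
  for (size_t j = 0; j < ntot; ++j) {
    sum += xp[j];
    sum2 += xp[j] * xp[j];
  }
  if (st.x_ptr == xp && st.N == xdim[0] && st.H == xdim[1] &&
      st.T == xdim[2] && st.C0 == xdim[3] && st.gain == gain &&
      st.x_sum == sum && st.x_sum2 == sum2)
    return;
  st.N = xdim[0]; st.H = xdim[1]; st.T = xdim[2]; st.C0 = xdim[3];
  size_t n = ntot;
  ensure(st.Xf, n);
  // source layout (n, h, t, c) col-major; dest (h, t, c, n)
  size_t per_sample = static_cast<size_t>(st.H) * st.T * st.C0;
  for (int c = 0; c < st.C0; ++c)
    for (int t = 0; t < st.T; ++t)
      for (int h = 0; h < st.H; ++h) {
        const double* src = xp + static_cast<size_t>(st.N) *
          (h + static_cast<size_t>(st.H) * (t + static_cast<size_t>(st.T) * c));
        size_t doff = h + static_cast<size_t>(st.H) * (t + static_cast<size_t>(st.T) * c);
        for (int nn = 0; nn < st.N; ++nn)
          st.Xf[doff + per_sample * nn] = static_cast<float>(src[nn] * gain);
      }
  st.x_ptr = xp;
  st.gain = gain;
  st.x_sum = sum;
  st.x_sum2 = sum2;
  st.B = -1;
}

// Forward pass over the 1-based sample indices idx of the loaded tensor.
// Returns the B x nd1 Dense1 pre-activation (double).
// [[Rcpp::export(rng = false)]]
NumericMatrix cnn_stack_forward(IntegerVector idx,
                                NumericVector w1, IntegerVector w1dim,
                                NumericVector b1,
                                NumericVector w2, IntegerVector w2dim,
                                NumericVector b2,
                                NumericMatrix wd1, NumericVector bd1,
                                int stride1, int stride2) {
  if (st.x_ptr == nullptr) stop("cnn_stack_load must be called first");
  int H = st.H, T = st.T, C0 = st.C0;
  st.k1 = w1dim[0]; st.f1 = w1dim[2]; st.s1 = stride1;
  st.k2 = w2dim[0]; st.f2 = w2dim[2]; st.s2 = stride2;
  st.B = idx.size();
  int B = st.B;
  st.T1 = conv_tout(T, st.s1);
  st.pl1 = conv_padl(T, st.k1, st.s1);
  st.Tp1 = st.T1 / 2;
  st.T2 = conv_tout(st.Tp1, st.s2);
  st.pl2 = conv_padl(st.Tp1, st.k2, st.s2);
  st.Tp2 = st.T2 / 2;
  st.nd1 = wd1.ncol();
  st.flat = H * st.Tp2 * st.f2;
  if (wd1.nrow() != st.flat)
    stop("Dense1 weight rows do not match the flattened conv output");
  size_t r1 = static_cast<size_t>(B) * H * st.T1;
  size_t r2 = static_cast<size_t>(B) * H * st.T2;
  size_t per_sample = static_cast<size_t>(H) * T * C0;

  ensure(st.Xb, per_sample * B);
  for (int b = 0; b < B; ++b) {
    int s = idx[b];
    if (s < 1 || s > st.N) stop("sample index out of range");
    std::copy(st.Xf.data() + per_sample * (s - 1),
              st.Xf.data() + per_sample * s, st.Xb.data() + per_sample * b);
  }

  ensure(st.A1, r1 * st.k1 * C0);
  ensure(st.Z1, r1 * st.f1);
  ensure(st.P1, static_cast<size_t>(B) * H * st.Tp1 * st.f1);
  ensure(st.A2, r2 * st.k2 * st.f1);
  ensure(st.Z2, r2 * st.f2);
  ensure(st.P2, static_cast<size_t>(B) * st.flat);
  ensure(st.Pm, static_cast<size_t>(B) * st.flat);
  ensure(st.am1, static_cast<size_t>(B) * H * st.Tp1 * st.f1);
  ensure(st.am2, static_cast<size_t>(B) * st.flat);

  to_float(REAL(w1), w1.size(), st.w1f);
  to_float(REAL(w2), w2.size(), st.w2f);
  to_float(REAL(wd1), static_cast<size_t>(wd1.nrow()) * wd1.ncol(), st.wd1f);

  im2col_htb(st.Xb.data(), H, T, C0, B, st.k1, st.s1, st.pl1, st.T1,
             st.A1.data(), r1);
  {
    arma::fmat A(st.A1.data(), r1, static_cast<size_t>(st.k1) * C0, false, true);
    arma::fmat W(st.w1f.data(), static_cast<size_t>(st.k1) * C0, st.f1, false, true);
    arma::fmat Z(st.Z1.data(), r1, st.f1, false, true);
    Z = A * W;
    for (int f = 0; f < st.f1; ++f) {
      float bf = static_cast<float>(b1[f]);
      float* zc = st.Z1.data() + r1 * f;
      for (size_t j = 0; j < r1; ++j) {
        float v = zc[j] + bf;
        zc[j] = v > 0.0f ? v : 0.0f;
      }
    }
  }
  pool_fwd(st.Z1.data(), H, st.T1, B, st.f1, st.P1.data(), st.am1.data());
  // P1 has layout (H, Tp1, B, f1); im2col wants (H, T, Cin, B): swap the two
  // trailing dims by treating f1 as Cin through a strided copy-free view is
  // not possible, so A2 is built with a variant loop.
  {
    size_t rows = r2;
    for (int ci = 0; ci < st.f1; ++ci)
      for (int b = 0; b < B; ++b) {
        const float* slab = st.P1.data() + static_cast<size_t>(H) * st.Tp1 *
          (b + static_cast<size_t>(B) * ci);
        for (int i = 0; i < st.k2; ++i) {
          float* col = st.A2.data() + rows * (i + static_cast<size_t>(st.k2) * ci);
          float* dstb = col + static_cast<size_t>(H) * st.T2 * b;
          for (int t = 0; t < st.T2; ++t) {
            int tin = t * st.s2 - st.pl2 + i;
            float* dst = dstb + static_cast<size_t>(H) * t;
            if (tin < 0 || tin >= st.Tp1) std::fill(dst, dst + H, 0.0f);
            else std::copy(slab + static_cast<size_t>(H) * tin,
                           slab + static_cast<size_t>(H) * tin + H, dst);
          }
        }
      }
  }
  {
    arma::fmat A(st.A2.data(), r2, static_cast<size_t>(st.k2) * st.f1, false, true);
    arma::fmat W(st.w2f.data(), static_cast<size_t>(st.k2) * st.f1, st.f2, false, true);
    arma::fmat Z(st.Z2.data(), r2, st.f2, false, true);
    Z = A * W;
    for (int f = 0; f < st.f2; ++f) {
      float bf = static_cast<float>(b2[f]);
      float* zc = st.Z2.data() + r2 * f;
      for (size_t j = 0; j < r2; ++j) {
        float v = zc[j] + bf;
        zc[j] = v > 0.0f ? v : 0.0f;
      }
    }
  }
  pool_fwd(st.Z2.data(), H, st.T2, B, st.f2, st.P2.data(), st.am2.data());
  // repack P2 (H, Tp2, B, f2) -> Pm (flat, B) with per-sample feature order
  // (h, t, c), matching R's column-major flatten of a (B, H, T, C) array.
  {
    size_t hm = static_cast<size_t>(H) * st.Tp2;
    for (int c = 0; c < st.f2; ++c)
      for (int b = 0; b < B; ++b)
        std::copy(st.P2.data() + hm * (b + static_cast<size_t>(B) * c),
                  st.P2.data() + hm * (b + static_cast<size_t>(B) * c) + hm,
                  st.Pm.data() + static_cast<size_t>(st.flat) * b + hm * c);
  }
  NumericMatrix out(B, st.nd1);
  {
    arma::fmat P(st.Pm.data(), st.flat, B, false, true);
    arma::fmat Wd(st.wd1f.data(), st.flat, st.nd1, false, true);
    arma::fmat O = P.t() * Wd;
    double* op = REAL(out);
    for (int j = 0; j < st.nd1; ++j) {
      double bj = bd1[j];
      for (int b = 0; b < B; ++b)
        op[b + static_cast<size_t>(B) * j] = static_cast<double>(O(b, j)) + bj;
    }
  }
  return out;
}

// Backward from the Dense1 pre-activation gradient (uses the buffers of the
// immediately preceding forward call), writing the double-precision gradients
// into caller-provided buffers so that no large allocation happens per step.
// [[Rcpp::export(rng = false)]]
void cnn_stack_backward_into(NumericMatrix dD1,
                             NumericVector w1, IntegerVector w1dim,
                             NumericVector w2, IntegerVector w2dim,
                             NumericMatrix wd1,
                             NumericVector gW1, NumericVector gb1,
                             NumericVector gW2, NumericVector gb2,
                             NumericMatrix gWd1, NumericVector gbd1) {
  if (st.B < 0) stop("cnn_stack_forward must be called first");
  int B = st.B, H = st.H;
  if (dD1.nrow() != B) stop("batch size mismatch with the stored forward pass");
  size_t r1 = static_cast<size_t>(B) * H * st.T1;
  size_t r2 = static_cast<size_t>(B) * H * st.T2;
  size_t p1sz = static_cast<size_t>(B) * H * st.Tp1 * st.f1;
  size_t flatB = static_cast<size_t>(B) * st.flat;
  ensure(st.dPm, flatB);
  ensure(st.dZ2, r2 * st.f2);
  ensure(st.dA2, r2 * st.k2 * st.f1);
  ensure(st.dP1, p1sz);
  ensure(st.dZ1, r1 * st.f1);

  if (gW1.size() != w1.size() || gW2.size() != w2.size() ||
      gWd1.nrow() != st.flat || gWd1.ncol() != st.nd1 ||
      gb1.size() != st.f1 || gb2.size() != st.f2 || gbd1.size() != st.nd1)
    stop("gradient buffer dimensions do not match the parameters");
  static std::vector<float> dD1f, Gbuf;
  ensure(dD1f, static_cast<size_t>(B) * st.nd1);
  for (size_t j = 0; j < static_cast<size_t>(B) * st.nd1; ++j)
    dD1f[j] = static_cast<float>(REAL(dD1)[j]);
  ensure(Gbuf, static_cast<size_t>(st.flat) * st.nd1);
  {
    arma::fmat P(st.Pm.data(), st.flat, B, false, true);
    arma::fmat dD(dD1f.data(), B, st.nd1, false, true);
    arma::fmat G(Gbuf.data(), st.flat, st.nd1, false, true);
    G = P * dD;  // flat x nd1
    double* gp = REAL(gWd1);
    for (size_t j = 0; j < static_cast<size_t>(st.flat) * st.nd1; ++j)
      gp[j] = static_cast<double>(Gbuf[j]);
    for (int j = 0; j < st.nd1; ++j) {
      double s = 0;
      for (int b = 0; b < B; ++b) s += dD1[b + static_cast<size_t>(B) * j];
      gbd1[j] = s;
    }
    arma::fmat Wd(st.wd1f.data(), st.flat, st.nd1, false, true);
    arma::fmat dP(st.dPm.data(), st.flat, B, false, true);
    dP = Wd * dD.t();
  }
  // unpack dPm (flat, B) -> (H, Tp2, B, f2) order, then pool2/relu2 backward
  std::fill(st.dZ2.begin(), st.dZ2.begin() + r2 * st.f2, 0.0f);
  {
    size_t hm = static_cast<size_t>(H) * st.Tp2;
    for (int c = 0; c < st.f2; ++c)
      for (int b = 0; b < B; ++b) {
        const float* src = st.dPm.data() + static_cast<size_t>(st.flat) * b + hm * c;
        size_t base = hm * (b + static_cast<size_t>(B) * c);
        for (size_t j = 0; j < hm; ++j) {
          int tgt = st.am2[base + j];
          if (st.Z2[tgt] > 0.0f) st.dZ2[tgt] += src[j];
        }
      }
  }
  {
    arma::fmat A(st.A2.data(), r2, static_cast<size_t>(st.k2) * st.f1, false, true);
    arma::fmat dZ(st.dZ2.data(), r2, st.f2, false, true);
    arma::fmat G = A.t() * dZ;
    for (R_xlen_t j = 0; j < gW2.size(); ++j) gW2[j] = static_cast<double>(G[j]);
    for (int f = 0; f < st.f2; ++f) {
      double s = 0;
      const float* zc = st.dZ2.data() + r2 * f;
      for (size_t j = 0; j < r2; ++j) s += zc[j];
      gb2[f] = s;
    }
    arma::fmat W(st.w2f.data(), static_cast<size_t>(st.k2) * st.f1, st.f2, false, true);
    arma::fmat dA(st.dA2.data(), r2, static_cast<size_t>(st.k2) * st.f1, false, true);
    dA = dZ * W.t();
  }
  // col2im into dP1 (H, Tp1, B, f1) -- mirrors the A2 construction loop
  std::fill(st.dP1.begin(), st.dP1.begin() + p1sz, 0.0f);
  {
    for (int ci = 0; ci < st.f1; ++ci)
      for (int b = 0; b < B; ++b) {
        float* slab = st.dP1.data() + static_cast<size_t>(H) * st.Tp1 *
          (b + static_cast<size_t>(B) * ci);
        for (int i = 0; i < st.k2; ++i) {
          const float* col = st.dA2.data() + r2 * (i + static_cast<size_t>(st.k2) * ci);
          const float* srcb = col + static_cast<size_t>(H) * st.T2 * b;
          for (int t = 0; t < st.T2; ++t) {
            int tin = t * st.s2 - st.pl2 + i;
            if (tin < 0 || tin >= st.Tp1) continue;
            float* dst = slab + static_cast<size_t>(H) * tin;
            const float* s2 = srcb + static_cast<size_t>(H) * t;
            for (int h = 0; h < H; ++h) dst[h] += s2[h];
          }
        }
      }
  }
  // pool1 + relu1 backward
  std::fill(st.dZ1.begin(), st.dZ1.begin() + r1 * st.f1, 0.0f);
  for (size_t j = 0; j < p1sz; ++j) {
    int tgt = st.am1[j];
    if (st.Z1[tgt] > 0.0f) st.dZ1[tgt] += st.dP1[j];
  }
  {
    arma::fmat A(st.A1.data(), r1, static_cast<size_t>(st.k1) * st.C0, false, true);
    arma::fmat dZ(st.dZ1.data(), r1, st.f1, false, true);
    arma::fmat G = A.t() * dZ;
    for (R_xlen_t j = 0; j < gW1.size(); ++j) gW1[j] = static_cast<double>(G[j]);
    for (int f = 0; f < st.f1; ++f) {
      double s = 0;
      const float* zc = st.dZ1.data() + r1 * f;
      for (size_t j = 0; j < r1; ++j) s += zc[j];
      gb1[f] = s;
    }
  }
}

// Allocating convenience wrapper around cnn_stack_backward_into (used by the
// dual-route tests; the training loop uses the in-place variant).
// [[Rcpp::export(rng = false)]]
List cnn_stack_backward(NumericMatrix dD1,
                        NumericVector w1, IntegerVector w1dim,
                        NumericVector w2, IntegerVector w2dim,
                        NumericMatrix wd1) {
  NumericVector dW1(w1.size()), db1(w1dim[2]);
  NumericVector dW2(w2.size()), db2(w2dim[2]);
  NumericMatrix dWd1(wd1.nrow(), wd1.ncol());
  NumericVector dbd1(wd1.ncol());
  cnn_stack_backward_into(dD1, w1, w1dim, w2, w2dim, wd1,
                          dW1, db1, dW2, db2, dWd1, dbd1);
  dW1.attr("dim") = w1dim;
  dW2.attr("dim") = w2dim;
  return List::create(_["dW1"] = dW1, _["db1"] = db1, _["dW2"] = dW2,
                      _["db2"] = db2, _["dWd1"] = dWd1, _["dbd1"] = dbd1);
}

// In-place Adam update: w, m, v are modified directly (they are private to
// the training loop). t is the 1-based step count.
// [[Rcpp::export(rng = false)]]
void adam_step_inplace(NumericVector w, NumericVector g,
                       NumericVector m, NumericVector v, int t,
                       double lr, double beta1, double beta2, double eps) {
  R_xlen_t n = w.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam buffers must match the parameter length");
  double c1 = 1.0 - std::pow(beta1, t);
  double c2 = 1.0 - std::pow(beta2, t);
  double* wp = REAL(w); double* gp = REAL(g);
  double* mp = REAL(m); double* vp = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// Post-ReLU convolutional activations of the most recent forward pass as a
// (B, H, Tx, Fx) double array.
// [[Rcpp::export(rng = false)]]
NumericVector cnn_stack_activation(std::string layer) {
  if (st.B < 0) stop("cnn_stack_forward must be called first");
  int B = st.B, H = st.H;
  const std::vector<float>* buf;
  int Tx, Fx;
  if (layer == "Conv1") { buf = &st.Z1; Tx = st.T1; Fx = st.f1; }
  else if (layer == "Conv2") { buf = &st.Z2; Tx = st.T2; Fx = st.f2; }
  else stop("unknown layer");
  NumericVector out(static_cast<R_xlen_t>(B) * H * Tx * Fx);
  double* op = REAL(out);
  // source layout (H, Tx, B, Fx) -> dest (B, H, Tx, Fx)
  for (int f = 0; f < Fx; ++f)
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tx; ++t) {
        const float* src = buf->data() + static_cast<size_t>(H) *
          (t + static_cast<size_t>(Tx) * (b + static_cast<size_t>(B) * f));
        for (int h = 0; h < H; ++h)
          op[b + static_cast<size_t>(B) *
             (h + static_cast<size_t>(H) * (t + static_cast<size_t>(Tx) * f))] =
            static_cast<double>(src[h]);
      }
  out.attr("dim") = IntegerVector::create(B, H, Tx, Fx);
  return out;
}

// Permutation entropy of the time series of a stored activation layer,
// averaged over filters: returns a B x H matrix (per epoch and channel row).
// Series run along t of the (H, Tx, B, Fx) buffer; ties rank by order of
// appearance, matching pe_cols().
// [[Rcpp::export(rng = false)]]
NumericMatrix cnn_stack_pe(std::string layer, int order, int delay) {
  if (st.B < 0) stop("cnn_stack_forward must be called first");
  if (order < 2 || order > 7) stop("order must be in 2..7");
  int B = st.B, H = st.H;
  const std::vector<float>* buf;
  int Tx, Fx;
  if (layer == "Conv1") { buf = &st.Z1; Tx = st.T1; Fx = st.f1; }
  else if (layer == "Conv2") { buf = &st.Z2; Tx = st.T2; Fx = st.f2; }
  else stop("unknown layer");
  int span = (order - 1) * delay;
  if (Tx < span + 1) stop("temporal length too short for PE at this layer");
  int nwin = Tx - span;
  int ncode = 1;
  for (int j = 0; j < order; ++j) ncode *= order;
  std::vector<int> counts(ncode);
  std::vector<int> touched;
  std::vector<double> v(order);
  NumericMatrix out(B, H);
  for (int f = 0; f < Fx; ++f)
    for (int b = 0; b < B; ++b)
      for (int h = 0; h < H; ++h) {
        const float* base = buf->data() + h +
          static_cast<size_t>(H) * (static_cast<size_t>(Tx) * (b + static_cast<size_t>(B) * f));
        std::fill(counts.begin(), counts.end(), 0);
        touched.clear();
        for (int w = 0; w < nwin; ++w) {
          for (int j = 0; j < order; ++j)
            v[j] = base[static_cast<size_t>(H) * (w + j * delay)];
          int code = 0, mult = 1;
          for (int j = 0; j < order; ++j) {
            int rnk = 0;
            for (int kk = 0; kk < order; ++kk) {
              if (kk == j) continue;
              if (v[kk] < v[j] || (v[kk] == v[j] && kk < j)) ++rnk;
            }
            code += rnk * mult;
            mult *= order;
          }
          if (counts[code] == 0) touched.push_back(code);
          ++counts[code];
        }
        double hent = 0.0;
        for (size_t ti = 0; ti < touched.size(); ++ti) {
          double p = static_cast<double>(counts[touched[ti]]) / nwin;
          hent -= p * std::log2(p);
        }
        out(b, h) += hent;
      }
  for (int b = 0; b < B; ++b)
    for (int h = 0; h < H; ++h) out(b, h) /= Fx;
  return out;
}

// Release all persistent buffers (tests use this to bound resident memory).
// [[Rcpp::export(rng = false)]]
void cnn_stack_release() {
  st = StackState();
}
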