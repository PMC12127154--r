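// Fused two-layer view encoder:
//   conv1 (k1, "same") -> ReLU -> average pool (stride s) ->
//   conv2 (k2, "same") -> ReLU -> adaptive average pool to Lout.
// One pass per sample with all intermediates in cache-resident workspace
// buffers, held time-major (L x channels) so every conv GEMM is tall
// (M = time steps) where BLAS is efficient, and so im2col reduces to
// per-tap memcpys of contiguous column segments. The backward pass
// recomputes the forward tiles instead of caching them, trading a little
// compute for an order of magnitude less memory traffic (the dominant cost
// on a single core). Input gradients are not needed (views are the network
// input), so only parameter gradients are produced. Adaptive pooling bins
// follow the standard rule [floor(o Lin / Lout), ceil((o+1) Lin / Lout)).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct EncShapes {
  int Cin, L, N, C1, C2, k1, k2, pl1, pl2, s, L2, Lout;
};

// time-major im2col: colT (L x Cin*k) column (j*Cin + ci) is channel ci's
// timeline shifted by j - pl; xt is (L x Cin), both zero-padded implicitly
static void fill_colT(const mat& xt, mat& colT, int k, int pl) {
  const int L = xt.n_rows, Cin = xt.n_cols;
  for (int j = 0; j < k; ++j) {
    const int d = j - pl;                     // source shift
    const int t0 = std::max(0, -d), t1 = L - 1 - std::max(0, d);
    for (int ci = 0; ci < Cin; ++ci) {
      double* dst = colT.colptr(j * Cin + ci);
      const double* src = xt.colptr(ci);
      if (t0 > 0) std::memset(dst, 0, sizeof(double) * t0);
      if (t1 < L - 1) std::memset(dst + t1 + 1, 0,
                                  sizeof(double) * (L - 1 - t1));
      if (t0 <= t1)
        std::memcpy(dst + t0, src + t0 + d, sizeof(double) * (t1 - t0 + 1));
    }
  }
}

static inline void relu_inplace(mat& m) {
  double* p = m.memptr();
  const std::size_t n = m.n_elem;
  for (std::size_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// forward tiles for one sample; returns through the workspace references
static void enc_sample_fwd(const double* X, const EncShapes& sh,
                           const mat& W1t, const rowvec& b1t,
                           const mat& W2t, const rowvec& b2t,
                           mat& xt, mat& col1T, mat& y1t, mat& p1t,
                           mat& col2T, mat& y2t,
                           const std::vector<int>& bin_lo,
                           const std::vector<int>& bin_hi, mat& outT) {
  for (int ci = 0; ci < sh.Cin; ++ci) {       // transpose sample to (L, Cin)
    double* dst = xt.colptr(ci);
    for (int t = 0; t < sh.L; ++t)
      dst[t] = X[static_cast<std::size_t>(t) * sh.Cin + ci];
  }
  fill_colT(xt, col1T, sh.k1, sh.pl1);
  y1t = col1T * W1t;
  y1t.each_row() += b1t;
  relu_inplace(y1t);
  const double inv_s = 1.0 / sh.s;
  for (int c = 0; c < sh.C1; ++c) {           // stride pool, column-wise
    const double* src = y1t.colptr(c);
    double* dst = p1t.colptr(c);
    for (int g = 0; g < sh.L2; ++g) {
      double acc = 0;
      const double* sg = src + static_cast<std::size_t>(g) * sh.s;
      for (int t = 0; t < sh.s; ++t) acc += sg[t];
      dst[g] = acc * inv_s;
    }
  }
  fill_colT(p1t, col2T, sh.k2, sh.pl2);
  y2t = col2T * W2t;
  y2t.each_row() += b2t;
  relu_inplace(y2t);
  for (int c = 0; c < sh.C2; ++c) {           // adaptive pool, column-wise
    const double* src = y2t.colptr(c);
    double* dst = outT.colptr(c);
    for (int o = 0; o < sh.Lout; ++o) {
      double acc = 0;
      for (int t = bin_lo[o]; t <= bin_hi[o]; ++t) acc += src[t];
      dst[o] = acc / (bin_hi[o] - bin_lo[o] + 1);
    }
  }
}

static EncShapes get_shapes(Rcpp::NumericVector x, int C1, int C2,
                            int k1, int k2, int s, int Lout) {
  Rcpp::IntegerVector dims = x.attr("dim");
  EncShapes sh;
  sh.Cin = dims[0]; sh.L = dims[1]; sh.N = dims[2];
  sh.C1 = C1; sh.C2 = C2; sh.k1 = k1; sh.k2 = k2;
  sh.pl1 = (k1 - 1) / 2; sh.pl2 = (k2 - 1) / 2;
  sh.s = s; sh.L2 = sh.L / s; sh.Lout = Lout;
  return sh;
}

static void get_bins(const EncShapes& sh, std::vector<int>& lo,
                     std::vector<int>& hi) {
  lo.resize(sh.Lout); hi.resize(sh.Lout);
  for (int o = 0; o < sh.Lout; ++o) {
    lo[o] = (int)std::floor((double)o * sh.L2 / sh.Lout);
    hi[o] = (int)std::ceil((double)(o + 1) * sh.L2 / sh.Lout) - 1;
  }
}

// [[Rcpp::export(name = ".enc_fwd_cpp")]]
Rcpp::NumericVector enc_fwd_cpp(Rcpp::NumericVector x,
                                Rcpp::NumericMatrix W1, Rcpp::NumericVector b1,
                                Rcpp::NumericMatrix W2, Rcpp::NumericVector b2,
                                int k1, int k2, int s, int Lout) {
  const EncShapes sh = get_shapes(x, W1.nrow(), W2.nrow(), k1, k2, s, Lout);
  const mat W1m(W1.begin(), W1.nrow(), W1.ncol(), false);
  const mat W2m(W2.begin(), W2.nrow(), W2.ncol(), false);
  const mat W1t = W1m.t(), W2t = W2m.t();
  const rowvec b1t(b1.begin(), b1.size());
  const rowvec b2t(b2.begin(), b2.size());
  std::vector<int> bin_lo, bin_hi;
  get_bins(sh, bin_lo, bin_hi);
  Rcpp::NumericVector y(static_cast<R_xlen_t>(sh.C2) * sh.Lout * sh.N);
  y.attr("dim") = Rcpp::IntegerVector::create(sh.C2, sh.Lout, sh.N);
  mat xt(sh.L, sh.Cin), col1T(sh.L, static_cast<std::size_t>(sh.Cin) * sh.k1);
  mat y1t(sh.L, sh.C1), p1t(sh.L2, sh.C1);
  mat col2T(sh.L2, static_cast<std::size_t>(sh.C1) * sh.k2);
  mat y2t(sh.L2, sh.C2), outT(sh.Lout, sh.C2);
  const std::size_t xstride = static_cast<std::size_t>(sh.Cin) * sh.L;
  const std::size_t ystride = static_cast<std::size_t>(sh.C2) * sh.Lout;
  for (int n = 0; n < sh.N; ++n) {
    enc_sample_fwd(x.begin() + n * xstride, sh, W1t, b1t, W2t, b2t,
                   xt, col1T, y1t, p1t, col2T, y2t, bin_lo, bin_hi, outT);
    double* Y = y.begin() + n * ystride;      // write back channel-major
    for (int c = 0; c < sh.C2; ++c) {
      const double* src = outT.colptr(c);
      for (int o = 0; o < sh.Lout; ++o)
        Y[static_cast<std::size_t>(o) * sh.C2 + c] = src[o];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".enc_bwd_cpp")]]
Rcpp::List enc_bwd_cpp(Rcpp::NumericVector dy, Rcpp::NumericVector x,
                       Rcpp::NumericMatrix W1, Rcpp::NumericVector b1,
                       Rcpp::NumericMatrix W2, Rcpp::NumericVector b2,
                       int k1, int k2, int s, int Lout) {
  const EncShapes sh = get_shapes(x, W1.nrow(), W2.nrow(), k1, k2, s, Lout);
  const mat W1m(W1.begin(), W1.nrow(), W1.ncol(), false);
  const mat W2m(W2.begin(), W2.nrow(), W2.ncol(), false);
  const mat W1t = W1m.t(), W2t = W2m.t();
  const rowvec b1t(b1.begin(), b1.size());
  const rowvec b2t(b2.begin(), b2.size());
  std::vector<int> bin_lo, bin_hi;
  get_bins(sh, bin_lo, bin_hi);
  mat dW1t(static_cast<std::size_t>(sh.Cin) * sh.k1, sh.C1, fill::zeros);
  mat dW2t(static_cast<std::size_t>(sh.C1) * sh.k2, sh.C2, fill::zeros);
  rowvec db1(sh.C1, fill::zeros), db2(sh.C2, fill::zeros);
  mat xt(sh.L, sh.Cin), col1T(sh.L, static_cast<std::size_t>(sh.Cin) * sh.k1);
  mat y1t(sh.L, sh.C1), dy1t(sh.L, sh.C1);
  mat p1t(sh.L2, sh.C1), dp1t(sh.L2, sh.C1);
  mat col2T(sh.L2, static_cast<std::size_t>(sh.C1) * sh.k2);
  mat dcol2T(sh.L2, static_cast<std::size_t>(sh.C1) * sh.k2);
  mat y2t(sh.L2, sh.C2), dy2t(sh.L2, sh.C2), outT(sh.Lout, sh.C2);
  const std::size_t xstride = static_cast<std::size_t>(sh.Cin) * sh.L;
  const std::size_t ystride = static_cast<std::size_t>(sh.C2) * sh.Lout;
  for (int n = 0; n < sh.N; ++n) {
    enc_sample_fwd(x.begin() + n * xstride, sh, W1t, b1t, W2t, b2t,
                   xt, col1T, y1t, p1t, col2T, y2t, bin_lo, bin_hi, outT);
    const double* dOut = dy.begin() + n * ystride;   // (C2, Lout) slice
    // adaptive-pool backward, then ReLU mask (y2t holds post-ReLU values)
    for (int c = 0; c < sh.C2; ++c) {
      double* dst = dy2t.colptr(c);
      std::memset(dst, 0, sizeof(double) * sh.L2);
      for (int o = 0; o < sh.Lout; ++o) {
        const double g = dOut[static_cast<std::size_t>(o) * sh.C2 + c] /
                         (bin_hi[o] - bin_lo[o] + 1);
        for (int t = bin_lo[o]; t <= bin_hi[o]; ++t) dst[t] += g;
      }
      const double* yv = y2t.colptr(c);
      for (int t = 0; t < sh.L2; ++t)
        if (yv[t] == 0) dst[t] = 0;
      db2[c] += accu(dy2t.col(c));
    }
    dW2t += col2T.t() * dy2t;
    dcol2T = dy2t * W2t.t();
    // col2im (time-major): accumulate shifted columns into dp1t
    dp1t.zeros();
    for (int j = 0; j < sh.k2; ++j) {
      const int d = j - sh.pl2;
      const int t0 = std::max(0, -d), t1 = sh.L2 - 1 - std::max(0, d);
      if (t0 > t1) continue;
      for (int ci = 0; ci < sh.C1; ++ci) {
        const double* src = dcol2T.colptr(j * sh.C1 + ci);
        double* dst = dp1t.colptr(ci);
        for (int t = t0; t <= t1; ++t) dst[t + d] += src[t];
      }
    }
    // stride-pool backward + ReLU mask
    const double inv_s = 1.0 / sh.s;
    for (int c = 0; c < sh.C1; ++c) {
      const double* src = dp1t.colptr(c);
      const double* yv = y1t.colptr(c);
      double* dst = dy1t.colptr(c);
      for (int g = 0; g < sh.L2; ++g) {
        const double v = src[g] * inv_s;
        double* dg = dst + static_cast<std::size_t>(g) * sh.s;
        const double* yg = yv + static_cast<std::size_t>(g) * sh.s;
        for (int t = 0; t < sh.s; ++t) dg[t] = yg[t] > 0 ? v : 0;
      }
      db1[c] += accu(dy1t.col(c));
    }
    dW1t += col1T.t() * dy1t;
  }
  return Rcpp::List::create(Rcpp::Named("dW1") = mat(dW1t.t()),
                            Rcpp::Named("db1") = vec(db1.t()),
                            Rcpp::Named("dW2") = mat(dW2t.t()),
                            Rcpp::Named("db2") = vec(db2.t()));
}
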