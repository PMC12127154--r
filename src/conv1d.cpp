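// Generic 1-D convolution (cross-correlation) kernels. Data layout matches
// the R side: signals are (channels, length, batch) column-major cubes;
// weights are (C_out, C_in * k) with tap j occupying columns
// (j-1)*C_in + 1 .. j*C_in. Per-sample im2col into a reused buffer feeds one
// GEMM per sample; the per-sample column matrix stays cache-resident. Used
// for the TDFE branches and any non-default encoder shape (the default
// two-layer view encoder has a dedicated fused kernel in encoder.cpp).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// copy the valid taps of sample X (Cin x L) into colm (Cin*k x L);
// colm's padding positions are zeroed once by the caller
static inline void fill_col(const double* X, double* colm,
                            int Cin, int L, int k, int pl) {
  const std::size_t nb = sizeof(double) * Cin;
  for (int t = 0; t < L; ++t) {
    double* cptr = colm + static_cast<std::size_t>(t) * Cin * k;
    const int jlo = std::max(0, pl - t);
    const int jhi = std::min(k, L + pl - t);
    for (int j = jlo; j < jhi; ++j)
      std::memcpy(cptr + j * Cin, X + static_cast<std::size_t>(t + j - pl) * Cin,
                  nb);
  }
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
Rcpp::NumericVector conv1d_fwd_cpp(Rcpp::NumericVector x, Rcpp::NumericMatrix W,
                                   Rcpp::NumericVector b, int k, int pl) {
  Rcpp::IntegerVector dims = x.attr("dim");
  const int Cin = dims[0], L = dims[1], N = dims[2];
  const mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  const vec bv(b.begin(), b.size(), false);
  const int Cout = Wm.n_rows;
  Rcpp::NumericVector y(static_cast<R_xlen_t>(Cout) * L * N);
  y.attr("dim") = Rcpp::IntegerVector::create(Cout, L, N);
  const std::size_t xstride = static_cast<std::size_t>(Cin) * L;
  const std::size_t ystride = static_cast<std::size_t>(Cout) * L;
  mat colm(static_cast<std::size_t>(Cin) * k, L, fill::zeros);
  for (int n = 0; n < N; ++n) {
    fill_col(x.begin() + n * xstride, colm.memptr(), Cin, L, k, pl);
    mat Yn(y.begin() + n * ystride, Cout, L, false, true);
    Yn = Wm * colm;
    Yn.each_col() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
Rcpp::List conv1d_bwd_cpp(Rcpp::NumericVector dy, Rcpp::NumericVector x,
                          Rcpp::NumericMatrix W, int k, int pl) {
  Rcpp::IntegerVector dims = x.attr("dim");
  const int Cin = dims[0], L = dims[1], N = dims[2];
  const mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  const int Cout = Wm.n_rows;
  Rcpp::NumericVector dx(static_cast<R_xlen_t>(Cin) * L * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(Cin, L, N);
  mat dW(Cout, static_cast<std::size_t>(Cin) * k, fill::zeros);
  vec db(Cout, fill::zeros);
  const std::size_t xstride = static_cast<std::size_t>(Cin) * L;
  const std::size_t ystride = static_cast<std::size_t>(Cout) * L;
  mat colm(static_cast<std::size_t>(Cin) * k, L, fill::zeros);
  mat dcol(static_cast<std::size_t>(Cin) * k, L);
  for (int n = 0; n < N; ++n) {
    const mat dYn(const_cast<double*>(dy.begin()) + n * ystride, Cout, L,
                  false, true);
    fill_col(x.begin() + n * xstride, colm.memptr(), Cin, L, k, pl);
    dW += dYn * colm.t();
    db += sum(dYn, 1);
    dcol = Wm.t() * dYn;
    double* dXn = dx.begin() + n * xstride;
    for (int t = 0; t < L; ++t) {
      const double* dcptr = dcol.colptr(t);
      const int jlo = std::max(0, pl - t);
      const int jhi = std::min(k, L + pl - t);
      for (int j = jlo; j < jhi; ++j) {
        double* dst = dXn + static_cast<std::size_t>(t + j - pl) * Cin;
        const double* src = dcptr + j * Cin;
        for (int c = 0; c < Cin; ++c) dst[c] += src[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
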