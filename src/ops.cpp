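// Elementwise and pooling kernels: ReLU forward/backward and non-overlapping
// strided average pooling on (channels, length, batch) cubes. These are pure
// memory-bound passes; doing them in one compiled sweep avoids the multiple
// intermediate copies R-level vector ops would make.

#include <Rcpp.h>

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
Rcpp::NumericVector relu_fwd_cpp(Rcpp::NumericVector x) {
  Rcpp::NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yi[i] = xi[i] > 0 ? xi[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
Rcpp::NumericVector relu_bwd_cpp(Rcpp::NumericVector dy, Rcpp::NumericVector y) {
  Rcpp::NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* di = dy.begin();
  const double* yi = y.begin();
  double* o = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = yi[i] > 0 ? di[i] : 0.0;
  return dx;
}

// x: (C, L, N) with L divisible by s -> (C, L/s, N)
// [[Rcpp::export(name = ".avgpool_fwd_cpp")]]
Rcpp::NumericVector avgpool_fwd_cpp(Rcpp::NumericVector x, int s) {
  Rcpp::IntegerVector dims = x.attr("dim");
  const int C = dims[0], L = dims[1], N = dims[2];
  const int Lo = L / s;
  Rcpp::NumericVector y(static_cast<R_xlen_t>(C) * Lo * N);
  y.attr("dim") = Rcpp::IntegerVector::create(C, Lo, N);
  const double inv = 1.0 / s;
  const double* xi = x.begin();
  double* yi = y.begin();
  const R_xlen_t ngroups = static_cast<R_xlen_t>(Lo) * N;
  for (R_xlen_t g = 0; g < ngroups; ++g) {
    double* yg = yi + g * C;
    const double* xg = xi + g * C * s;
    for (int c = 0; c < C; ++c) yg[c] = 0.0;
    for (int t = 0; t < s; ++t) {
      const double* xt = xg + static_cast<R_xlen_t>(t) * C;
      for (int c = 0; c < C; ++c) yg[c] += xt[c];
    }
    for (int c = 0; c < C; ++c) yg[c] *= inv;
  }
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd_cpp")]]
Rcpp::NumericVector avgpool_bwd_cpp(Rcpp::NumericVector dy, int s) {
  Rcpp::IntegerVector dims = dy.attr("dim");
  const int C = dims[0], Lo = dims[1], N = dims[2];
  Rcpp::NumericVector dx(static_cast<R_xlen_t>(C) * Lo * s * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(C, Lo * s, N);
  const double inv = 1.0 / s;
  const double* di = dy.begin();
  double* o = dx.begin();
  const R_xlen_t ngroups = static_cast<R_xlen_t>(Lo) * N;
  for (R_xlen_t g = 0; g < ngroups; ++g) {
    const double* dg = di + g * C;
    double* og = o + g * C * s;
    for (int t = 0; t < s; ++t) {
      double* ot = og + static_cast<R_xlen_t>(t) * C;
      for (int c = 0; c < C; ++c) ot[c] = dg[c] * inv;
    }
  }
  return dx;
}
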