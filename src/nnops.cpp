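// Fused layer primitives for the 3D U-Net engine: im2col convolution with
// direct BLAS dgemm, affine-free instance normalisation and per-channel
// PReLU, each with a hand-derived backward pass. Keeping these in C++
// avoids large R temporaries (the feature maps run to tens of MB).
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

NumericMatrix im2col3d(NumericVector x, IntegerVector dims, int k,
                       int stride, int pad);
NumericVector col2im3d(NumericMatrix cols, IntegerVector dims, int k,
                       int stride, int pad);

static inline int outdim(int d, int k, int stride, int pad) {
  return (d + 2 * pad - k) / stride + 1;
}

// x: (X,Y,Z,Cin) column-major; Wm: (k^3*Cin) x Cout; returns y laid out
// (Xo,Yo,Zo,Cout) plus the (N x R) im2col buffer for the backward pass.
// [[Rcpp::export]]
List conv_fwd_cpp(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                  NumericVector b, int k, int stride, int pad) {
  NumericMatrix cols = im2col3d(x, dims, k, stride, pad);
  const int N = cols.nrow();
  const int R = cols.ncol();
  const int cout = Wm.ncol();
  NumericVector y((R_xlen_t)N * cout);
  const double one = 1.0, zero = 0.0;
  // y (N x cout) = cols (N x R) * Wm (R x cout)
  F77_CALL(dgemm)("N", "N", &N, &cout, &R, &one, cols.begin(), &N,
                  Wm.begin(), &R, &zero, y.begin(), &N FCONE FCONE);
  double *py = y.begin();
  for (int c = 0; c < cout; ++c) {
    const double bc = b[c];
    for (int i = 0; i < N; ++i) py[(R_xlen_t)c * N + i] += bc;
  }
  return List::create(_["y"] = y, _["cols"] = cols);
}

// dy: (N x cout) flattened; returns dW (R x cout), db, dx.
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector dy, NumericMatrix cols, NumericMatrix Wm,
                  IntegerVector dims, int k, int stride, int pad) {
  const int N = cols.nrow();
  const int R = cols.ncol();
  const int cout = Wm.ncol();
  const double one = 1.0, zero = 0.0;
  NumericMatrix dW(R, cout);
  // dW (R x cout) = cols' (R x N) * dy (N x cout)
  F77_CALL(dgemm)("T", "N", &R, &cout, &N, &one, cols.begin(), &N,
                  dy.begin(), &N, &zero, dW.begin(), &R FCONE FCONE);
  NumericVector db(cout);
  const double *pdy = dy.begin();
  for (int c = 0; c < cout; ++c) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += pdy[(R_xlen_t)c * N + i];
    db[c] = s;
  }
  // dcols (N x R) = dy (N x cout) * Wm' (cout x R)
  NumericMatrix dcols(N, R);
  F77_CALL(dgemm)("N", "T", &N, &R, &cout, &one, dy.begin(), &N,
                  Wm.begin(), &R, &zero, dcols.begin(), &N FCONE FCONE);
  NumericVector dx = col2im3d(dcols, dims, k, stride, pad);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Affine-free instance normalisation over the spatial dims of each channel.
// [[Rcpp::export]]
List instnorm_fwd_cpp(NumericVector x, int nspat, int C, double eps) {
  NumericVector y(x.size());
  NumericVector isd(C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * nspat;
    double *yc = py + (R_xlen_t)c * nspat;
    double mu = 0.0;
    for (int i = 0; i < nspat; ++i) mu += xc[i];
    mu /= nspat;
    double va = 0.0;
    for (int i = 0; i < nspat; ++i) {
      const double d = xc[i] - mu;
      va += d * d;
    }
    va /= nspat;
    const double s = 1.0 / std::sqrt(va + eps);
    isd[c] = s;
    for (int i = 0; i < nspat; ++i) yc[i] = (xc[i] - mu) * s;
  }
  return List::create(_["y"] = y, _["isd"] = isd);
}

// [[Rcpp::export]]
NumericVector instnorm_bwd_cpp(NumericVector dy, NumericVector y,
                               NumericVector isd, int nspat, int C) {
  NumericVector dx(dy.size());
  const double *pdy = dy.begin(), *py = y.begin();
  double *pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double *dyc = pdy + (R_xlen_t)c * nspat;
    const double *yc = py + (R_xlen_t)c * nspat;
    double *dxc = pdx + (R_xlen_t)c * nspat;
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < nspat; ++i) {
      m1 += dyc[i];
      m2 += dyc[i] * yc[i];
    }
    m1 /= nspat;
    m2 /= nspat;
    const double s = isd[c];
    for (int i = 0; i < nspat; ++i)
      dxc[i] = (dyc[i] - m1 - yc[i] * m2) * s;
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector prelu_fwd_cpp(NumericVector x, NumericVector a, int nspat) {
  const int C = a.size();
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double *xc = px + (R_xlen_t)c * nspat;
    double *yc = py + (R_xlen_t)c * nspat;
    for (int i = 0; i < nspat; ++i)
      yc[i] = xc[i] >= 0 ? xc[i] : ac * xc[i];
  }
  return y;
}

// [[Rcpp::export]]
List prelu_bwd_cpp(NumericVector dy, NumericVector x, NumericVector a,
                   int nspat) {
  const int C = a.size();
  NumericVector dx(dy.size());
  NumericVector da(C);
  const double *pdy = dy.begin(), *px = x.begin();
  double *pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double *dyc = pdy + (R_xlen_t)c * nspat;
    const double *xc = px + (R_xlen_t)c * nspat;
    double *dxc = pdx + (R_xlen_t)c * nspat;
    double s = 0.0;
    for (int i = 0; i < nspat; ++i) {
      if (xc[i] >= 0) {
        dxc[i] = dyc[i];
      } else {
        dxc[i] = ac * dyc[i];
        s += dyc[i] * xc[i];
      }
    }
    da[c] = s;
  }
  return List::create(_["dx"] = dx, _["da"] = da);
}
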