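// Gather/scatter primitives for 3D convolution (im2col / col2im).
// Feature maps are column-major arrays of layout (X, Y, Z, C). The im2col
// buffer is laid out (N x R) with N = Xo*Yo*Zo output voxels (xo fastest)
// and R = k^3*C kernel taps ordered (dx, dy, dz, c) with dx fastest --
// matching an R weight array of dim (k, k, k, Cin, Cout) flattened over
// its first four dimensions. With this layout every (tap, zo, yo) slice
// is one contiguous run over xo, so stride-1 convolutions reduce to
// straight memcpy/axpy passes.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims, int k,
                       int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = (X + 2 * pad - k) / stride + 1;
  const int Yo = (Y + 2 * pad - k) / stride + 1;
  const int Zo = (Z + 2 * pad - k) / stride + 1;
  const int R = k * k * k * C;
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  NumericMatrix out(N, R);
  const double *px = x.begin();
  const R_xlen_t sy = X, sz = (R_xlen_t)X * Y, sc = (R_xlen_t)X * Y * Z;
  int r = 0;
  for (int c = 0; c < C; ++c) {
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx, ++r) {
          double *pr = out.begin() + (R_xlen_t)r * N;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + dz;
            if (zi < 0 || zi >= Z) {
              std::memset(pr, 0, sizeof(double) * Xo * Yo);
              pr += (R_xlen_t)Xo * Yo;
              continue;
            }
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + dy;
              if (yi < 0 || yi >= Y) {
                std::memset(pr, 0, sizeof(double) * Xo);
                pr += Xo;
                continue;
              }
              const double *ps = px + c * sc + zi * sz + yi * sy;
              const int off = dx - pad;
              if (stride == 1) {
                const int lo = std::max(0, -off);          // first valid xo
                const int hi = std::min(Xo, X - off);      // one past last
                for (int xo = 0; xo < lo; ++xo) pr[xo] = 0.0;
                if (hi > lo)
                  std::memcpy(pr + lo, ps + lo + off,
                              sizeof(double) * (hi - lo));
                for (int xo = hi; xo < Xo; ++xo) pr[xo] = 0.0;
              } else {
                for (int xo = 0; xo < Xo; ++xo) {
                  const int xi = xo * stride + off;
                  pr[xo] = (xi >= 0 && xi < X) ? ps[xi] : 0.0;
                }
              }
              pr += Xo;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector dims, int k,
                       int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = (X + 2 * pad - k) / stride + 1;
  const int Yo = (Y + 2 * pad - k) / stride + 1;
  const int Zo = (Z + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  NumericVector out((R_xlen_t)X * Y * Z * C);
  double *po = out.begin();
  const R_xlen_t sy = X, sz = (R_xlen_t)X * Y, sc = (R_xlen_t)X * Y * Z;
  int r = 0;
  for (int c = 0; c < C; ++c) {
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx, ++r) {
          const double *pr = cols.begin() + (R_xlen_t)r * N;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + dz;
            if (zi < 0 || zi >= Z) {
              pr += (R_xlen_t)Xo * Yo;
              continue;
            }
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + dy;
              if (yi < 0 || yi >= Y) {
                pr += Xo;
                continue;
              }
              double *ps = po + c * sc + zi * sz + yi * sy;
              const int off = dx - pad;
              if (stride == 1) {
                const int lo = std::max(0, -off);
                const int hi = std::min(Xo, X - off);
                for (int xo = lo; xo < hi; ++xo) ps[xo + off] += pr[xo];
              } else {
                for (int xo = 0; xo < Xo; ++xo) {
                  const int xi = xo * stride + off;
                  if (xi >= 0 && xi < X) ps[xi] += pr[xo];
                }
              }
              pr += Xo;
            }
          }
        }
      }
    }
  }
  return out;
}
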