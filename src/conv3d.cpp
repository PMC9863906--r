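// 3D convolution primitives for the volumetric network engine.
//
// Layout conventions (match the R side everywhere):
//   * volumes are column-major arrays dim = (X, Y, Z, C): element (x,y,z,c)
//     sits at x + X*(y + Y*(z + Z*c)), 0-based.
//   * weights are a (k^3 * Cin) x Cout matrix whose row index is
//     kx + k*(ky + k*(kz + k*ci)).
//   * "same" padding is asymmetric in the TensorFlow sense: pad_lo given,
//     out side = ceil(n / stride); indices falling outside the volume read
//     as zero (forward) or are dropped (backward scatter).
//
// Forward, backward-data and backward-filter are all expressed as an
// im2col gather per output z-plane followed by one GEMM, which keeps peak
// memory at one plane's worth of columns.  Transposed convolution is the
// adjoint: its forward IS backward-data and vice versa, so no separate
// kernels are needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_side(int n, int stride) {
  return (n + stride - 1) / stride;
}

// Fill M ((Xo*Yo) x (k^3*Ci)) with the receptive-field columns of output
// plane zo.  Out-of-range taps stay zero.
static void gather_plane(const double* x, int X, int Y, int Z, int Ci,
                         int Xo, int Yo, int zo, int k, int stride,
                         int padlo, arma::mat& M) {
  M.zeros();
  const long XY = (long)X * Y;
  const long XYZ = XY * Z;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int kz = 0; kz < k; ++kz) {
      const int zi = zo * stride - padlo + kz;
      if (zi < 0 || zi >= Z) continue;
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * ci));
          double* dst = M.colptr(col);
          const double* src = x + XYZ * ci + XY * zi;
          for (int yo = 0; yo < Yo; ++yo) {
            const int yi = yo * stride - padlo + ky;
            if (yi < 0 || yi >= Y) continue;
            const double* srow = src + (long)X * yi;
            double* drow = dst + (long)Xo * yo;
            for (int xo = 0; xo < Xo; ++xo) {
              const int xi = xo * stride - padlo + kx;
              if (xi < 0 || xi >= X) continue;
              drow[xo] = srow[xi];
            }
          }
        }
      }
    }
  }
}

// Adjoint of gather_plane: accumulate P ((Xo*Yo) x (k^3*Ci)) back into the
// input-shaped gradient gx.
static void scatter_plane(double* gx, int X, int Y, int Z, int Ci,
                          int Xo, int Yo, int zo, int k, int stride,
                          int padlo, const arma::mat& P) {
  const long XY = (long)X * Y;
  const long XYZ = XY * Z;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int kz = 0; kz < k; ++kz) {
      const int zi = zo * stride - padlo + kz;
      if (zi < 0 || zi >= Z) continue;
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * ci));
          const double* srcp = P.colptr(col);
          double* dst = gx + XYZ * ci + XY * zi;
          for (int yo = 0; yo < Yo; ++yo) {
            const int yi = yo * stride - padlo + ky;
            if (yi < 0 || yi >= Y) continue;
            double* drow = dst + (long)X * yi;
            const double* srow = srcp + (long)Xo * yo;
            for (int xo = 0; xo < Xo; ++xo) {
              const int xi = xo * stride - padlo + kx;
              if (xi < 0 || xi >= X) continue;
              drow[xi] += srow[xo];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericMatrix Wm, NumericVector b,
                             int k, int stride, int padlo) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Ci = xdim[3];
  const int Xo = out_side(X, stride), Yo = out_side(Y, stride),
            Zo = out_side(Z, stride);
  const int Co = Wm.ncol();
  if (Wm.nrow() != k * k * k * Ci)
    stop("weight matrix rows (%d) != k^3 * in_channels (%d)",
         Wm.nrow(), k * k * k * Ci);
  arma::mat W(Wm.begin(), Wm.nrow(), Co, false, true);
  arma::rowvec bias(b.begin(), Co, false, true);

  NumericVector out((R_xlen_t)Xo * Yo * Zo * Co);
  const long oXY = (long)Xo * Yo;
  const long oXYZ = oXY * Zo;
  arma::mat M(oXY, (long)k * k * k * Ci);
  for (int zo = 0; zo < Zo; ++zo) {
    gather_plane(x.begin(), X, Y, Z, Ci, Xo, Yo, zo, k, stride, padlo, M);
    arma::mat O = M * W;
    O.each_row() += bias;
    for (int co = 0; co < Co; ++co)
      std::memcpy(out.begin() + oXYZ * co + oXY * zo, O.colptr(co),
                  sizeof(double) * oXY);
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_data(NumericVector g, NumericMatrix Wm,
                                  int k, int stride, int padlo,
                                  IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Ci = xdim[3];
  const int Xo = out_side(X, stride), Yo = out_side(Y, stride),
            Zo = out_side(Z, stride);
  const int Co = Wm.ncol();
  if ((R_xlen_t)g.size() != (R_xlen_t)Xo * Yo * Zo * Co)
    stop("gradient size does not match the stated input dimensions");
  arma::mat W(Wm.begin(), Wm.nrow(), Co, false, true);

  NumericVector gx((R_xlen_t)X * Y * Z * Ci);  // zero-initialised
  const long oXY = (long)Xo * Yo;
  const long oXYZ = oXY * Zo;
  arma::mat G(oXY, Co);
  for (int zo = 0; zo < Zo; ++zo) {
    for (int co = 0; co < Co; ++co)
      std::memcpy(G.colptr(co), g.begin() + oXYZ * co + oXY * zo,
                  sizeof(double) * oXY);
    arma::mat P = G * W.t();
    scatter_plane(gx.begin(), X, Y, Z, Ci, Xo, Yo, zo, k, stride, padlo, P);
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  return gx;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_filter(NumericVector x, IntegerVector xdim,
                           NumericVector g, int Co,
                           int k, int stride, int padlo) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Ci = xdim[3];
  const int Xo = out_side(X, stride), Yo = out_side(Y, stride),
            Zo = out_side(Z, stride);
  if ((R_xlen_t)g.size() != (R_xlen_t)Xo * Yo * Zo * Co)
    stop("gradient size does not match input dimensions / out channels");

  const long K = (long)k * k * k * Ci;
  const long oXY = (long)Xo * Yo;
  const long oXYZ = oXY * Zo;
  arma::mat gW(K, Co, arma::fill::zeros);
  arma::rowvec gb(Co, arma::fill::zeros);
  arma::mat M(oXY, K);
  arma::mat G(oXY, Co);
  for (int zo = 0; zo < Zo; ++zo) {
    gather_plane(x.begin(), X, Y, Z, Ci, Xo, Yo, zo, k, stride, padlo, M);
    for (int co = 0; co < Co; ++co)
      std::memcpy(G.colptr(co), g.begin() + oXYZ * co + oXY * zo,
                  sizeof(double) * oXY);
    gW += M.t() * G;
    gb += arma::sum(G, 0);
  }
  return List::create(_["W"] = wrap(gW), _["b"] = wrap(arma::vec(gb.t())));
}
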