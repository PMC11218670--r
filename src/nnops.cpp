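#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <algorithm>
using namespace Rcpp;

// 3x3 convolution blocks for the small score network, via im2col + BLAS.
// Layout:
//   x: numeric array (H, W, Cin), R column-major
//   W: matrix (Cout, Cin * 9); row f holds kernel weights for output channel
//      f, column index c * 9 + (kx + 1) * 3 + (ky + 1) for input channel c
//      and offsets (ky, kx) in {-1, 0, 1}^2; out[r,c] += w * x[r+ky, c+kx]
//   b: length-Cout bias
// Zero padding, stride 1, shape preserving.

// patch matrix P (HW x Cin*9): column k holds the (ky,kx)-shifted channel
static arma::mat im2col3(const double* xp, int H, int W, int Cin) {
  const size_t HW = (size_t)H * W;
  arma::mat P(HW, (size_t)Cin * 9, arma::fill::zeros);
  for (int ch = 0; ch < Cin; ++ch) {
    const double* xc = xp + (size_t)ch * HW;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        double* col = P.colptr((size_t)ch * 9 + (kx + 1) * 3 + (ky + 1));
        const int r0 = std::max(0, -ky), r1 = H - 1 - std::max(0, ky);
        const int c0 = std::max(0, -kx), c1 = W - 1 - std::max(0, kx);
        for (int c = c0; c <= c1; ++c) {
          const double* src = xc + (size_t)(c + kx) * H + (r0 + ky);
          double* dst = col + (size_t)c * H + r0;
          std::copy(src, src + (r1 - r0 + 1), dst);
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector b) {
  const int H = dims[0], W = dims[1], Cin = dims[2];
  const int Cout = Wm.nrow();
  if (Wm.ncol() != Cin * 9) stop("weight shape mismatch");
  const size_t HW = (size_t)H * W;
  arma::mat P = im2col3(REAL(x), H, W, Cin);
  const arma::mat Wa(Wm.begin(), Cout, Cin * 9);
  arma::mat O = P * Wa.t();                      // (HW x Cout)
  for (int f = 0; f < Cout; ++f) O.col(f) += b[f];
  NumericVector out(HW * Cout);
  std::copy(O.memptr(), O.memptr() + HW * Cout, REAL(out));
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// gradient w.r.t. the input: dX[r+ky, c+kx] += dP[(r,c), k]
// [[Rcpp::export]]
NumericVector cpp_conv3_bwd_input(NumericVector delta, IntegerVector dims,
                                  NumericMatrix Wm, int Cin) {
  const int H = dims[0], W = dims[1], Cout = dims[2];
  const size_t HW = (size_t)H * W;
  const arma::mat D(REAL(delta), HW, Cout);
  const arma::mat Wa(Wm.begin(), Cout, Cin * 9);
  arma::mat dP = D * Wa;                         // (HW x Cin*9)
  NumericVector out(HW * Cin);
  double* op = REAL(out);
  for (int ch = 0; ch < Cin; ++ch) {
    double* oc = op + (size_t)ch * HW;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const double* col = dP.colptr((size_t)ch * 9 + (kx + 1) * 3 + (ky + 1));
        const int r0 = std::max(0, -ky), r1 = H - 1 - std::max(0, ky);
        const int c0 = std::max(0, -kx), c1 = W - 1 - std::max(0, kx);
        for (int c = c0; c <= c1; ++c) {
          const double* src = col + (size_t)c * H + r0;
          double* dst = oc + (size_t)(c + kx) * H + (r0 + ky);
          for (int r = r0; r <= r1; ++r) *dst++ += *src++;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cin);
  return out;
}

// gradients w.r.t. weights and bias, accumulated into gW / gb in place
// [[Rcpp::export]]
void cpp_conv3_bwd_weights(NumericVector x, IntegerVector dims,
                           NumericVector delta, int Cout,
                           NumericMatrix gW, NumericVector gb) {
  const int H = dims[0], W = dims[1], Cin = dims[2];
  const size_t HW = (size_t)H * W;
  arma::mat P = im2col3(REAL(x), H, W, Cin);
  const arma::mat D(REAL(delta), HW, Cout);
  arma::mat G = D.t() * P;                       // (Cout x Cin*9)
  for (int f = 0; f < Cout; ++f) {
    gb[f] += arma::accu(D.col(f));
    for (int k = 0; k < Cin * 9; ++k) gW(f, k) += G(f, k);
  }
}

// generic same-size 2D convolution (correlation) of a matrix with an odd
// kernel; boundary: 0 = zero pad, 1 = reflect (edge mirror without repeat)
// [[Rcpp::export]]
NumericMatrix cpp_conv2_same(NumericMatrix x, NumericMatrix k, int boundary) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = k.nrow(), kw = k.ncol();
  const int oy = kh / 2, ox = kw / 2;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int j = 0; j < kw; ++j) {
        int cc = c + j - ox;
        for (int i = 0; i < kh; ++i) {
          int rr = r + i - oy;
          double v;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
            if (boundary == 0) { v = 0.0; }
            else {
              int rm = rr < 0 ? -rr - 1 : (rr >= H ? 2 * H - rr - 1 : rr);
              int cm = cc < 0 ? -cc - 1 : (cc >= W ? 2 * W - cc - 1 : cc);
              if (rm < 0) rm = 0; if (rm >= H) rm = H - 1;
              if (cm < 0) cm = 0; if (cm >= W) cm = W - 1;
              v = x(rm, cm);
            }
          } else v = x(rr, cc);
          acc += k(i, j) * v;
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}
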