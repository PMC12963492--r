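// Low-level numeric kernels for the network engine: stride-1 same-padding
// 2-D convolution (im2col + GEMM) and 2x2 max pooling, with backward passes.
// Array layout follows R column-major conventions:
//   activations x : (H, W, C, N)
//   weights     w : (k, k, Cin, Cout)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int k, arma::mat& col) {
  // col: (k*k*C) x (H*W); zero padding of width (k-1)/2
  const int p = (k - 1) / 2;
  const int HW = H * W;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)HW * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - p;
          if (jj < 0 || jj >= W) continue;
          double* dst = col.colptr(H * j) + r; // advance by col stride manually
          const double* src = xc + H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - p;
            if (ii < 0 || ii >= H) continue;
            // col(r, i + H*j) = x(ii, jj, c)
            dst[(size_t)(col.n_rows) * i] = src[ii];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C, int k, double* dx) {
  const int p = (k - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)HW * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - p;
          if (jj < 0 || jj >= W) continue;
          const double* src = col.colptr(H * j) + r;
          double* dst = xc + H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - p;
            if (ii < 0 || ii >= H) continue;
            dst[ii] += src[(size_t)(col.n_rows) * i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  const int HW = H * W, kkC = k * k * C;
  NumericVector out((size_t)HW * Cout * N);
  arma::mat Wm(w.begin(), kkC, Cout, false, true);
  arma::mat col(kkC, HW);
  arma::vec bias(b.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, k, col);
    arma::mat O = Wm.t() * col;            // Cout x HW
    O.each_col() += bias;
    double* op = out.begin() + (size_t)HW * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < HW; ++p)
        op[p + (size_t)HW * co] = O(co, p);
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dout,
                     IntegerVector xdim, IntegerVector wdim, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  const int HW = H * W, kkC = k * k * C;
  arma::mat Wm(w.begin(), kkC, Cout, false, true);
  arma::mat dW(kkC, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 0);
  arma::mat col(kkC, HW);
  arma::mat dO(Cout, HW);
  for (int n = 0; n < N; ++n) {
    const double* dp = dout.begin() + (size_t)HW * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < HW; ++p)
        dO(co, p) = dp[p + (size_t)HW * co];
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, k, col);
    dW += col * dO.t();
    db += arma::sum(dO, 1);
    if (need_dx) {
      arma::mat dcol = Wm * dO;            // kkC x HW
      col2im_add(dcol, H, W, C, k, dx.begin() + (size_t)HW * C * n);
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wdim;
  NumericVector dbr(db.begin(), db.end());
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dW"] = dWr, _["db"] = dbr, _["dx"] = dx);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx(out.size()); // linear index into x of the argmax
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t a = base + 2 * i + (size_t)H * 2 * j;
          size_t best = a;
          double bv = xp[a];
          if (xp[a + 1] > bv) { bv = xp[a + 1]; best = a + 1; }
          if (xp[a + H] > bv) { bv = xp[a + H]; best = a + H; }
          if (xp[a + H + 1] > bv) { bv = xp[a + H + 1]; best = a + H + 1; }
          size_t o = (size_t)i + (size_t)Ho * j + (size_t)Ho * Wo * (c + (size_t)C * n);
          op[o] = bv;
          ip[o] = (int)best;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dout, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const double* dp = dout.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  const size_t n = dout.size();
  for (size_t q = 0; q < n; ++q) xp[ip[q]] += dp[q];
  dx.attr("dim") = xdim;
  return dx;
}
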