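// Compact CPU convolution kernels (im2col/col2im + BLAS gemm) used by the
// network engine. Array layout is R column-major throughout:
//   image batches  (H, W, C, N)
//   conv weights   (k, k, C_in, C_out)
//   transposed-conv weights (k, k, C_out, C_in)
// im2col row index r = kh + k*kw + k*k*c; column index l = oh + out_h*ow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gather patches of one (H, W, C) sample into a (C*k*k) x (out_h*out_w) matrix.
static void im2col_one(const double* x, int H, int W, int C, int k, int stride,
                       int pad, int out_h, int out_w, arma::mat& cols) {
  const int L = out_h * out_w;
  cols.zeros(C * k * k, L);
  for (int ow = 0; ow < out_w; ++ow) {
    for (int oh = 0; oh < out_h; ++oh) {
      const int l = oh + out_h * ow;
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            cols(kh + k * kw + k * k * c, l) = x[ih + H * iw + H * W * c];
          }
        }
      }
    }
  }
}

// Adjoint of im2col_one: scatter-add columns back into an (H, W, C) sample.
static void col2im_one(const arma::mat& cols, int H, int W, int C, int k,
                       int stride, int pad, int out_h, int out_w, double* x) {
  for (int ow = 0; ow < out_w; ++ow) {
    for (int oh = 0; oh < out_h; ++oh) {
      const int l = oh + out_h * ow;
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            x[ih + H * iw + H * W * c] += cols(kh + k * kw + k * k * c, l);
          }
        }
      }
    }
  }
}

static IntegerVector dims_of(const NumericVector& a) {
  if (!a.hasAttribute("dim")) stop("expected an array");
  return a.attr("dim");
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector X, NumericVector Wt, NumericVector b,
                             int stride, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  const int out_h = (H + 2 * pad - k) / stride + 1;
  const int out_w = (W + 2 * pad - k) / stride + 1;
  if (out_h < 1 || out_w < 1) stop("conv output collapsed below 1x1");
  const int L = out_h * out_w;

  NumericVector Y(L * Cout * N);
  Y.attr("dim") = IntegerVector::create(out_h, out_w, Cout, N);
  arma::mat Wm(const_cast<double*>(Wt.begin()), k * k * Cin, Cout, false, true);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col_one(X.begin() + (R_xlen_t)n * H * W * C, H, W, C, k, stride, pad,
               out_h, out_w, cols);
    arma::mat Yl(Y.begin() + (R_xlen_t)n * L * Cout, L, Cout, false, true);
    Yl = cols.t() * Wm;            // (L x Cout)
    for (int co = 0; co < Cout; ++co) Yl.col(co) += b[co];
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector X, NumericVector Wt, NumericVector dY,
                    int stride, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt), dy = dims_of(dY);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int out_h = dy[0], out_w = dy[1];
  const int L = out_h * out_w;

  NumericVector dX(X.size()); dX.attr("dim") = dx;
  NumericVector dWt(Wt.size()); dWt.attr("dim") = dw;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(Wt.begin()), k * k * C, Cout, false, true);
  arma::mat dWm(dWt.begin(), k * k * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    arma::mat dYl(const_cast<double*>(dY.begin()) + (R_xlen_t)n * L * Cout,
                  L, Cout, false, true);
    im2col_one(X.begin() + (R_xlen_t)n * H * W * C, H, W, C, k, stride, pad,
               out_h, out_w, cols);
    dWm += cols * dYl;                         // (Ckk x Cout)
    dbv += arma::sum(dYl, 0).t();
    arma::mat dcols = Wm * dYl.t();            // (Ckk x L)
    col2im_one(dcols, H, W, C, k, stride, pad, out_h, out_w,
               dX.begin() + (R_xlen_t)n * H * W * C);
  }
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}

// Transposed (fractionally strided) convolution: forward pass is the adjoint
// of a stride-`stride` convolution taking the (out_h, out_w) plane down to the
// input plane. Weight layout (k, k, C_out, C_in).
// [[Rcpp::export]]
NumericVector cpp_convtr2d_fwd(NumericVector X, NumericVector Wt,
                               NumericVector b, int stride, int pad,
                               int out_h, int out_w) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt);
  const int h = dx[0], w = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[2];
  if (dw[3] != Cin) stop("channel mismatch in convtr2d");
  const int chk_h = (out_h + 2 * pad - k) / stride + 1;
  const int chk_w = (out_w + 2 * pad - k) / stride + 1;
  if (chk_h != h || chk_w != w) stop("unreachable output size for convtr2d");
  const int L = h * w;

  NumericVector Y((R_xlen_t)out_h * out_w * Cout * N);
  Y.attr("dim") = IntegerVector::create(out_h, out_w, Cout, N);
  arma::mat Wm(const_cast<double*>(Wt.begin()), k * k * Cout, Cin, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(X.begin()) + (R_xlen_t)n * L * Cin,
                 L, Cin, false, true);             // (L x Cin)
    arma::mat cols = Wm * Xm.t();                  // (Cout*k*k x L)
    double* yn = Y.begin() + (R_xlen_t)n * out_h * out_w * Cout;
    col2im_one(cols, out_h, out_w, Cout, k, stride, pad, h, w, yn);
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (R_xlen_t)co * out_h * out_w;
      for (int i = 0; i < out_h * out_w; ++i) yc[i] += b[co];
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_convtr2d_bwd(NumericVector X, NumericVector Wt, NumericVector dY,
                      int stride, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt), dy = dims_of(dY);
  const int h = dx[0], w = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[2];
  const int out_h = dy[0], out_w = dy[1];
  const int L = h * w;

  NumericVector dX(X.size()); dX.attr("dim") = dx;
  NumericVector dWt(Wt.size()); dWt.attr("dim") = dw;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(Wt.begin()), k * k * Cout, Cin, false, true);
  arma::mat dWm(dWt.begin(), k * k * Cout, Cin, false, true);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const double* dyn = dY.begin() + (R_xlen_t)n * out_h * out_w * Cout;
    im2col_one(dyn, out_h, out_w, Cout, k, stride, pad, h, w, cols);
    arma::mat Xm(const_cast<double*>(X.begin()) + (R_xlen_t)n * L * Cin,
                 L, Cin, false, true);
    dWm += cols * Xm;                              // (Cout*k*k x Cin)
    arma::mat dXm(dX.begin() + (R_xlen_t)n * L * Cin, L, Cin, false, true);
    dXm = cols.t() * Wm;                           // (L x Cin)
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (R_xlen_t)co * out_h * out_w;
      double s = 0.0;
      for (int i = 0; i < out_h * out_w; ++i) s += dyc[i];
      db[co] += s;
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}

// 2x2 max pooling, stride 2 (trailing odd row/column dropped).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector X) {
  IntegerVector dx = dims_of(X);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int oh = H / 2, ow = W / 2;
  if (oh < 1 || ow < 1) stop("pooling collapsed below 1x1");
  NumericVector Y((R_xlen_t)oh * ow * C * N);
  IntegerVector idx((R_xlen_t)oh * ow * C * N);  // 0-based (h + H*w) in sample plane
  Y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  idx.attr("dim") = IntegerVector::create(oh, ow, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = X.begin() + (R_xlen_t)(n * C + c) * H * W;
      for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i) {
          int best = 2 * i + H * (2 * j);
          double bv = xp[best];
          const int cand[3] = {2 * i + 1 + H * (2 * j), 2 * i + H * (2 * j + 1),
                               2 * i + 1 + H * (2 * j + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          Y[o] = bv; idx[o] = best; ++o;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dY, IntegerVector idx, int H, int W) {
  IntegerVector dy = dims_of(dY);
  const int oh = dy[0], ow = dy[1], C = dy[2], N = dy[3];
  NumericVector dX((R_xlen_t)H * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xp = dX.begin() + (R_xlen_t)(n * C + c) * H * W;
      for (R_xlen_t t = 0; t < (R_xlen_t)oh * ow; ++t, ++o) xp[idx[o]] += dY[o];
    }
  }
  return dX;
}
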