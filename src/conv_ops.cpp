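// Minimal convolution / pooling kernels for the two-stream network.
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N).
// Convolution weights: dim = (kh, kw, C_in, C_out); no bias term for conv
// layers that are followed by batch normalisation (bias passed as zeros).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix (K x Ho*Wo) for one image (H x W x C slab).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = di + kh * (dj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + dj;
          const bool jin = (j >= 0 && j < W);
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + di;
            double v = 0.0;
            if (jin && i >= 0 && i < H) v = x[i + H * j + HW * c];
            col(row, oi + Ho * oj) = v;
          }
        }
      }
    }
  }
}

// Scatter-add a col matrix back into an image gradient (col2im).
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = di + kh * (dj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + di;
            if (i < 0 || i >= H) continue;
            dx[i + H * j + HW * c] += col(row, oi + Ho * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cw = wd[2], F = wd[3];
  if (Cw != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cw);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = kh * kw * C;

  // Weight matrix (F x K), rows of col in (di, dj, c) order.
  arma::mat Wm(F, K);
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < K; ++k)
      Wm(f, k) = w[k + K * f];

  NumericVector out(Ho * Wo * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat col(K, Ho * Wo);
  const int xstep = H * W * C, ostep = Ho * Wo * F;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat res = Wm * col;  // F x (Ho*Wo)
    double* o = out.begin() + n * ostep;
    for (int p = 0; p < Ho * Wo; ++p)
      for (int f = 0; f < F; ++f)
        o[p + Ho * Wo * f] = res(f, p) + bias[f];
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w,
                         NumericVector grad_out, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = grad_out.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * C;

  arma::mat Wm(F, K);
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < K; ++k)
      Wm(f, k) = w[k + K * f];

  NumericVector dx(x.size()), dw(w.size()), db(F);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dW(F, K, arma::fill::zeros);
  arma::mat col(K, Ho * Wo), g(F, Ho * Wo);
  const int xstep = H * W * C, ostep = Ho * Wo * F;

  for (int n = 0; n < N; ++n) {
    const double* go = grad_out.begin() + n * ostep;
    for (int p = 0; p < Ho * Wo; ++p)
      for (int f = 0; f < F; ++f)
        g(f, p) = go[p + Ho * Wo * f];
    im2col(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    dW += g * col.t();
    arma::mat dcol = Wm.t() * g;  // K x (Ho*Wo)
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo, dx.begin() + n * xstep);
    for (int f = 0; f < F; ++f) db[f] += arma::accu(g.row(f));
  }
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < K; ++k)
      dw[k + K * f] = dW(f, k);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector out(Ho * Wo * C * N);
  IntegerVector idx(Ho * Wo * C * N);  // 1-based linear index into x
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + HW * (c + C * n);
      const long base = (long)HW * (c + C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = R_NegInf;
          int besti = -1;
          for (int dj = 0; dj < k; ++dj) {
            const int j = oj * stride - pad + dj;
            if (j < 0 || j >= W) continue;
            for (int di = 0; di < k; ++di) {
              const int i = oi * stride - pad + di;
              if (i < 0 || i >= H) continue;
              const double v = xs[i + H * j];
              if (v > best) { best = v; besti = i + H * j; }
            }
          }
          const long o = oi + (long)Ho * oj + (long)Ho * Wo * (c + C * n);
          out[o] = best;
          idx[o] = (int)(base + besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector grad_out, IntegerVector idx,
                                   IntegerVector xdim) {
  long total = 1;
  for (int d = 0; d < xdim.size(); ++d) total *= xdim[d];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < grad_out.size(); ++p)
    dx[idx[p] - 1] += grad_out[p];
  return dx;
}
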