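#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Grouped 2-D convolution via im2col + BLAS.
//
// Activation layout: R array (H, W, C, N), column-major, so each channel
// plane (H*W doubles) is contiguous. Weight layout: R array (kh, kw, Cg, Co)
// with Cg = C_in / groups; flattening the first three dims gives the im2col
// row order (ki fastest, then kj, then in-channel).

static void im2col(const double* img, int H, int W, int c0, int Cg,
                   int kh, int kw, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  // col is (kh*kw*Cg) x (Ho*Wo); column p = ho + Ho*wo
  col.zeros();
  for (int c = 0; c < Cg; ++c) {
    const double* plane = img + (size_t)(c0 + c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* src = plane + (size_t)wi * H;
          double* dst = col.memptr() + (size_t)r + (size_t)col.n_rows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            dst[(size_t)ho * col.n_rows] = src[hi];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* img, int H, int W,
                       int c0, int Cg, int kh, int kw, int stride, int pad,
                       int Ho, int Wo) {
  for (int c = 0; c < Cg; ++c) {
    double* plane = img + (size_t)(c0 + c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* dst = plane + (size_t)wi * H;
          const double* src = col.memptr() + (size_t)r + (size_t)col.n_rows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            dst[hi] += src[(size_t)ho * col.n_rows];
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dim4(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int stride, int pad, int groups) {
  IntegerVector xd = dim4(x, "input"), wd = dim4(w, "weight");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Co = wd[3];
  if (C != Cg * groups) stop("input channels (%d) != weight channels x groups (%d x %d)", C, Cg, groups);
  if (Co % groups != 0) stop("output channels not divisible by groups");
  const int Cog = Co / groups;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("non-positive output size");
  const int K = kh * kw * Cg, P = Ho * Wo;

  NumericVector y = alloc4(Ho, Wo, Co, N);
  arma::mat col(K, P);
  arma::rowvec brow;
  const bool has_b = bias.isNotNull();
  if (has_b) {
    NumericVector b(bias);
    brow = arma::rowvec(b.begin(), Co);
  }
  for (int n = 0; n < N; ++n) {
    const double* img = x.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(img, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * K * Cog, K, Cog, false, true);
      arma::mat Y(y.begin() + ((size_t)n * Co + (size_t)g * Cog) * P, P, Cog, false, true);
      Y = col.t() * Wm;
      if (has_b) Y.each_row() += brow.subvec(g * Cog, (g + 1) * Cog - 1);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int groups, bool need_dx) {
  IntegerVector xd = dim4(x, "input"), wd = dim4(w, "weight"), yd = dim4(dy, "grad");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Co = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Co || yd[3] != N) stop("grad shape mismatch");
  const int Cog = Co / groups;
  const int K = kh * kw * Cg, P = Ho * Wo;

  NumericVector dw = alloc4(kh, kw, Cg, Co);
  NumericVector db(Co);
  NumericVector dx;
  if (need_dx) dx = alloc4(H, W, C, N);
  arma::mat col(K, P), dcol(K, P);

  for (int n = 0; n < N; ++n) {
    const double* img = x.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(img, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      arma::mat dY(const_cast<double*>(dy.begin()) + ((size_t)n * Co + (size_t)g * Cog) * P,
                   P, Cog, false, true);
      arma::mat dWg(dw.begin() + (size_t)g * K * Cog, K, Cog, false, true);
      dWg += col * dY;
      arma::rowvec s = arma::sum(dY, 0);
      for (int c = 0; c < Cog; ++c) db[g * Cog + c] += s[c];
      if (need_dx) {
        arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * K * Cog, K, Cog, false, true);
        dcol = Wm * dY.t();
        col2im_add(dcol, dx.begin() + (size_t)n * H * W * C, H, W, g * Cg, Cg,
                   kh, kw, stride, pad, Ho, Wo);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
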