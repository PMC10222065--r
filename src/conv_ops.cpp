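// Hot inner loops of the convolutional branches: im2col/col2im for 'same'
// zero-padded k x k convolution, non-overlapping max pooling, and global
// average+max pooling. Tensors are R arrays (B, H, W, C), column-major.
// The GEMMs themselves stay in R (BLAS).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int B, int H, int W, int C, int k) {
  int p = (k - 1) / 2;
  NumericMatrix out(B * H * W, k * k * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int o = dw * k + dh;
        int col = o * C + c;
        double* op = &out(0, col);
        for (int w = 0; w < W; ++w) {
          int ws = w + dw - p;
          for (int h = 0; h < H; ++h) {
            int hs = h + dh - p;
            int r = h * B + w * B * H;
            if (hs < 0 || hs >= H || ws < 0 || ws >= W) continue;
            const double* src = xp + hs * B + ws * B * H + (size_t)c * B * H * W;
            double* dst = op + r;
            for (int b = 0; b < B; ++b) dst[b] = src[b];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dxc, int B, int H, int W, int C, int k) {
  int p = (k - 1) / 2;
  NumericVector dx((size_t)B * H * W * C);
  dx.attr("dim") = IntegerVector::create(B, H, W, C);
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int o = dw * k + dh;
        int col = o * C + c;
        const double* sp = &dxc(0, col);
        for (int w = 0; w < W; ++w) {
          int ws = w + dw - p;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hs = h + dh - p;
            if (hs < 0 || hs >= H) continue;
            const double* src = sp + h * B + w * B * H;
            double* dst = dp + hs * B + ws * B * H + (size_t)c * B * H * W;
            for (int b = 0; b < B; ++b) dst[b] += src[b];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int B, int H, int W, int C,
                     int ph, int pw) {
  int Ho = H / ph, Wo = W / pw;
  NumericVector out((size_t)B * Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(B, Ho, Wo, C);
  IntegerVector flat(B * Ho * Wo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* fp = flat.begin();
  for (int c = 0; c < C; ++c) {
    size_t coff = (size_t)c * B * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          size_t bestIdx = 0;
          for (int j = 0; j < pw; ++j) {
            int w = wo * pw + j;
            for (int i = 0; i < ph; ++i) {
              int h = ho * ph + i;
              size_t idx = coff + b + (size_t)h * B + (size_t)w * B * H;
              if (xp[idx] > best) { best = xp[idx]; bestIdx = idx; }
            }
          }
          size_t oidx = b + (size_t)ho * B + (size_t)wo * B * Ho +
            (size_t)c * B * Ho * Wo;
          op[oidx] = best;
          fp[oidx] = (int)(bestIdx + 1);  // 1-based for R
        }
      }
    }
  }
  return List::create(_["out"] = out, _["flat"] = flat);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector flat,
                              int B, int H, int W, int C) {
  NumericVector dx((size_t)B * H * W * C);
  dx.attr("dim") = IntegerVector::create(B, H, W, C);
  double* dp = dx.begin();
  const double* yp = dy.begin();
  const int* fp = flat.begin();
  int n = dy.size();
  for (int i = 0; i < n; ++i) dp[fp[i] - 1] += yp[i];
  return dx;
}

// [[Rcpp::export]]
List cpp_gapgmp_fwd(NumericVector x, int B, int HW, int C) {
  NumericMatrix out(B, C);
  IntegerMatrix arg(B, C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      double s = 0.0, best = R_NegInf;
      int bestJ = 0;
      const double* base = xp + b + (size_t)c * B * HW;
      for (int j = 0; j < HW; ++j) {
        double v = base[(size_t)j * B];
        s += v;
        if (v > best) { best = v; bestJ = j; }
      }
      out(b, c) = s / HW + best;
      arg(b, c) = bestJ + 1;
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_gapgmp_bwd(NumericMatrix dy, IntegerMatrix arg,
                             int B, int HW, int C) {
  NumericVector dx((size_t)B * HW * C);
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      double d = dy(b, c);
      double* base = dp + b + (size_t)c * B * HW;
      double dAvg = d / HW;
      for (int j = 0; j < HW; ++j) base[(size_t)j * B] += dAvg;
      base[(size_t)(arg(b, c) - 1) * B] += d;
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix cpp_add_cols(NumericMatrix x, NumericVector a) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* s = &x(0, j);
    double* d = &out(0, j);
    double aj = a[j];
    for (int i = 0; i < nr; ++i) d[i] = s[i] + aj;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mul_cols(NumericMatrix x, NumericVector a) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* s = &x(0, j);
    double* d = &out(0, j);
    double aj = a[j];
    for (int i = 0; i < nr; ++i) d[i] = s[i] * aj;
  }
  return out;
}
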