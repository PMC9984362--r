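// Minimal CNN inference primitives: 2D convolution (im2col + GEMM),
// depthwise convolution, and max/average pooling on H x W x C arrays
// (column-major, channel-last). Used by the deep-feature engine to run
// reference CNN topologies at their native input sizes.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p0, int p1) {
  return (n + p0 + p1 - k) / s + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericMatrix w,
                         int kh, int kw, int sh, int sw,
                         int pt, int pb, int pl, int pr, bool relu) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int OH = out_size(H, kh, sh, pt, pb);
  const int OW = out_size(W, kw, sw, pl, pr);
  const int K = kh * kw * C;
  const int Cout = w.ncol();
  if (w.nrow() != K) stop("weight rows do not match kernel size");

  arma::mat cols(OH * (std::size_t)OW, K, arma::fill::zeros);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = xp + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const std::size_t colidx = (std::size_t)c * kh * kw + (std::size_t)j * kh + i;
        double* dst = cols.colptr(colidx);
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * sw - pl + j;
          if (iw < 0 || iw >= W) continue;
          const double* src = plane + (std::size_t)iw * H;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * sh - pt + i;
            if (ih < 0 || ih >= H) continue;
            dst[(std::size_t)ow * OH + oh] = src[ih];
          }
        }
      }
    }
  }
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat out = cols * wm;            // (OH*OW) x Cout
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(OH, OW, Cout);
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d(NumericVector x, NumericMatrix w,
                           int kh, int kw, int sh, int sw,
                           int pt, int pb, int pl, int pr, bool relu) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  if (w.nrow() != kh * kw || w.ncol() != C) stop("depthwise weight shape mismatch");
  const int OH = out_size(H, kh, sh, pt, pb);
  const int OW = out_size(W, kw, sw, pl, pr);
  NumericVector res((std::size_t)OH * OW * C);
  const double* xp = x.begin();
  double* rp = res.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = xp + (std::size_t)H * W * c;
    const double* wc = &w(0, c);
    double* outp = rp + (std::size_t)OH * OW * c;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double acc = 0.0;
        for (int j = 0; j < kw; ++j) {
          const int iw = ow * sw - pl + j;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int ih = oh * sh - pt + i;
            if (ih < 0 || ih >= H) continue;
            acc += plane[(std::size_t)iw * H + ih] * wc[j * kh + i];
          }
        }
        if (relu && acc < 0.0) acc = 0.0;
        outp[(std::size_t)ow * OH + oh] = acc;
      }
    }
  }
  res.attr("dim") = IntegerVector::create(OH, OW, C);
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_pool2d(NumericVector x, int kh, int kw, int sh, int sw,
                         int pt, int pb, int pl, int pr, bool take_max) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int OH = out_size(H, kh, sh, pt, pb);
  const int OW = out_size(W, kw, sw, pl, pr);
  NumericVector res((std::size_t)OH * OW * C);
  const double* xp = x.begin();
  double* rp = res.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = xp + (std::size_t)H * W * c;
    double* outp = rp + (std::size_t)OH * OW * c;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double best = -std::numeric_limits<double>::infinity();
        double acc = 0.0;
        int cnt = 0;
        for (int j = 0; j < kw; ++j) {
          const int iw = ow * sw - pl + j;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int ih = oh * sh - pt + i;
            if (ih < 0 || ih >= H) continue;
            const double v = plane[(std::size_t)iw * H + ih];
            if (v > best) best = v;
            acc += v; ++cnt;
          }
        }
        outp[(std::size_t)ow * OH + oh] =
          take_max ? (cnt ? best : 0.0) : (cnt ? acc / cnt : 0.0);
      }
    }
  }
  res.attr("dim") = IntegerVector::create(OH, OW, C);
  return res;
}
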