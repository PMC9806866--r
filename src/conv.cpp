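#include <Rcpp.h>
using namespace Rcpp;

// 2-D convolution kernels for H x W x C x N arrays (column-major, R
// layout).  Weights are kh x kw x Cin x Cout.  Zero padding `pad` on
// both spatial sides, common stride.  These are the only compiled
// primitives; everything else (gates, pooling, softmax, Adam) is
// cheap enough in R.

static inline int outSize(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d_fw: input has %d channels, weights expect %d", C, Ci);
  const int Ho = outSize(H, kh, stride, pad), Wo = outSize(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d_fw: output would be empty");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const double *X = x.begin(), *Wt = w.begin(), *B = b.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; ++n) {
    const double *Xn = X + static_cast<R_xlen_t>(n) * H * W * C;
    double *Yn = Y + static_cast<R_xlen_t>(n) * Ho * Wo * Co;
    for (int co = 0; co < Co; ++co) {
      double *Yc = Yn + static_cast<R_xlen_t>(co) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = B[co];
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < C; ++ci) {
            const double *Xc = Xn + static_cast<R_xlen_t>(ci) * H * W;
            const double *Wc = Wt + (static_cast<R_xlen_t>(co) * Ci + ci) * kh * kw;
            for (int kx = 0; kx < kw; ++kx) {
              const int wi = w0 + kx;
              if (wi < 0 || wi >= W) continue;
              const double *Xcol = Xc + static_cast<R_xlen_t>(wi) * H;
              const double *Wcol = Wc + static_cast<R_xlen_t>(kx) * kh;
              for (int ky = 0; ky < kh; ++ky) {
                const int hi = h0 + ky;
                if (hi < 0 || hi >= H) continue;
                acc += Xcol[hi] * Wcol[ky];
              }
            }
          }
          Yc[wo * Ho + ho] = acc;
        }
      }
    }
  }
  return y;
}

// Gradients of the convolution w.r.t. input, weights and bias.
// [[Rcpp::export(rng = false)]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  if (Ci != C || gd[2] != Co || gd[3] != N) stop("conv2d_bw: shape mismatch");
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *X = x.begin(), *Wt = w.begin(), *GY = gy.begin();
  double *GX = gx.begin(), *GW = gw.begin(), *GB = gb.begin();
  for (int n = 0; n < N; ++n) {
    const double *Xn = X + static_cast<R_xlen_t>(n) * H * W * C;
    double *GXn = GX + static_cast<R_xlen_t>(n) * H * W * C;
    const double *GYn = GY + static_cast<R_xlen_t>(n) * Ho * Wo * Co;
    for (int co = 0; co < Co; ++co) {
      const double *Gc = GYn + static_cast<R_xlen_t>(co) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = Gc[wo * Ho + ho];
          if (g == 0.0) { continue; }
          GB[co] += g;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < C; ++ci) {
            const double *Xc = Xn + static_cast<R_xlen_t>(ci) * H * W;
            double *GXc = GXn + static_cast<R_xlen_t>(ci) * H * W;
            const double *Wc = Wt + (static_cast<R_xlen_t>(co) * Ci + ci) * kh * kw;
            double *GWc = GW + (static_cast<R_xlen_t>(co) * Ci + ci) * kh * kw;
            for (int kx = 0; kx < kw; ++kx) {
              const int wi = w0 + kx;
              if (wi < 0 || wi >= W) continue;
              for (int ky = 0; ky < kh; ++ky) {
                const int hi = h0 + ky;
                if (hi < 0 || hi >= H) continue;
                GWc[kx * kh + ky] += Xc[wi * H + hi] * g;
                GXc[wi * H + hi] += Wc[kx * kh + ky] * g;
              }
            }
          }
        }
      }
    }
  }
  // gb accumulated inside the g != 0 branch above skips zero grads,
  // which is exact (adding zero), so nothing to fix up here.
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
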