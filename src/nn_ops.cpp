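#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 2-D convolution kernels over H x W x C arrays (R column-major layout:
// index h + H*(w + W*c)).  Zero "same" padding of (k-1)/2; odd k only.
// Weights are k x k x Cin x Cout arrays.  Deterministic double-precision
// loops: the codec's losslessness rests on encoder and decoder computing
// bit-identical activations.

static inline int out_dim(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// valid output range [lo, hi] for one kernel tap: stride*o - pad + kk in [0, n)
static inline void tap_range(int n, int nout, int pad, int stride, int kk,
                             int &lo, int &hi) {
  int a = pad - kk;                        // need stride*o >= a
  lo = a <= 0 ? 0 : (a + stride - 1) / stride;
  int bmax = n - 1 + pad - kk;             // need stride*o <= bmax
  hi = bmax < 0 ? -1 : bmax / stride;
  if (hi > nout - 1) hi = nout - 1;
}

// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, int stride) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2];
  const int k = wdim[0], Co = wdim[3];
  if (wdim[1] != k || wdim[2] != Ci) stop("weight/input channel mismatch");
  const int pad = (k - 1) / 2;
  const int Ho = out_dim(H, k, pad, stride), Wo = out_dim(W, k, pad, stride);
  NumericVector y(Ho * (R_xlen_t)Wo * Co);
  const double *px = REAL(x), *pw = REAL(w), *pb = REAL(b);
  double *py = REAL(y);
  for (int co = 0; co < Co; co++) {
    double *yc = py + (R_xlen_t)Ho * Wo * co;
    const double bias = pb[co];
    for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; i++) yc[i] = bias;
    for (int ci = 0; ci < Ci; ci++) {
      const double *xc = px + (R_xlen_t)H * W * ci;
      const double *wc = pw + (R_xlen_t)k * k * (ci + (R_xlen_t)Ci * co);
      for (int kj = 0; kj < k; kj++) {
        int wlo, whi;
        tap_range(W, Wo, pad, stride, kj, wlo, whi);
        for (int ki = 0; ki < k; ki++) {
          const double wv = wc[ki + k * kj];
          if (wv == 0.0) continue;
          int hlo, hhi;
          tap_range(H, Ho, pad, stride, ki, hlo, hhi);
          const int nh = hhi - hlo + 1;
          if (nh <= 0) continue;
          for (int wo = wlo; wo <= whi; wo++) {
            const int wi = wo * stride - pad + kj;
            const double *xcol = xc + (R_xlen_t)H * wi + (hlo * stride - pad + ki);
            double *ycol = yc + (R_xlen_t)Ho * wo + hlo;
            if (stride == 1) {
              for (int t = 0; t < nh; t++) ycol[t] += wv * xcol[t];
            } else {
              for (int t = 0; t < nh; t++) ycol[t] += wv * xcol[(R_xlen_t)t * stride];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  return y;
}

// channelwise softmax over an H x W x C array
// [[Rcpp::export(name = ".softmax_ch_cpp")]]
NumericVector softmax_ch_cpp(NumericVector z, IntegerVector zdim) {
  const int HW = zdim[0] * zdim[1], C = zdim[2];
  NumericVector y(z.size());
  const double *pz = REAL(z);
  double *py = REAL(y);
  for (int i = 0; i < HW; i++) {
    double mx = pz[i];
    for (int c = 1; c < C; c++) {
      double v = pz[i + (R_xlen_t)HW * c];
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int c = 0; c < C; c++) {
      double e = std::exp(pz[i + (R_xlen_t)HW * c] - mx);
      py[i + (R_xlen_t)HW * c] = e;
      s += e;
    }
    for (int c = 0; c < C; c++) py[i + (R_xlen_t)HW * c] /= s;
  }
  y.attr("dim") = zdim;
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector dy, int stride) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2];
  const int k = wdim[0], Co = wdim[3];
  const int pad = (k - 1) / 2;
  const int Ho = out_dim(H, k, pad, stride), Wo = out_dim(W, k, pad, stride);
  NumericVector dx(x.size()), dw(w.size()), db(Co);
  const double *px = REAL(x), *pw = REAL(w), *pdy = REAL(dy);
  double *pdx = REAL(dx), *pdw = REAL(dw), *pdb = REAL(db);
  for (int co = 0; co < Co; co++) {
    for (int wo = 0; wo < Wo; wo++) {
      for (int ho = 0; ho < Ho; ho++) {
        const double g = pdy[ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * co)];
        if (g == 0.0) continue;
        pdb[co] += g;
        const int hi0 = ho * stride - pad, wi0 = wo * stride - pad;
        for (int ci = 0; ci < Ci; ci++) {
          const double *xc = px + (R_xlen_t)H * W * ci;
          double *dxc = pdx + (R_xlen_t)H * W * ci;
          const double *wc = pw + (R_xlen_t)k * k * (ci + (R_xlen_t)Ci * co);
          double *dwc = pdw + (R_xlen_t)k * k * (ci + (R_xlen_t)Ci * co);
          for (int kj = 0; kj < k; kj++) {
            const int wi = wi0 + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ki++) {
              const int hi = hi0 + ki;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t xi = hi + (R_xlen_t)H * wi;
              dwc[ki + k * kj] += g * xc[xi];
              dxc[xi] += g * wc[ki + k * kj];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
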