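#include <Rcpp.h>
using namespace Rcpp;

// 3x3xKD patch extraction (KD = 1 or 3) with zero padding 1 in-plane and
// (KD-1)/2 in depth, for a H x W x S x C array (column-major, h fastest).
// Row r of the output indexes the voxel position r = h + H*w + H*W*s;
// column indexes (dh, dw, ds, c) with dh fastest. The matrix form lets the
// convolution itself run as one BLAS matmul in R.

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int H, int W, int S, int C,
                      int KD = 3) {
  const R_xlen_t npos = (R_xlen_t)H * W * S;
  const int rad = (KD - 1) / 2;
  NumericMatrix out(npos, 9 * KD * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * H * W * S;
    for (int ds = -rad; ds <= rad; ++ds)
      for (int dw = -1; dw <= 1; ++dw)
        for (int dh = -1; dh <= 1; ++dh) {
          int col = c * 9 * KD + (ds + rad) * 9 + (dw + 1) * 3 + (dh + 1);
          double *oc = po + (R_xlen_t)col * npos;
          for (int s = 0; s < S; ++s) {
            int ss = s + ds;
            if (ss < 0 || ss >= S) continue;
            for (int w = 0; w < W; ++w) {
              int ww = w + dw;
              if (ww < 0 || ww >= W) continue;
              const double *src = xc + ((R_xlen_t)ss * W + ww) * H;
              double *dst = oc + ((R_xlen_t)s * W + w) * H;
              int h0 = (dh < 0) ? 1 : 0;
              int h1 = (dh > 0) ? H - 1 : H;
              for (int h = h0; h < h1; ++h) dst[h] = src[h + dh];
            }
          }
        }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch-space gradients back onto the
// padded input volume. g has dim (H*W*S) x (9*KD*C); returns H x W x S x C.

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix g, int H, int W, int S, int C,
                      int KD = 3) {
  const R_xlen_t npos = (R_xlen_t)H * W * S;
  const int rad = (KD - 1) / 2;
  NumericVector out((R_xlen_t)H * W * S * C);
  double *po = out.begin();
  const double *pg = g.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = po + (R_xlen_t)c * H * W * S;
    for (int ds = -rad; ds <= rad; ++ds)
      for (int dw = -1; dw <= 1; ++dw)
        for (int dh = -1; dh <= 1; ++dh) {
          int col = c * 9 * KD + (ds + rad) * 9 + (dw + 1) * 3 + (dh + 1);
          const double *gc = pg + (R_xlen_t)col * npos;
          for (int s = 0; s < S; ++s) {
            int ss = s + ds;
            if (ss < 0 || ss >= S) continue;
            for (int w = 0; w < W; ++w) {
              int ww = w + dw;
              if (ww < 0 || ww >= W) continue;
              double *dst = xc + ((R_xlen_t)ss * W + ww) * H;
              const double *src = gc + ((R_xlen_t)s * W + w) * H;
              int h0 = (dh < 0) ? 1 : 0;
              int h1 = (dh > 0) ? H - 1 : H;
              for (int h = h0; h < h1; ++h) dst[h + dh] += src[h];
            }
          }
        }
  }
  out.attr("dim") = IntegerVector::create(H, W, S, C);
  return out;
}
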