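// Hot memory-movement kernels for the 1-D network: im2col/col2im with
// implicit zero padding, and non-overlapping max-pooling with argmax
// bookkeeping. Arithmetic-heavy products stay in R's BLAS.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// x: c_in x t_in x bsz (column-major). Returns (c_in*k) x (t_out*bsz)
// patch matrix, rows in tap-major blocks of c_in channels, columns over
// (position, sample) with position fastest. t_out = t_in + 2*pad - k + 1.
// [[Rcpp::export(name = ".im2col_pad")]]
NumericMatrix im2col_pad(NumericVector x, int c_in, int t_in, int bsz,
                         int k, int pad) {
  const int t_out = t_in + 2 * pad - k + 1;
  if (t_out < 1) stop("input too short for kernel");
  NumericMatrix P(c_in * k, t_out * bsz);
  const double* xp = x.begin();
  double* pp = P.begin();
  const int nrow = c_in * k;
  for (int b = 0; b < bsz; ++b) {
    const double* xb = xp + (R_xlen_t)b * c_in * t_in;
    for (int t = 0; t < t_out; ++t) {
      double* col = pp + (R_xlen_t)(b * t_out + t) * nrow;
      for (int i = 0; i < k; ++i) {
        const int tp = t + i - pad;
        if (tp >= 0 && tp < t_in) {
          std::memcpy(col + (R_xlen_t)i * c_in, xb + (R_xlen_t)tp * c_in,
                      c_in * sizeof(double));
        }
        // else: leave the zero-initialised padding block
      }
    }
  }
  return P;
}

// Adjoint of im2col_pad: scatter-add patch-matrix gradients back onto the
// (unpadded) input layout c_in x t_in x bsz.
// [[Rcpp::export(name = ".col2im_pad")]]
NumericVector col2im_pad(NumericMatrix dP, int c_in, int t_in, int bsz,
                         int k, int pad) {
  const int t_out = t_in + 2 * pad - k + 1;
  NumericVector dx((R_xlen_t)c_in * t_in * bsz);
  dx.attr("dim") = IntegerVector::create(c_in, t_in, bsz);
  const double* pp = dP.begin();
  double* dxp = dx.begin();
  const int nrow = c_in * k;
  for (int b = 0; b < bsz; ++b) {
    double* xb = dxp + (R_xlen_t)b * c_in * t_in;
    for (int t = 0; t < t_out; ++t) {
      const double* col = pp + (R_xlen_t)(b * t_out + t) * nrow;
      for (int i = 0; i < k; ++i) {
        const int tp = t + i - pad;
        if (tp < 0 || tp >= t_in) continue;
        double* dst = xb + (R_xlen_t)tp * c_in;
        const double* src = col + (R_xlen_t)i * c_in;
        for (int c = 0; c < c_in; ++c) dst[c] += src[c];
      }
    }
  }
  return dx;
}

// Non-overlapping max-pooling over the temporal axis with argmax slots
// (1-based) for the backward pass. Ties keep the earliest position.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int C, int t_in, int bsz, int size) {
  const int t_out = t_in / size;
  if (t_out < 1) stop("temporal length shorter than pool size");
  NumericVector out((R_xlen_t)C * t_out * bsz);
  IntegerVector idx((R_xlen_t)C * t_out * bsz);
  out.attr("dim") = IntegerVector::create(C, t_out, bsz);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int b = 0; b < bsz; ++b) {
    const double* xb = xp + (R_xlen_t)b * C * t_in;
    for (int t = 0; t < t_out; ++t) {
      for (int c = 0; c < C; ++c) {
        double best = xb[(R_xlen_t)(t * size) * C + c];
        int bs = 1;
        for (int s = 1; s < size; ++s) {
          const double v = xb[(R_xlen_t)(t * size + s) * C + c];
          if (v > best) { best = v; bs = s + 1; }
        }
        const R_xlen_t o = (R_xlen_t)b * C * t_out + (R_xlen_t)t * C + c;
        op[o] = best;
        ip[o] = bs;
      }
    }
  }
  return List::create(Named("out") = out, Named("idx") = idx);
}

// Route upstream gradients to the recorded argmax positions.
// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector idx, int C,
                          int t_in, int bsz, int size) {
  const int t_out = t_in / size;
  NumericVector dx((R_xlen_t)C * t_in * bsz);
  dx.attr("dim") = IntegerVector::create(C, t_in, bsz);
  const double* dp = dout.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  for (int b = 0; b < bsz; ++b) {
    double* xb = xp + (R_xlen_t)b * C * t_in;
    for (int t = 0; t < t_out; ++t) {
      for (int c = 0; c < C; ++c) {
        const R_xlen_t o = (R_xlen_t)b * C * t_out + (R_xlen_t)t * C + c;
        xb[(R_xlen_t)(t * size + ip[o] - 1) * C + c] = dp[o];
      }
    }
  }
  return dx;
}
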