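#include <Rcpp.h>
using namespace Rcpp;

// Valid-mode stereo convolution is implemented as im2col + GEMM (the GEMM is
// done in R through BLAS). Patch rows are ordered patch-major, then output
// position in column-major order; columns are left-eye kernel elements in
// column-major order followed by the right eye, matching the column-major
// layout of a (kh, kw, 2, K) kernel array flattened to a (kh*kw*2, K) matrix.

// [[Rcpp::export]]
NumericMatrix stereo_im2col(NumericVector L, NumericVector R,
                            int kh, int kw) {
  IntegerVector dim = L.attr("dim");
  if (dim.size() != 3) stop("inputs must be (h, w, n) arrays");
  const int h = dim[0], w = dim[1], n = dim[2];
  const int oh = h - kh + 1, ow = w - kw + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than input");
  const int P = oh * ow, KK = kh * kw;
  NumericMatrix X(n * P, 2 * KK);
  const double *lp = L.begin(), *rp = R.begin();
  double *xp = X.begin();
  const R_xlen_t nrow = (R_xlen_t)n * P;
  for (int kc = 0; kc < kw; ++kc) {
    for (int kr = 0; kr < kh; ++kr) {
      const R_xlen_t colL = (R_xlen_t)(kc * kh + kr) * nrow;
      const R_xlen_t colR = colL + (R_xlen_t)KK * nrow;
      for (int p = 0; p < n; ++p) {
        const R_xlen_t img = (R_xlen_t)p * h * w;
        for (int oc = 0; oc < ow; ++oc) {
          const R_xlen_t src = img + (R_xlen_t)(oc + kc) * h + kr;
          const R_xlen_t dst = (R_xlen_t)p * P + (R_xlen_t)oc * oh;
          for (int orr = 0; orr < oh; ++orr) {
            xp[colL + dst + orr] = lp[src + orr];
            xp[colR + dst + orr] = rp[src + orr];
          }
        }
      }
    }
  }
  return X;
}

// Adjoint of stereo_im2col: scatter-add a (n*P x kh*kw*2) gradient back onto
// the input images. Used for input-gradient computations (optimal stimuli).

// [[Rcpp::export]]
List stereo_col2im(NumericMatrix dX, int h, int w, int n, int kh, int kw) {
  const int oh = h - kh + 1, ow = w - kw + 1;
  const int P = oh * ow, KK = kh * kw;
  if (dX.nrow() != (R_xlen_t)n * P || dX.ncol() != 2 * KK)
    stop("gradient matrix has wrong shape");
  NumericVector dL((R_xlen_t)h * w * n), dR((R_xlen_t)h * w * n);
  dL.attr("dim") = IntegerVector::create(h, w, n);
  dR.attr("dim") = IntegerVector::create(h, w, n);
  const double *xp = dX.begin();
  double *lp = dL.begin(), *rp = dR.begin();
  const R_xlen_t nrow = (R_xlen_t)n * P;
  for (int kc = 0; kc < kw; ++kc) {
    for (int kr = 0; kr < kh; ++kr) {
      const R_xlen_t colL = (R_xlen_t)(kc * kh + kr) * nrow;
      const R_xlen_t colR = colL + (R_xlen_t)KK * nrow;
      for (int p = 0; p < n; ++p) {
        const R_xlen_t img = (R_xlen_t)p * h * w;
        for (int oc = 0; oc < ow; ++oc) {
          const R_xlen_t src = img + (R_xlen_t)(oc + kc) * h + kr;
          const R_xlen_t dst = (R_xlen_t)p * P + (R_xlen_t)oc * oh;
          for (int orr = 0; orr < oh; ++orr) {
            lp[src + orr] += xp[colL + dst + orr];
            rp[src + orr] += xp[colR + dst + orr];
          }
        }
      }
    }
  }
  return List::create(_["left"] = dL, _["right"] = dR);
}
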