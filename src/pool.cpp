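#include <Rcpp.h>
using namespace Rcpp;

// 2x2 non-overlapping max pooling over an (n*P x K) convolutional activity
// matrix whose rows hold output positions in column-major order per patch.
// Ties break to the first cell in column-major window order. The argmax row
// index (0-based, into the conv matrix) is returned for the backward pass.
// Pooled activities come back in readout layout: within-kernel pooled
// positions fastest, kernels next, one column per patch.

// [[Rcpp::export]]
List pool_max_forward(const NumericMatrix &conv, int oh, int ow,
                      int n, int K) {
  const int ph = oh / 2, pw = ow / 2;
  const int P = oh * ow, PL = ph * pw;
  NumericMatrix pooled(PL * K, n);
  IntegerMatrix idx(PL * K, n);
  for (int k = 0; k < K; ++k) {
    const double *col = &conv(0, k);
    for (int p = 0; p < n; ++p) {
      const R_xlen_t base = (R_xlen_t)p * P;
      for (int pc = 0; pc < pw; ++pc) {
        for (int pr = 0; pr < ph; ++pr) {
          R_xlen_t r00 = base + (R_xlen_t)(2 * pc) * oh + 2 * pr;
          R_xlen_t cand[4] = {r00, r00 + 1, r00 + oh, r00 + oh + 1};
          R_xlen_t best = cand[0];
          double bv = col[cand[0]];
          for (int c = 1; c < 4; ++c) {
            if (col[cand[c]] > bv) { bv = col[cand[c]]; best = cand[c]; }
          }
          const int out = k * PL + pc * ph + pr;
          pooled(out, p) = bv;
          idx(out, p) = (int)best;
        }
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix pool_max_backward(const NumericMatrix &dpooled,
                                const IntegerMatrix &idx, int oh, int ow,
                                int n, int K) {
  const int ph = oh / 2, pw = ow / 2;
  const int P = oh * ow, PL = ph * pw;
  NumericMatrix dconv((R_xlen_t)n * P, K);
  for (int k = 0; k < K; ++k) {
    double *col = &dconv(0, k);
    for (int p = 0; p < n; ++p) {
      for (int j = 0; j < PL; ++j) {
        const int out = k * PL + j;
        col[idx(out, p)] += dpooled(out, p);
      }
    }
  }
  return dconv;
}
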