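#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for 1D 'same' convolutions. A is a [B, L, C] array
// (column-major, b fastest); output is [B*L, k*C] with row r = b + B*l.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector A, int B, int L, int C, int k) {
  int hw = (k - 1) / 2;
  NumericMatrix P(B * L, k * C);
  const double *a = A.begin();
  double *p = P.begin();
  for (int j = 0; j < k; ++j) {
    int off = j - hw;
    for (int c = 0; c < C; ++c) {
      double *pcol = p + (size_t)(j * C + c) * (B * L);
      const double *acol = a + (size_t)c * (B * L);
      for (int l = 0; l < L; ++l) {
        int ls = l + off;
        double *prow = pcol + (size_t)l * B;
        if (ls < 0 || ls >= L) {
          std::fill(prow, prow + B, 0.0);
        } else {
          std::copy(acol + (size_t)ls * B, acol + (size_t)(ls + 1) * B, prow);
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, int B, int L, int C, int k) {
  int hw = (k - 1) / 2;
  NumericVector dA(B * L * C);
  const double *p = dP.begin();
  double *a = dA.begin();
  for (int j = 0; j < k; ++j) {
    int off = j - hw;
    for (int c = 0; c < C; ++c) {
      const double *pcol = p + (size_t)(j * C + c) * (B * L);
      double *acol = a + (size_t)c * (B * L);
      for (int l = 0; l < L; ++l) {
        int ls = l + off;
        if (ls < 0 || ls >= L) continue;
        const double *prow = pcol + (size_t)l * B;
        double *arow = acol + (size_t)ls * B;
        for (int b = 0; b < B; ++b) arow[b] += prow[b];
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(B, L, C);
  return dA;
}

// [[Rcpp::export]]
NumericVector cpp_hardswish(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    out[i] = v >= 3 ? v : (v <= -3 ? 0.0 : v * (v + 3) / 6);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hardswish_grad(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    out[i] = v >= 3 ? 1.0 : (v <= -3 ? 0.0 : (2 * v + 3) / 6);
  }
  return out;
}

// Inverted-dropout mask using R's RNG (reproducible under set.seed).
// [[Rcpp::export]]
NumericVector cpp_dropout_mask(int n, double p) {
  NumericVector out(n);
  double keep = 1 - p;
  for (int i = 0; i < n; ++i) out[i] = unif_rand() < keep ? 1.0 / keep : 0.0;
  return out;
}
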