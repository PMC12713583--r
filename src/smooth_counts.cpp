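#include <Rcpp.h>
using namespace Rcpp;

// Direct truncated convolution of 1-ms spike counts with a symmetric
// kernel, exploiting count sparsity: only nonzero bins contribute.  Layout
// is bins x samples (one column per trial), so both the scan and the adds
// are contiguous.  Edges are zero-padded (no renormalization), matching a
// "same"-length linear convolution of the zero-extended series.
// [[Rcpp::export(name = ".smooth_counts_cpp")]]
NumericMatrix smooth_counts_cpp(IntegerMatrix counts, NumericVector kernel) {
  const int nb = counts.nrow(), ns = counts.ncol(), L = kernel.size();
  const int m = (L - 1) / 2;
  NumericMatrix out(nb, ns);
  for (int s = 0; s < ns; ++s) {
    const int* cc = &counts(0, s);
    double* oo = &out(0, s);
    for (int b = 0; b < nb; ++b) {
      const int c = cc[b];
      if (c == 0) continue;
      const int lo = std::max(0, b - m), hi = std::min(nb - 1, b + m);
      for (int j = lo; j <= hi; ++j)
        oo[j] += c * kernel[j - b + m];
    }
  }
  return out;
}

// Column-wise standardization (x - mu) / sd in one pass, one allocation.
// [[Rcpp::export(name = ".zscale_cols_cpp")]]
NumericMatrix zscale_cols_cpp(NumericMatrix x, NumericVector mu,
                              NumericVector sd) {
  const int nb = x.nrow(), ns = x.ncol();
  NumericMatrix out(nb, ns);
  for (int s = 0; s < ns; ++s) {
    const double m = mu[s], v = sd[s];
    const double* xi = &x(0, s);
    double* oo = &out(0, s);
    for (int b = 0; b < nb; ++b) oo[b] = (xi[b] - m) / v;
  }
  return out;
}
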