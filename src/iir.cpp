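// Direct-form-II-transposed IIR filter with explicit initial state, the
// inner loop of zero-phase (forward-backward) filtering.

#include <RcppArmadillo.h>

// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  int nf = std::max(a.n_elem, b.n_elem);
  arma::vec bb(nf, arma::fill::zeros), aa(nf, arma::fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  if (aa[0] == 0.0) Rcpp::stop("a[1] must be non-zero");
  bb /= aa[0]; aa /= aa[0];
  int ns = nf - 1;
  if ((int)zi.n_elem != ns) Rcpp::stop("initial state must have length %d", ns);
  arma::vec z = zi;
  int n = x.n_elem;
  arma::vec y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int k = 0; k < ns - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (ns > 0) z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
    y[i] = yi;
  }
  return y;
}
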