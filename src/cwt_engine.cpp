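#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Continuous wavelet transform power by frequency-domain filtering.
// X: FFT of the zero-padded signal (length nfft); for scale i only the bins
// j0[i]..j1[i] (1-based, inclusive) carry a non-negligible wavelet response,
// given in resp[i]. Returns the nf x n matrix of squared coefficient
// magnitudes over the first n samples.
// [[Rcpp::export]]
arma::mat cwt_power_engine(const arma::cx_vec& X, const int n,
                           const Rcpp::IntegerVector& j0,
                           const Rcpp::IntegerVector& j1,
                           const Rcpp::List& resp) {
  const arma::uword nfft = X.n_elem;
  const int nf = j0.size();
  arma::mat power(nf, n);
  arma::cx_vec Y(nfft);
  for (int i = 0; i < nf; ++i) {
    Y.zeros();
    Rcpp::NumericVector h = resp[i];
    const int a = j0[i] - 1;
    for (int k = 0; k < h.size(); ++k) {
      Y[a + k] = X[a + k] * h[k];
    }
    arma::cx_vec w = arma::ifft(Y);
    for (int t = 0; t < n; ++t) {
      const double re = w[t].real(), im = w[t].imag();
      power(i, t) = re * re + im * im;
    }
  }
  return power;
}
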