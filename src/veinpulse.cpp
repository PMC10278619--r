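#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

//' Per-frame Euclidean distance to the local median image.
//'
//' @param pixels matrix, one column per frame, one row per pixel.
//' @param window centred window length in frames (truncated at boundaries,
//'   the frame itself included).
//' @noRd
// [[Rcpp::export(name = ".ed_local_median")]]
arma::vec ed_local_median(const arma::mat& pixels, const int window) {
  const int n = pixels.n_cols;
  const int half = (window - 1) / 2;
  arma::vec ed(n);
  for (int i = 0; i < n; ++i) {
    const int w0 = std::max(0, i - half);
    const int w1 = std::min(n - 1, i + half);
    const arma::mat sub = pixels.cols(w0, w1).t();   // frames x pixels
    const arma::rowvec med = arma::median(sub, 0);   // per-pixel, contiguous
    ed(i) = arma::norm(pixels.col(i) - med.t(), 2);
  }
  return ed;
}

// Running median with arbitrary (odd or even) window, reflect padding.
// For even windows the sample sits left of centre: the window covering
// position i spans [i - floor((size-1)/2), i + size - 1 - floor((size-1)/2)].
// [[Rcpp::export(name = ".run_median")]]
arma::vec run_median(const arma::vec& x, const int size) {
  const int n = x.n_elem;
  const int left = (size - 1) / 2;
  const int right = size - 1 - left;
  // reflect padding: (c b a | a b c ...)
  arma::vec xp(n + size - 1);
  for (int i = 0; i < left; ++i) xp(i) = x(std::min(n - 1, left - i - 1));
  xp.subvec(left, left + n - 1) = x;
  for (int i = 0; i < right; ++i) xp(left + n + i) = x(std::max(0, n - 1 - i));
  arma::vec out(n);
  std::vector<double> buf(size);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < size; ++j) buf[j] = xp(i + j);
    const int k = size / 2;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double m = buf[k];
    if (size % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + k - 1, buf.begin() + k);
      m = 0.5 * (m + buf[k - 1]);
    }
    out(i) = m;
  }
  return out;
}
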