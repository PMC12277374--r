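#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. Coefficients are pre-padded to a
// common length by the caller so the inner loop carries no branches.
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  const size_t nz = b.size() - 1;
  std::vector<double> z(nz + 1, 0.0);  // one spare slot, z[nz] stays 0
  const double b0 = b[0];
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z[0];
    for (size_t k = 0; k < nz; ++k)
      z[k] = b[k + 1] * xi - a[k + 1] * yi + z[k + 1];
    x[i] = yi;
  }
}

//' Zero-phase IIR filtering (forward-backward pass)
//'
//' Applies the rational filter (b, a) forward and then backward so the net
//' phase response is zero. The signal is extended at both ends by an
//' odd-reflected pad of length \code{npad} samples to suppress start-up
//' transients; the pad is discarded before returning.
//'
//' @param b,a numeric filter coefficients (a[1] must be non-zero).
//' @param x numeric signal.
//' @param npad pad length in samples.
//' @return filtered signal, same length as \code{x}.
//' @keywords internal
// [[Rcpp::export]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x,
                           int npad = 2000) {
  const int n = x.size();
  if (n < 2) stop("signal too short to filter");
  if (a.size() < 1 || a[0] == 0.0) stop("a[1] must be non-zero");
  if (npad < 0) npad = 0;
  if (npad > n - 1) npad = n - 1;

  const size_t nc = std::max(b.size(), a.size());
  std::vector<double> bb(nc, 0.0), aa(nc, 0.0);
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k] / a[0];
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k] / a[0];

  std::vector<double> ext(n + 2 * npad);
  // odd reflection: 2*x[0] - x[k], mirrored
  for (int i = 0; i < npad; ++i) ext[i] = 2.0 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i) ext[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) ext[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  iir_pass(bb, aa, ext);
  std::reverse(ext.begin(), ext.end());
  iir_pass(bb, aa, ext);
  std::reverse(ext.begin(), ext.end());

  NumericVector out(n);
  std::copy(ext.begin() + npad, ext.begin() + npad + n, out.begin());
  return out;
}

//' Median via selection (linear time)
//'
//' @param x numeric vector (non-empty, finite).
//' @return the sample median (mean of the middle pair for even lengths).
//' @keywords internal
// [[Rcpp::export]]
double fast_median(NumericVector x) {
  const R_xlen_t n = x.size();
  if (n == 0) stop("empty vector");
  std::vector<double> v(x.begin(), x.end());
  const R_xlen_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

//' Median absolute deviation about a given centre (linear time)
//'
//' @param x numeric vector.
//' @param center subtrahend (usually the median of x).
//' @return median(|x - center|), unscaled.
//' @keywords internal
// [[Rcpp::export]]
double fast_mad_raw(NumericVector x, double center) {
  const R_xlen_t n = x.size();
  if (n == 0) stop("empty vector");
  std::vector<double> v(n);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = std::fabs(x[i] - center);
  const R_xlen_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

//' Strict local minima below a level
//'
//' A sample i (1 < i < n) qualifies when x[i] < level, x[i] <= x[i-1] and
//' x[i] < x[i+1] (plateaus report their last sample).
//'
//' @param x numeric signal.
//' @param level threshold level.
//' @return 1-based sample indices of qualifying minima.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector minima_below(NumericVector x, double level) {
  const R_xlen_t n = x.size();
  std::vector<int> idx;
  for (R_xlen_t i = 1; i + 1 < n; ++i) {
    if (x[i] < level && x[i] <= x[i - 1] && x[i] < x[i + 1])
      idx.push_back(static_cast<int>(i) + 1);
  }
  return wrap(idx);
}
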