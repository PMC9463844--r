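#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum Bernoulli scan LLR per replicate. `ord` holds, per centre
// column, the 1-based district positions in ascending distance order;
// `wlen` the number of admissible prefixes per centre (MSWS cap);
// `cases` one column of null case counts per replicate. High-rate scan:
// a window scores only when its rate exceeds the outside rate.
// [[Rcpp::export]]
NumericVector scan_max_bernoulli(const IntegerMatrix& ord,
                                 const IntegerVector& wlen,
                                 const NumericVector& totals,
                                 const NumericMatrix& cases,
                                 const double C, const double N) {
  const int n = ord.nrow(), R = cases.ncol();
  NumericVector out(R);
  if (C <= 0.0 || C >= N) return out;
  const double null_ll = C * std::log(C / N) +
    (N - C) * std::log(1.0 - C / N);
  for (int r = 0; r < R; ++r) {
    double best = 0.0;
    const double* cs = &cases(0, r);
    for (int c = 0; c < n; ++c) {
      double cum_c = 0.0, cum_n = 0.0;
      const int L = wlen[c];
      for (int i = 0; i < L; ++i) {
        const int k = ord(i, c) - 1;
        cum_c += cs[k];
        cum_n += totals[k];
        const double co = C - cum_c, no = N - cum_n;
        if (no > 0.0 && cum_c * no > co * cum_n) {
          double ll = -null_ll;
          if (cum_c > 0.0) ll += cum_c * std::log(cum_c / cum_n);
          if (cum_n > cum_c)
            ll += (cum_n - cum_c) * std::log((cum_n - cum_c) / cum_n);
          if (co > 0.0) ll += co * std::log(co / no);
          if (no > co) ll += (no - co) * std::log((no - co) / no);
          if (ll > best) best = ll;
        }
      }
    }
    out[r] = best;
  }
  return out;
}

// Maximum weighted normal scan LLR per replicate; y and w columns are
// the jointly permuted (rate, weight) pairs of one null replicate.
// sigma1^2 is floored at 1e-12; zero total variance gives 0.
// [[Rcpp::export]]
NumericVector scan_max_wnormal(const IntegerMatrix& ord,
                               const IntegerVector& wlen,
                               const NumericMatrix& y,
                               const NumericMatrix& w) {
  const int n = ord.nrow(), R = y.ncol();
  NumericVector out(R);
  for (int r = 0; r < R; ++r) {
    const double* yr = &y(0, r);
    const double* wr = &w(0, r);
    double Tw = 0.0, Twy = 0.0, Twyy = 0.0;
    for (int i = 0; i < n; ++i) {
      Tw += wr[i];
      Twy += wr[i] * yr[i];
      Twyy += wr[i] * yr[i] * yr[i];
    }
    const double s0 = (Twyy - Twy * Twy / Tw) / n;
    double best = 0.0;
    if (s0 > 1e-12) {
      for (int c = 0; c < n; ++c) {
        double sw = 0.0, swy = 0.0;
        const int L = wlen[c] < n - 1 ? wlen[c] : n - 1;
        for (int i = 0; i < L; ++i) {
          const int k = ord(i, c) - 1;
          sw += wr[k];
          swy += wr[k] * yr[k];
          const double ow = Tw - sw, owy = Twy - swy;
          if (ow > 0.0 && swy * ow > owy * sw) {
            double s1 = (Twyy - swy * swy / sw - owy * owy / ow) / n;
            if (s1 < 1e-12) s1 = 1e-12;
            const double ll = 0.5 * n * std::log(s0 / s1);
            if (ll > best) best = ll;
          }
        }
      }
    }
    out[r] = best;
  }
  return out;
}
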