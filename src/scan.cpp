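#include <Rcpp.h>
using namespace Rcpp;

// One-sided Bernoulli scan log likelihood ratio for a single window.
// l0 is the null log-likelihood term C*log(C/N) + (N-C)*log(1-C/N).
// 0*log(0) is taken as 0 throughout.
static inline double window_llr(double c, double n, double C, double N,
                                double l0) {
  double cout_ = C - c, nout = N - n;
  if (nout <= 0.0) return 0.0;                 // whole-series window
  if (c * nout <= cout_ * n) return 0.0;       // not a high-rate window
  double ll = 0.0;
  if (c > 0.0)              ll += c * std::log(c / n);
  if (n - c > 0.0)          ll += (n - c) * std::log(1.0 - c / n);
  if (cout_ > 0.0)          ll += cout_ * std::log(cout_ / nout);
  if (nout - cout_ > 0.0)   ll += (nout - cout_) * std::log(1.0 - cout_ / nout);
  return ll - l0;
}

static inline double null_loglik(double C, double N) {
  double l0 = 0.0;
  if (C > 0.0)     l0 += C * std::log(C / N);
  if (N - C > 0.0) l0 += (N - C) * std::log(1.0 - C / N);
  return l0;
}

// Enumerate all contiguous day windows of length 1..max_len and return the
// one maximizing the Bernoulli LLR. Ties: earliest start, then shortest
// window (guaranteed by ascending iteration with a strict comparison).
// [[Rcpp::export(name = ".scan_max_llr")]]
List scan_max_llr(IntegerVector totals, IntegerVector cases, int max_len) {
  int days = totals.size();
  if (cases.size() != days) stop("totals and cases lengths differ");
  if (max_len < 1 || max_len > days) stop("max_len out of range");
  double N = 0.0, C = 0.0;
  for (int i = 0; i < days; ++i) { N += totals[i]; C += cases[i]; }
  double l0 = null_loglik(C, N);
  double best = 0.0;
  int best_s = 0, best_len = 1;
  bool found = false;
  for (int s = 0; s < days; ++s) {
    double n = 0.0, c = 0.0;
    int lmax = std::min(max_len, days - s);
    for (int L = 1; L <= lmax; ++L) {
      n += totals[s + L - 1];
      c += cases[s + L - 1];
      if (c <= 0.0) continue;
      double llr = window_llr(c, n, C, N, l0);
      if (llr > best) {
        best = llr; best_s = s; best_len = L; found = true;
      }
    }
  }
  // recompute n, c of the best window
  double bn = 0.0, bc = 0.0;
  for (int i = best_s; i < best_s + best_len; ++i) { bn += totals[i]; bc += cases[i]; }
  return List::create(_["start"] = best_s + 1, _["len"] = best_len,
                      _["n"] = bn, _["c"] = bc, _["llr"] = best,
                      _["found"] = found);
}

// Maximum LLR only (used inside the Monte Carlo loop).
static double max_llr_only(const IntegerVector& totals, const int* cases,
                           int max_len, double N, double C, double l0) {
  int days = totals.size();
  double best = 0.0;
  for (int s = 0; s < days; ++s) {
    double n = 0.0, c = 0.0;
    int lmax = std::min(max_len, days - s);
    for (int L = 1; L <= lmax; ++L) {
      n += totals[s + L - 1];
      c += cases[s + L - 1];
      if (c <= 0.0) continue;
      double llr = window_llr(c, n, C, N, l0);
      if (llr > best) best = llr;
    }
  }
  return best;
}

// Monte Carlo replicates: condition on N (daily totals) and C; redistribute
// the C case labels uniformly at random among the N conceptions (multivariate
// hypergeometric over days, drawn sequentially), then rescan. Sampling is
// without replacement so simulated daily cases never exceed daily totals.
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".scan_mc_max_llrs")]]
NumericVector scan_mc_max_llrs(IntegerVector totals, int C, int reps,
                               int max_len) {
  int days = totals.size();
  double N = 0.0;
  for (int i = 0; i < days; ++i) N += totals[i];
  if (N <= 0.0) stop("empty series");
  if ((double)C > N) stop("C exceeds N");
  double l0 = null_loglik((double)C, N);
  std::vector<int> sim(days);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double remaining_n = N;
    int remaining_c = C;
    for (int i = 0; i < days; ++i) {
      if (remaining_c == 0) { sim[i] = 0; remaining_n -= totals[i]; continue; }
      double white = totals[i], black = remaining_n - totals[i];
      int ci = (int)::Rf_rhyper(white, black, (double)remaining_c);
      sim[i] = ci;
      remaining_c -= ci;
      remaining_n -= totals[i];
    }
    out[r] = max_llr_only(totals, sim.data(), max_len, N, (double)C, l0);
  }
  return out;
}
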