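#include <Rcpp.h>
using namespace Rcpp;

static inline double expected(double ra, double rb, double scale) {
  return 1.0 / (1.0 + std::pow(10.0, (rb - ra) / scale));
}

// Single sequential Elo pass over (winner, loser) index pairs (1-based).
// [[Rcpp::export]]
NumericVector elo_run_cpp(IntegerVector winner, IntegerVector loser,
                          int n_items, double k, double scale, double start) {
  NumericVector r(n_items, start);
  const int n = winner.size();
  for (int t = 0; t < n; ++t) {
    const int w = winner[t] - 1, l = loser[t] - 1;
    const double e = expected(r[w], r[l], scale);
    const double d = k * (1.0 - e);
    r[w] += d;
    r[l] -= d;
  }
  return r;
}

// Final ratings from n_seq independent uniform shuffles of the record order.
// Returns an n_items x n_seq matrix; shuffling uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix elo_sequences_cpp(IntegerVector winner, IntegerVector loser,
                                int n_items, double k, double scale,
                                double start, int n_seq) {
  const int n = winner.size();
  NumericMatrix out(n_items, n_seq);
  std::vector<int> idx(n);
  std::vector<double> r(n_items);
  for (int s = 0; s < n_seq; ++s) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    // Fisher-Yates driven by R's RNG stream
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    std::fill(r.begin(), r.end(), start);
    for (int t = 0; t < n; ++t) {
      const int w = winner[idx[t]] - 1, l = loser[idx[t]] - 1;
      const double e = expected(r[w], r[l], scale);
      const double d = k * (1.0 - e);
      r[w] += d;
      r[l] -= d;
    }
    for (int i = 0; i < n_items; ++i) out(i, s) = r[i];
  }
  return out;
}

// Running consistency index: process records sequentially, maintaining
// standing Elo ratings. A record is "evaluated" when the standing ratings
// differ; it is an "upset" when the lower-rated item wins. weighting:
// 0 = |standing rating difference|, 1 = expected-probability margin
// 2 * |E_winner - 0.5|.
// [[Rcpp::export]]
List consistency_cpp(IntegerVector winner, IntegerVector loser, int n_items,
                     double k, double scale, double start, int weighting) {
  NumericVector r(n_items, start);
  const int n = winner.size();
  const double tol = 1e-9;
  long n_eval = 0, n_upset = 0;
  double w_eval = 0.0, w_upset = 0.0;
  for (int t = 0; t < n; ++t) {
    const int w = winner[t] - 1, l = loser[t] - 1;
    const double rw = r[w], rl = r[l];
    const double e = expected(rw, rl, scale);
    if (std::fabs(rw - rl) > tol) {
      const double wt = (weighting == 0) ? std::fabs(rw - rl)
                                         : 2.0 * std::fabs(e - 0.5);
      ++n_eval;
      w_eval += wt;
      if (rw < rl) {
        ++n_upset;
        w_upset += wt;
      }
    }
    const double d = k * (1.0 - e);
    r[w] += d;
    r[l] -= d;
  }
  return List::create(_["n_evaluated"] = static_cast<double>(n_eval),
                      _["n_upsets"] = static_cast<double>(n_upset),
                      _["weight_evaluated"] = w_eval,
                      _["weight_upsets"] = w_upset);
}
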