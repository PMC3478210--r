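#include <Rcpp.h>
using namespace Rcpp;

// Embedded jump chain of the four reaction channels. Only the identity of
// each event matters for fixation, so waiting times are never sampled and
// alpha drops out. Uses R's RNG stream (one uniform per event), so results
// are reproducible under set.seed().

static inline int step(long long &m, long long &n, int Ni, int Nf,
                       double cost) {
  double N = (double)(m + n);
  double bS = (Nf - N) * (double)n * (double)m / N;
  double bA = (Nf - N) * (double)n * (double)n / N;
  double dS = (N - Ni) * (double)m * (double)m / N;
  double dA = cost * (N - Ni) * (double)m * (double)n / N;
  double u = unif_rand() * (bS + bA + dS + dA);
  if (u < bS)                { ++m; return 0; }
  if (u < bS + bA)           { ++n; return 1; }
  if (u < bS + bA + dS)      { --m; return 2; }
  --n; return 3;
}

// [[Rcpp::export]]
List gillespie_batch_cpp(int Ni, int Nf, double cost, int m0, int n0,
                         int reps, double max_events) {
  IntegerVector outcome(reps);
  NumericVector n_events(reps);
  for (int r = 0; r < reps; ++r) {
    long long m = m0, n = n0;
    double ev = 0.0;
    while (m > 0 && n > 0) {
      if (ev >= max_events)
        stop("event cap (%g) hit in replicate %d", max_events, r + 1);
      step(m, n, Ni, Nf, cost);
      ev += 1.0;
    }
    outcome[r] = (m == 0) ? 1 : 0;  // 1 = altruists fixed
    n_events[r] = ev;
  }
  return List::create(_["outcome"] = outcome, _["n_events"] = n_events);
}

// [[Rcpp::export]]
List gillespie_trajectory_cpp(int Ni, int Nf, double cost, int m0, int n0,
                              double max_events) {
  std::vector<int> mm, nn;
  long long m = m0, n = n0;
  double ev = 0.0;
  mm.push_back((int)m); nn.push_back((int)n);
  while (m > 0 && n > 0) {
    if (ev >= max_events)
      stop("event cap (%g) hit", max_events);
    step(m, n, Ni, Nf, cost);
    ev += 1.0;
    mm.push_back((int)m); nn.push_back((int)n);
  }
  return List::create(_["outcome"] = (m == 0) ? 1 : 0,
                      _["n_events"] = ev,
                      _["m"] = wrap(mm), _["n"] = wrap(nn));
}
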