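// Metropolis Monte Carlo over protonation microstates.
//
// Energies are in pK units: g(s) = sum_i s_i (pH - pKint_i)
//                                 + sum_{i<j} W_ij s_i s_j,
// Boltzmann weight 10^(-g).  Each MC step is one cycle: every site is
// visited once in a fresh random order and a random protonation state is
// proposed for it; then every strongly coupled pair (W_ij above the pair
// threshold) is visited once in random order with a random joint state
// proposed for the two sites.  Proposals are symmetric (the new state is
// drawn uniformly, possibly equal to the current one), so the Metropolis
// acceptance min(1, 10^(-dg)) leaves the Boltzmann distribution invariant
// and the chain stays ergodic even for degenerate (dg = 0) moves.  Uses
// R's RNG, so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline bool accept(double dg) {
  return dg <= 0.0 || unif_rand() < std::pow(10.0, -dg);
}

// [[Rcpp::export(name = ".mcTitrationCpp")]]
List mcTitrationCpp(NumericVector pKint, NumericMatrix W, double pH,
                    int nSteps, double pairThreshold, double burnIn,
                    IntegerVector startState) {
  const int n = pKint.size();
  if (W.nrow() != n || W.ncol() != n)
    stop("W dimensions must match pKint");
  if (n > 20) stop("too many sites for dense state counting");
  if (nSteps < 1) stop("nSteps must be >= 1");

  std::vector<int> s(n, 0);
  if (startState.size() == n)
    for (int i = 0; i < n; ++i) s[i] = startState[i] ? 1 : 0;

  std::vector<std::pair<int, int> > pairs;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > pairThreshold) pairs.push_back(std::make_pair(i, j));

  const int nStates = 1 << n;
  std::vector<double> counts(nStates, 0.0);
  std::vector<double> occ(n, 0.0);
  NumericVector totalSeries(nSteps);
  const int burn = (int)std::floor(burnIn * nSteps);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<int> porder(pairs.size());
  for (size_t i = 0; i < pairs.size(); ++i) porder[i] = (int)i;

  long proposed = 0, accepted = 0;
  double kept = 0.0;

  for (int step = 0; step < nSteps; ++step) {
    // fresh random visiting order for the single-site sweep
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      const int si = unif_rand() < 0.5 ? 0 : 1;  // random proposed state
      if (si == s[i]) continue;                  // no-op proposal
      double dg = pH - pKint[i];
      for (int j = 0; j < n; ++j)
        if (j != i) dg += W(i, j) * s[j];
      if (s[i] == 1) dg = -dg;      // deprotonation reverses the sign
      ++proposed;
      if (accept(dg)) { s[i] = si; ++accepted; }
    }
    // coupled-pair sweep
    if (!pairs.empty()) {
      for (int i = (int)porder.size() - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        std::swap(porder[i], porder[j]);
      }
      for (size_t k = 0; k < porder.size(); ++k) {
        const int i = pairs[porder[k]].first;
        const int j = pairs[porder[k]].second;
        const int draw = (int)std::floor(unif_rand() * 4.0);
        const int si = draw & 1, sj = (draw >> 1) & 1;  // random joint state
        if (si == s[i] && sj == s[j]) continue;
        double dg = (si - s[i]) * (pH - pKint[i]) +
                    (sj - s[j]) * (pH - pKint[j]) +
                    W(i, j) * (si * sj - s[i] * s[j]);
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j) continue;
          dg += W(i, m) * (si - s[i]) * s[m];
          dg += W(j, m) * (sj - s[j]) * s[m];
        }
        ++proposed;
        if (accept(dg)) { s[i] = si; s[j] = sj; ++accepted; }
      }
    }
    int tot = 0, idx = 0;
    for (int i = 0; i < n; ++i) { tot += s[i]; idx |= (s[i] << i); }
    totalSeries[step] = tot;
    if (step >= burn) {
      counts[idx] += 1.0;
      for (int i = 0; i < n; ++i) occ[i] += s[i];
      kept += 1.0;
    }
  }

  NumericVector countsOut(counts.begin(), counts.end());
  NumericVector occOut(n);
  for (int i = 0; i < n; ++i) occOut[i] = occ[i] / kept;
  IntegerVector finalState(n);
  for (int i = 0; i < n; ++i) finalState[i] = s[i];

  return List::create(
    _["counts"] = countsOut,
    _["occupancy"] = occOut,
    _["total_series"] = totalSeries,
    _["final_state"] = finalState,
    _["n_kept"] = kept,
    _["n_pairs"] = (int)pairs.size(),
    _["acceptance"] = proposed > 0 ? (double)accepted / proposed : NA_REAL);
}
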