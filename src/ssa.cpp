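#include <Rcpp.h>
using namespace Rcpp;

// Exact (direct-method) event-driven simulation of the 8-species
// association/dissociation network in copy numbers.
//
// Species order (fixed): A_TU, B_U, A_L, B_L,
//                        A_TU_B_U, A_TU_B_L, A_L_B_U, A_L_B_L
// Channels 0-3: association A+B -> AB, propensity (k_on/omega) * nA * nB
// Channels 4-7: dissociation AB -> A+B, propensity k_off * nAB
//
// Uses R's RNG (unif_rand) so trajectories are reproducible under set.seed.
// [[Rcpp::export(name = ".ssa_exchange")]]
IntegerMatrix ssa_exchange(IntegerVector n0, double k_on, double k_off,
                           double omega, NumericVector t_grid) {
  const int nSpecies = 8, nChan = 8, nT = t_grid.size();
  // channel -> (free A index, free B index, complex index)
  const int iA[4] = {0, 0, 2, 2};
  const int iB[4] = {1, 3, 1, 3};
  const int iC[4] = {4, 5, 6, 7};
  const double kb = k_on / omega;

  std::vector<double> n(nSpecies);
  for (int i = 0; i < nSpecies; ++i) n[i] = n0[i];

  IntegerMatrix out(nT, nSpecies);
  double t = 0.0;
  int next = 0;
  double a[nChan];

  RNGScope scope;
  for (;;) {
    double a0 = 0.0;
    for (int c = 0; c < 4; ++c) { a[c] = kb * n[iA[c]] * n[iB[c]]; a0 += a[c]; }
    for (int c = 0; c < 4; ++c) { a[4 + c] = k_off * n[iC[c]]; a0 += a[4 + c]; }

    double t_event;
    if (a0 <= 0.0) {
      t_event = R_PosInf;               // absorbing: no reactants left
    } else {
      double u = unif_rand();
      if (u <= 0.0) u = DBL_MIN;        // guard log(0)
      t_event = t - std::log(u) / a0;
    }

    while (next < nT && t_grid[next] < t_event) {
      for (int i = 0; i < nSpecies; ++i) out(next, i) = (int)n[i];
      ++next;
    }
    if (next >= nT) break;
    t = t_event;

    double r = unif_rand() * a0;
    int c = 0;
    double cum = a[0];
    while (r > cum && c < nChan - 1) cum += a[++c];
    if (c < 4) {                        // association
      n[iA[c]] -= 1; n[iB[c]] -= 1; n[iC[c]] += 1;
    } else {                            // dissociation
      int d = c - 4;
      n[iA[d]] += 1; n[iB[d]] += 1; n[iC[d]] -= 1;
    }
  }
  return out;
}
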