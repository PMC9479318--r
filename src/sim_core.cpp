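#include <Rcpp.h>
using namespace Rcpp;

// Agent-based opinion-dynamics step loop.
//
// Each time step every agent initiates a discussion with probability equal
// to its per-step rate. The partner is drawn from the agent's own
// ideological group with probability bias (ingroup bias of the initiator),
// otherwise from the other group, uniformly within group. Both parties
// argue for their current opinion; each presents an HVFL-kind argument with
// probability (1+A)/2 when arguing the advantaged opinion and (1-A)/2 when
// arguing the disadvantaged one. A listener holding the opposite opinion
// switches with probability s when the argument kind is relevant to it:
// liberals are moved only by HVFL arguments, conservatives by any kind.
// Both parties are evaluated on pre-encounter opinions; all switches are
// applied simultaneously at the end of the step.
//
// opinion0: 0/1 (1 = advantaged opinion); ideology: 0 = liberal, 1 = cons;
// cell: 0-based cell index (ideology x frequency class) for reporting.
// Returns (horizon+1) x n_cells matrix of cell prevalences of opinion 1.

// [[Rcpp::export]]
NumericMatrix sim_run_cpp(IntegerVector opinion0, IntegerVector ideology,
                          NumericVector rate, NumericVector bias,
                          IntegerVector cell, int n_cells,
                          double advantage, double persuade, int horizon) {
  int n = opinion0.size();
  std::vector<int> op(opinion0.begin(), opinion0.end());
  std::vector<int> libs, cons;
  libs.reserve(n); cons.reserve(n);
  for (int i = 0; i < n; i++) {
    if (ideology[i] == 0) libs.push_back(i); else cons.push_back(i);
  }
  std::vector<int> cell_n(n_cells, 0);
  for (int i = 0; i < n; i++) cell_n[cell[i]]++;

  NumericMatrix prev(horizon + 1, n_cells);
  std::vector<int> cell_sum(n_cells, 0);
  for (int i = 0; i < n; i++) cell_sum[cell[i]] += op[i];
  for (int c = 0; c < n_cells; c++)
    prev(0, c) = cell_n[c] > 0 ? (double)cell_sum[c] / cell_n[c] : NA_REAL;

  double p_adv = (1.0 + advantage) / 2.0;   // P(HVFL kind | arguing advantaged)
  double p_dis = (1.0 - advantage) / 2.0;
  std::vector<char> flip(n, 0);

  for (int t = 1; t <= horizon; t++) {
    std::fill(flip.begin(), flip.end(), 0);
    for (int i = 0; i < n; i++) {
      if (unif_rand() >= rate[i]) continue;
      bool ingroup = unif_rand() < bias[i];
      bool i_lib = (ideology[i] == 0);
      const std::vector<int>& pool =
        (ingroup == i_lib) ? libs : cons;   // same group if ingroup
      if (pool.empty()) continue;
      size_t k = (size_t)(unif_rand() * pool.size());
      if (k >= pool.size()) k = pool.size() - 1;
      int j = pool[k];
      if (j == i) continue;                  // no self-discussion
      if (op[i] == op[j]) continue;          // agreement: no switch possible
      // i speaks to j, then j speaks to i, both on pre-encounter opinions
      int pair_sp[2] = {i, j};
      int pair_li[2] = {j, i};
      for (int d = 0; d < 2; d++) {
        int sp = pair_sp[d], li = pair_li[d];
        double p_hvfl = (op[sp] == 1) ? p_adv : p_dis;
        bool hvfl = unif_rand() < p_hvfl;
        bool relevant = (ideology[li] == 1) || hvfl;
        if (relevant && unif_rand() < persuade) flip[li] = 1;
      }
    }
    for (int i = 0; i < n; i++) if (flip[i]) op[i] = 1 - op[i];
    std::fill(cell_sum.begin(), cell_sum.end(), 0);
    for (int i = 0; i < n; i++) cell_sum[cell[i]] += op[i];
    for (int c = 0; c < n_cells; c++)
      prev(t, c) = cell_n[c] > 0 ? (double)cell_sum[c] / cell_n[c] : NA_REAL;
  }
  return prev;
}
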