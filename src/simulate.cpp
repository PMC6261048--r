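// Monte-Carlo Birth-Death Moran trajectories, used as an independent
// stochastic check of the exact and numeric solvers.  Each step picks a
// reproducing individual with probability proportional to fitness (r for
// mutants, 1 for residents) and replaces a uniformly chosen neighbour,
// which realises the subset-chain transition kernel exactly.  Uses R's RNG
// so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_fixation(List adj, double r, int runs, IntegerVector initial) {
  const int n = adj.size();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i] = std::vector<int>(v.begin(), v.end()); // 1-based vertices
  }
  const bool uniform_init = initial.size() == 0;
  const long long step_cap = 100000000LL; // absorption is a.s. finite
  RNGScope scope;

  int fixations = 0;
  IntegerVector init_runs(n), init_fix(n);
  std::vector<char> mutant(n + 1);

  for (int run = 0; run < runs; ++run) {
    std::fill(mutant.begin(), mutant.end(), 0);
    int k; // number of mutants
    int init_v = -1;
    if (uniform_init) {
      init_v = 1 + (int)(unif_rand() * n);
      if (init_v > n) init_v = n;
      mutant[init_v] = 1;
      k = 1;
      init_runs[init_v - 1]++;
    } else {
      for (int j = 0; j < initial.size(); ++j) mutant[initial[j]] = 1;
      k = initial.size();
    }
    long long steps = 0;
    while (k > 0 && k < n) {
      if (++steps > step_cap)
        stop("trajectory exceeded the step cap; this indicates a bug");
      double w = r * k + (n - k);
      double u = unif_rand() * w;
      int repro;
      if (u < r * k) {
        // uniformly among the k mutants
        int idx = (int)(u / r); // in [0, k)
        if (idx >= k) idx = k - 1;
        repro = 0;
        for (int v = 1; v <= n; ++v) if (mutant[v] && idx-- == 0) { repro = v; break; }
      } else {
        int idx = (int)(u - r * k); // in [0, n-k)
        if (idx >= n - k) idx = n - k - 1;
        repro = 0;
        for (int v = 1; v <= n; ++v) if (!mutant[v] && idx-- == 0) { repro = v; break; }
      }
      const std::vector<int>& ns = nb[repro - 1];
      int j = ns[(int)(unif_rand() * ns.size()) % ns.size()];
      if (mutant[j] != mutant[repro]) {
        k += mutant[repro] ? 1 : -1;
        mutant[j] = mutant[repro];
      }
      if ((steps & 0xFFFFF) == 0) checkUserInterrupt();
    }
    if (k == n) {
      ++fixations;
      if (uniform_init) init_fix[init_v - 1]++;
    }
  }
  return List::create(_["fixations"] = fixations,
                      _["initial_runs"] = init_runs,
                      _["initial_fixations"] = init_fix);
}
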