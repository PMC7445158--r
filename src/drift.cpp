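#include "core.h"

using namespace Rcpp;
using namespace cellmet;

// Directional-drift walker: a non-negative integer fidelity value takes a
// lazy +/-1 random walk clamped at 0.  The first mutation channel fires with
// probability 0.5^fidelity (test mode), 0 (min control) or 1 (max control);
// a second channel fires with a constant base probability.
// mode: 0 = test, 1 = min_control, 2 = max_control.

// [[Rcpp::export]]
NumericVector cpp_drift_ensemble(int mode, int n_runs, int n_steps,
                                 int initial_fidelity, double base_prob) {
  std::vector<double> hist;
  for (int r = 0; r < n_runs; ++r) {
    int x = initial_fidelity;
    for (int s = 0; s < n_steps; ++s) {
      double p1 = mode == 1 ? 0.0 : (mode == 2 ? 1.0 : std::pow(0.5, x));
      if (coin(p1)) {
        x += coin(0.5) ? 1 : -1;
        if (x < 0) x = 0;
      }
      if (coin(base_prob)) {
        x += coin(0.5) ? 1 : -1;
        if (x < 0) x = 0;
      }
    }
    if (x >= static_cast<int>(hist.size())) hist.resize(x + 1, 0.0);
    hist[x] += 1.0;
  }
  NumericVector out = wrap(hist);
  CharacterVector nm(hist.size());
  for (size_t i = 0; i < hist.size(); ++i) nm[i] = std::to_string(i);
  out.names() = nm;
  return out;
}
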