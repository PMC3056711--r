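#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integration of an ensemble of Izhikevich neurons sharing the
// parameter set (a, b, c, d). Each unit is driven by a constant current plus
// iid Gaussian noise redrawn at every step. The membrane update uses the
// customary two half-steps of dt for numerical stability; dt is in ms.
// Noise is drawn from R's RNG so runs are reproducible under set.seed().
//
// Returns per-unit spike counts, the updated (v, u) state and, optionally,
// spike times (ms, relative to the start of this call) with unit indices.
// [[Rcpp::export]]
List izh_ensemble_run(NumericVector v, NumericVector u, NumericVector current,
                      double noise_sd, double a, double b, double c, double d,
                      int n_steps, double dt, bool keep_times) {
  int n = v.size();
  if (u.size() != n || current.size() != n)
    stop("v, u and current must have the same length");
  NumericVector vv = clone(v), uu = clone(u);
  IntegerVector counts(n);
  std::vector<double> times;
  std::vector<int> units;
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double I = current[i];
      if (noise_sd > 0) I += R::norm_rand() * noise_sd;
      double vi = vv[i], ui = uu[i];
      vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui += dt * a * (b * vi - ui);
      if (vi >= 30.0) {
        vi = c;
        ui += d;
        counts[i]++;
        if (keep_times) {
          times.push_back((t + 1) * dt);
          units.push_back(i + 1);
        }
      }
      vv[i] = vi;
      uu[i] = ui;
    }
  }
  List out = List::create(_["v"] = vv, _["u"] = uu, _["counts"] = counts);
  if (keep_times) {
    out["times"] = NumericVector(times.begin(), times.end());
    out["units"] = IntegerVector(units.begin(), units.end());
  }
  return out;
}
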