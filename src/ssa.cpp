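#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (direct-method SSA) of the labeling process.
// Molecules born during (t_obs - t_label, t_obs] carry a label flag;
// degradation and splicing act identically on labeled and unlabeled
// molecules. Transcription runs at rate alpha until t_switch, then stops
// (induction-then-off). Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export(name = ".ssa_baseline")]]
IntegerMatrix ssa_baseline(NumericVector alpha, NumericVector gamma_t,
                           NumericVector t_obs, NumericVector t_label,
                           NumericVector t_switch) {
  int n = t_obs.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("l", "r");
  for (int j = 0; j < n; ++j) {
    double a = alpha[j % alpha.size()];
    double g = gamma_t[j % gamma_t.size()];
    double T = t_obs[j];
    double tl = t_label[j % t_label.size()];
    double ts = t_switch[j % t_switch.size()];
    if (!R_finite(a) || !R_finite(g) || a < 0 || g < 0)
      stop("non-finite or negative rates");
    double win = T - tl;  // label window start
    double t = 0.0;
    int U = 0, L = 0;
    while (t < T) {
      double birth = (t < ts) ? a : 0.0;
      double total = birth + g * (U + L);
      if (total <= 0.0) {
        if (t < ts && a > 0.0) { t = ts; continue; }
        break;
      }
      double dt = R::rexp(1.0 / total);
      if (t < ts && t + dt > ts && birth > 0.0) { t = ts; continue; }
      t += dt;
      if (t >= T) break;
      if (R::unif_rand() * total < birth) {
        if (t > win) ++L; else ++U;
      } else {
        if (R::unif_rand() * (U + L) < L) --L; else --U;
      }
    }
    out(j, 0) = L;
    out(j, 1) = U + L;
  }
  return out;
}

// [[Rcpp::export(name = ".ssa_splicing")]]
IntegerMatrix ssa_splicing(NumericVector alpha, NumericVector beta,
                           NumericVector gamma_s, NumericVector t_obs,
                           NumericVector t_label, NumericVector t_switch) {
  int n = t_obs.size();
  IntegerMatrix out(n, 4);
  colnames(out) = CharacterVector::create("uu", "ul", "su", "sl");
  for (int j = 0; j < n; ++j) {
    double a = alpha[j % alpha.size()];
    double b = beta[j % beta.size()];
    double g = gamma_s[j % gamma_s.size()];
    double T = t_obs[j];
    double tl = t_label[j % t_label.size()];
    double ts = t_switch[j % t_switch.size()];
    if (!R_finite(a) || !R_finite(b) || !R_finite(g) ||
        a < 0 || b < 0 || g < 0)
      stop("non-finite or negative rates");
    double win = T - tl;
    double t = 0.0;
    int UU = 0, UL = 0, SU = 0, SL = 0;
    while (t < T) {
      double birth = (t < ts) ? a : 0.0;
      double spl = b * (UU + UL);
      double deg = g * (SU + SL);
      double total = birth + spl + deg;
      if (total <= 0.0) {
        if (t < ts && a > 0.0) { t = ts; continue; }
        break;
      }
      double dt = R::rexp(1.0 / total);
      if (t < ts && t + dt > ts && birth > 0.0) { t = ts; continue; }
      t += dt;
      if (t >= T) break;
      double u = R::unif_rand() * total;
      if (u < birth) {
        if (t > win) ++UL; else ++UU;
      } else if (u < birth + spl) {
        if (R::unif_rand() * (UU + UL) < UL) { --UL; ++SL; }
        else { --UU; ++SU; }
      } else {
        if (R::unif_rand() * (SU + SL) < SL) --SL; else --SU;
      }
    }
    out(j, 0) = UU; out(j, 1) = UL; out(j, 2) = SU; out(j, 3) = SL;
  }
  return out;
}
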