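// Greedy ("ideal agent") reward harvesting over parameter grids.
//
// An ideal agent always takes the response type its model currently rates
// most likely to be rewarded; exact ties at belief 0.5 are broken by a fair
// coin drawn from R's RNG stream (so runs are reproducible under set.seed).
// Coupled beliefs update from the revealed rewarded type, so each grid
// point can be evaluated independently on the same outcome sequence.

#include <Rcpp.h>
using namespace Rcpp;

static inline int greedy_type1(double b1) {
  // b1 = belief that a type-1 response is rewarded
  if (b1 > 0.5) return 1;
  if (b1 < 0.5) return 2;
  return (unif_rand() < 0.5) ? 1 : 2;
}

// [[Rcpp::export]]
IntegerVector cpp_rl_ideal_wins(NumericVector alphas, IntegerVector rewarded) {
  int g = alphas.size(), n = rewarded.size();
  IntegerVector wins(g);
  for (int i = 0; i < g; ++i) {
    double q = 0.5;
    int w = 0;
    for (int t = 0; t < n; ++t) {
      int resp = greedy_type1(q);
      if (resp == rewarded[t]) ++w;
      double r = (rewarded[t] == 1) ? 1.0 : 0.0;
      q += alphas[i] * (r - q);
    }
    wins[i] = w;
  }
  return wins;
}

// [[Rcpp::export]]
IntegerVector cpp_wl_ideal_wins(NumericVector alpha_win,
                                NumericVector alpha_loss,
                                IntegerVector rewarded) {
  int g = alpha_win.size(), n = rewarded.size();
  IntegerVector wins(g);
  for (int i = 0; i < g; ++i) {
    double q = 0.5;
    int w = 0;
    for (int t = 0; t < n; ++t) {
      int resp = greedy_type1(q);
      bool win = (resp == rewarded[t]);
      if (win) ++w;
      double a = win ? alpha_win[i] : alpha_loss[i];
      double r = (rewarded[t] == 1) ? 1.0 : 0.0;
      q += a * (r - q);
    }
    wins[i] = w;
  }
  return wins;
}

// [[Rcpp::export]]
IntegerVector cpp_hmm_ideal_wins(NumericVector p_switch, NumericVector p_error,
                                 IntegerVector rewarded) {
  int g = p_switch.size(), n = rewarded.size();
  IntegerVector wins(g);
  for (int i = 0; i < g; ++i) {
    double stay = 1.0 - p_switch[i], hit = 1.0 - p_error[i];
    double post0 = 0.5, post1 = 0.5;
    int w = 0;
    for (int t = 0; t < n; ++t) {
      double q0 = stay * post0 + p_switch[i] * post1;
      double q1 = p_switch[i] * post0 + stay * post1;
      double b = hit * q0 + p_error[i] * q1;
      int resp = greedy_type1(b);
      if (resp == rewarded[t]) ++w;
      double l0 = (rewarded[t] == 1) ? hit : p_error[i];
      double l1 = (rewarded[t] == 1) ? p_error[i] : hit;
      double norm = l0 * q0 + l1 * q1;
      post0 = l0 * q0 / norm;
      post1 = l1 * q1 / norm;
    }
    wins[i] = w;
  }
  return wins;
}
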