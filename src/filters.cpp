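// Belief-trajectory filters for the trial-by-trial learning models.
//
// Encodings shared with the R side:
//   rewarded  : 1 or 2, the response type that wins on each trial
//   responded : TRUE unless the trial was missed (missed trials never update)
//   feedback  : 1 win, 0 loss, -1 missed (the responder's own outcome)
//   color     : 1 red, 2 blue;  button : 1 or 2, 0 when missed
//
// Every trajectory function returns the belief *used on* trial t, i.e. the
// state after incorporating trials 1..t-1 only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Coupled delta rule: Q1 tracks the predicted value of a type-1 response,
// updated from the revealed rewarded type on every responded trial.
// [[Rcpp::export]]
NumericVector cpp_rl_belief(double alpha, IntegerVector rewarded,
                            LogicalVector responded) {
  int n = rewarded.size();
  NumericVector B(n);
  double q = 0.5;
  for (int t = 0; t < n; ++t) {
    B[t] = q;
    if (responded[t]) {
      double r = (rewarded[t] == 1) ? 1.0 : 0.0;
      q += alpha * (r - q);
    }
  }
  return B;
}

// Win/loss-split delta rule: the update incorporating trial t uses
// alpha_win when trial t was a win for the responder, alpha_loss on a loss.
// [[Rcpp::export]]
NumericVector cpp_wl_belief(double alpha_win, double alpha_loss,
                            IntegerVector rewarded, IntegerVector feedback) {
  int n = rewarded.size();
  NumericVector B(n);
  double q = 0.5;
  for (int t = 0; t < n; ++t) {
    B[t] = q;
    if (feedback[t] >= 0) {
      double a = (feedback[t] == 1) ? alpha_win : alpha_loss;
      double r = (rewarded[t] == 1) ? 1.0 : 0.0;
      q += a * (r - q);
    }
  }
  return B;
}

// Uncoupled learner: four action values, one per (color, button) cell;
// only the experienced cell moves, R = 1 on a win, 0 on a loss.
// Returns the two displayed-color values (button 1, button 2) per trial.
// [[Rcpp::export]]
NumericMatrix cpp_unc_belief(double alpha, IntegerVector color,
                             IntegerVector button, IntegerVector feedback) {
  int n = color.size();
  NumericMatrix B(n, 2);
  double q[2][2] = {{0.5, 0.5}, {0.5, 0.5}}; // [color-1][button-1]
  for (int t = 0; t < n; ++t) {
    int c = color[t] - 1;
    B(t, 0) = q[c][0];
    B(t, 1) = q[c][1];
    if (feedback[t] >= 0 && button[t] > 0) {
      int b = button[t] - 1;
      double r = (feedback[t] == 1) ? 1.0 : 0.0;
      q[c][b] += alpha * (r - q[c][b]);
    }
  }
  return B;
}

// Two-state hidden Markov forward filter.  The belief reported for trial t
// is the predictive probability that a type-1 response is rewarded, with one
// state transition applied beyond the posterior over trials 1..t-1.  The
// per-trial normalizer equals that predictive outcome probability, so the
// product of normalizers is the marginal likelihood of the outcome sequence.
// [[Rcpp::export]]
List cpp_hmm_filter(double p_switch, double p_error, IntegerVector rewarded,
                    LogicalVector responded) {
  int n = rewarded.size();
  NumericVector B(n);
  double post0 = 0.5, post1 = 0.5; // P(state = rule 1), P(state = rule 2)
  double stay = 1.0 - p_switch;
  double hit = 1.0 - p_error; // P(rule-consistent type rewarded | state)
  double loglik = 0.0;
  for (int t = 0; t < n; ++t) {
    double q0 = stay * post0 + p_switch * post1;
    double q1 = p_switch * post0 + stay * post1;
    double b = hit * q0 + p_error * q1; // P(type 1 rewarded next)
    B[t] = b;
    if (responded[t]) {
      double norm, l0, l1;
      if (rewarded[t] == 1) {
        l0 = hit; l1 = p_error; norm = b;
      } else {
        l0 = p_error; l1 = hit; norm = 1.0 - b;
      }
      if (norm <= 0.0)
        stop("zero normalizer in HMM filter (degenerate p_error)");
      loglik += std::log(norm);
      post0 = l0 * q0 / norm;
      post1 = l1 * q1 / norm;
    }
  }
  return List::create(_["belief"] = B, _["loglik"] = loglik);
}

// Hierarchical volatility filter.  Joint over X (reward probability of a
// type-2 response), V (volatility) and K (confidence in volatility),
// propagated with the supplied discretized kernels and renormalized each
// responded trial.  The belief reported for trial t is E[X] under the
// posterior from trials 1..t-1 (the X kernel is mean-preserving, so no
// further propagation is applied before the choice).
//   Xker : cube (x_next, x_prev, v) ; Vker : cube (v_next, v_prev, k)
// [[Rcpp::export]]
NumericVector cpp_vol_filter(arma::cube Xker, arma::cube Vker,
                             arma::vec x_grid, IntegerVector rewarded,
                             LogicalVector responded) {
  int nx = Xker.n_rows, nv = Xker.n_slices, nk = Vker.n_slices;
  int n = rewarded.size();
  arma::cube J(nx, nv, nk);
  J.fill(1.0 / (nx * nv * nk)); // uniform prior

  NumericVector B(n);
  double ex = arma::dot(x_grid, arma::ones<arma::vec>(nx)) / nx; // 0.5
  arma::vec lik_win2 = x_grid;        // P(type-2 rewarded | X = x)
  arma::vec lik_win1 = 1.0 - x_grid;  // P(type-1 rewarded | X = x)

  arma::cube J1(nx, nv, nk);
  for (int t = 0; t < n; ++t) {
    B[t] = ex;
    if (!responded[t]) continue;
    // propagate V given K, then X given V
    for (int k = 0; k < nk; ++k) {
      J1.slice(k) = J.slice(k) * Vker.slice(k).t();
      for (int v = 0; v < nv; ++v)
        J.slice(k).col(v) = Xker.slice(v) * J1.slice(k).col(v);
    }
    // incorporate the observed rewarded type and renormalize
    const arma::vec &lik = (rewarded[t] == 2) ? lik_win2 : lik_win1;
    for (int k = 0; k < nk; ++k)
      J.slice(k).each_col() %= lik;
    double z = arma::accu(J);
    if (z <= 0.0) stop("zero normalizer in volatility filter");
    J /= z;
    // posterior mean of the X marginal
    arma::vec xm(nx, arma::fill::zeros);
    for (int k = 0; k < nk; ++k)
      xm += arma::sum(J.slice(k), 1);
    ex = arma::dot(x_grid, xm);
  }
  return B;
}
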