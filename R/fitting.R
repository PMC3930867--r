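#' Per-trial belief trajectory of a model on observed data
#'
#' Runs a model forward over a trial table, updating beliefs from the
#' outcomes of responded trials only (missed trials never update).  For the
#' coupled and Bayesian models the returned belief is the probability that
#' a type-1 response is rewarded, as used *on* each trial; for the
#' uncoupled learner it is the two displayed-color action values (a
#' two-column matrix).
#'
#' @inheritParams validate_params
#' @param trials trial data.frame in the schedule dialect, with
#'   `rewarded_type`, `response_type`, `feedback` (and `color` for UNC)
#'   filled.
#' @param kernels volatility-filter kernels (VOL only).
#' @return numeric vector (coupled/Bayes) or n x 2 matrix (UNC).
#' @export
belief_trajectory <- function(model, params, trials,
                              kernels = .default_vol_kernels()) {
  model <- match.arg(model, model_ids())
  params <- validate_params(model, params)
  responded <- !is.na(trials$feedback) & trials$feedback != "missed"
  switch(model,
    RL = cpp_rl_belief(params[["alpha"]], trials$rewarded_type, responded),
    WL = cpp_wl_belief(params[["alpha_win"]], params[["alpha_loss"]],
                       trials$rewarded_type,
                       .feedback_code(trials$feedback)),
    HMM = cpp_hmm_filter(params[["p_switch"]], params[["p_error"]],
                         trials$rewarded_type, responded)$belief,
    VOL = 1 - vol_filter(trials$rewarded_type, responded, kernels),
    UNC = cpp_unc_belief(params[["alpha"]],
                         ifelse(trials$color == "red", 1L, 2L),
                         .unc_button(trials),
                         .feedback_code(trials$feedback))
  )
}

.feedback_code <- function(feedback) {
  ifelse(is.na(feedback) | feedback == "missed", -1L,
         ifelse(feedback == "win", 1L, 0L))
}

# button pressed given color and response type (type 1 = button 1 on red)
.unc_button <- function(trials) {
  b <- ifelse(trials$color == "red", trials$response_type,
              3L - trials$response_type)
  ifelse(is.na(b), 0L, as.integer(b))
}

#' Log-likelihood of a response sequence under a model
#'
#' Runs the model forward over the trials and returns the sum of natural-log
#' softmax probabilities of the responses actually taken.  Missed trials
#' contribute nothing to the sum and do not update beliefs, but the
#' after-loss temperature applies to the following trial.
#'
#' @inheritParams belief_trajectory
#' @return the log-likelihood (a non-positive number).
#' @export
sequence_loglik <- function(model, params, trials,
                            kernels = .default_vol_kernels()) {
  model <- match.arg(model, model_ids())
  params <- validate_params(model, params)
  responded <- !is.na(trials$feedback) & trials$feedback != "missed"
  if (nrow(trials) == 0 || !any(responded)) {
    stop("no responded trials to fit", call. = FALSE)
  }
  B <- belief_trajectory(model, params, trials, kernels)
  sum(.response_loglik_terms(model, params, trials, B)[responded])
}

# per-trial log choice probabilities given a belief trajectory; belief is
# parameter-free for VOL, so fitting reuses a cached trajectory
.response_loglik_terms <- function(model, params, trials, B) {
  temps <- select_temperature(model, params, .prev_feedback(trials$feedback))
  if (model == "UNC") {
    d <- (B[, 1] - B[, 2]) / temps
    .log_choice_prob(d, .unc_button(trials) == 1L)
  } else {
    d <- (2 * B - 1) / temps
    .log_choice_prob(d, trials$response_type == 1L)
  }
}

#' Maximum-likelihood fit of one model to one participant
#'
#' Bounded multi-start maximum-likelihood estimation: `n_starts` starting
#' points are drawn uniformly over the parameter box (learning rates in
#' \[0.0001, 1\], switch/error probabilities in \[0.00001, 0.5\],
#' temperatures in \[0.01, `t_max`\]) and each is refined with L-BFGS-B;
#' the best local optimum is returned.  The temperature cap `t_max` is a
#' search setting: beyond it the likelihood is flat in `T` (responding is
#' effectively random).  For the VOL model the belief trajectory is
#' parameter-free and computed once; only the temperatures are optimized.
#'
#' @inheritParams belief_trajectory
#' @param n_starts number of seeded random starting points.
#' @param seed integer seed making the fit reproducible.
#' @param t_max temperature upper search bound.
#' @return object of class `revlearn_fit`: a list with `model`, `params`
#'   (named fitted values), `log_likelihood`, `n_responded`, `bic`, `k`,
#'   and `n_starts_converged`.
#' @export
fit_participant <- function(model, trials, n_starts = 10, seed = 1,
                            t_max = 20, kernels = .default_vol_kernels()) {
  model <- match.arg(model, model_ids())
  responded <- !is.na(trials$feedback) & trials$feedback != "missed"
  if (nrow(trials) == 0 || !any(responded)) {
    stop("no responded trials to fit", call. = FALSE)
  }
  b <- model_bounds(model, t_max = t_max)
  nm <- model_param_names(model)
  np <- length(nm)

  vol_B <- if (model == "VOL") {
    1 - vol_filter(trials$rewarded_type, responded, kernels)
  } else NULL

  negll <- function(par) {
    names(par) <- nm
    B <- if (model == "VOL") vol_B
         else belief_trajectory(model, par, trials, kernels)
    ll <- sum(.response_loglik_terms(model, par, trials, B)[responded])
    if (!is.finite(ll)) 1e10 else -ll
  }

  set.seed(seed)
  starts <- matrix(runif(n_starts * np, rep(b$lower, each = n_starts),
                         rep(b$upper, each = n_starts)),
                   nrow = n_starts)
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = 300,
                           parscale = b$upper - b$lower)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop(sprintf("optimizer failed on all %d starts for model %s",
                 n_starts, model), call. = FALSE)
  }
  params <- setNames(best$par, nm)
  n_resp <- sum(responded)
  ll <- -best$value
  structure(list(
    model = model,
    params = params,
    log_likelihood = ll,
    n_responded = n_resp,
    k = model_k(model),
    bic = bic(ll, model_k(model), n_resp),
    n_starts = n_starts,
    n_starts_converged = n_conv,
    seed = seed
  ), class = "revlearn_fit")
}

#' @export
print.revlearn_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.2f over %d responded trials (BIC = %.2f)\n",
              x$model, x$log_likelihood, x$n_responded, x$bic))
  print(round(x$params, 4))
  invisible(x)
}
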