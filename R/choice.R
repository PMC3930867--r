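#' Softmax choice probabilities
#'
#' For the coupled and Bayesian models the belief `B` is the probability
#' that a type-1 response is rewarded, the alternative's value is `1 - B`,
#' and the probability of responding type 1 is
#' `exp(B/T) / (exp(B/T) + exp((1-B)/T))`, i.e. `plogis((2B - 1)/T)`.
#' For the uncoupled learner the two displayed-color action values enter
#' the softmax directly (they are not complementary).  The temperature `T`
#' sets the randomization: low `T` approaches greedy choice, high `T`
#' approaches a fair coin.
#'
#' @param B belief in \[0, 1\] that a type-1 response is rewarded.
#' @param Q1,Q2 action values in \[0, 1\] for buttons 1 and 2 given the
#'   displayed color.
#' @param T softmax temperature, `>= 0.01` (the fitting lower bound).
#' @return probability of a type-1 response (`softmax_prob`) or of pressing
#'   button 1 (`unc_softmax_prob`); vectorized over beliefs.
#' @export
softmax_prob <- function(B, T) {
  .check_temp(T)
  stopifnot(all(B >= 0 & B <= 1))
  plogis((2 * B - 1) / T)
}

#' @rdname softmax_prob
#' @export
unc_softmax_prob <- function(Q1, Q2, T) {
  .check_temp(T)
  stopifnot(all(Q1 >= 0 & Q1 <= 1), all(Q2 >= 0 & Q2 <= 1))
  plogis((Q1 - Q2) / T)
}

.check_temp <- function(T) {
  if (any(T < 0.01)) {
    stop("temperature must be >= 0.01", call. = FALSE)
  }
  invisible(T)
}

#' Outcome-dependent temperature selection
#'
#' Models with a temperature pair (WL, HMM, VOL) use `T_win` after a win
#' and `T_loss` after a loss; a missed previous trial counts as a loss.
#' On trial 1 (`prev_feedback == "none"`) `T_win` is used -- with symmetric
#' initial beliefs the choice probability is 0.5 under either temperature,
#' so the convention is inconsequential.  Single-temperature models (RL,
#' UNC) always use `T`.
#'
#' @inheritParams validate_params
#' @param prev_feedback previous trial's feedback: `"win"`, `"loss"`,
#'   `"missed"`, or `"none"` for trial 1; vectorized.
#' @return numeric vector of temperatures, one per element of
#'   `prev_feedback`.
#' @export
select_temperature <- function(model, params, prev_feedback) {
  model <- match.arg(model, model_ids())
  bad <- !prev_feedback %in% c("win", "loss", "missed", "none")
  if (any(bad)) stop("unknown previous feedback value", call. = FALSE)
  if (model %in% c("RL", "UNC")) {
    return(rep(params[["T"]], length(prev_feedback)))
  }
  ifelse(prev_feedback %in% c("loss", "missed"),
         params[["T_loss"]], params[["T_win"]])
}

# log choice probability of the response taken, numerically stable at
# extreme belief/temperature combinations
.log_choice_prob <- function(d, took_first) {
  plogis(ifelse(took_first, d, -d), log.p = TRUE)
}
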