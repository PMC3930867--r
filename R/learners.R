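#' Delta-rule update
#'
#' The Rescorla-Wagner update `Q + alpha * (R - Q)`: the prediction error
#' `R - Q` moves the predicted value toward the realized reward, weighted by
#' the learning rate.  With rewards coded 0/1 the predicted value stays in
#' \[0, 1\].
#'
#' @param Q predicted value in \[0, 1\].
#' @param R realized reward, 0 or 1.
#' @param alpha learning rate in \[0, 1\].
#' @return the updated predicted value.
#' @export
delta_update <- function(Q, R, alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    stop("learning rate must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(Q >= 0 & Q <= 1), all(R %in% c(0, 1)))
  Q + alpha * (R - Q)
}

#' Coupled learner steps
#'
#' `rl_step()` advances the standard coupled learner: `Q1`, the predicted
#' value of a type-1 response, is updated from the revealed rewarded type
#' with `R = 1` if type 1 won and 0 otherwise.  Because outcomes are coupled
#' (`Q2 = 1 - Q1`), feedback is fully informative whichever response was
#' made.  `wl_step()` is identical except that the learning rate is
#' `alpha_win` when the responder's own feedback on the trial was a win and
#' `alpha_loss` on a loss.  On a missed trial (`rewarded_type` `NA` or
#' `feedback == "missed"`) the belief is returned unchanged.
#'
#' @param Q1 belief in \[0, 1\] (initially 0.5).
#' @param rewarded_type 1 or 2; `NA` for a missed trial.
#' @param alpha,alpha_win,alpha_loss learning rates in \[0, 1\].
#' @param feedback the responder's own outcome, `"win"`, `"loss"` or
#'   `"missed"`.
#' @return the updated `Q1`.
#' @export
rl_step <- function(Q1, rewarded_type, alpha) {
  if (is.na(rewarded_type)) return(Q1)
  stopifnot(rewarded_type %in% c(1L, 2L))
  delta_update(Q1, as.numeric(rewarded_type == 1L), alpha)
}

#' @rdname rl_step
#' @export
wl_step <- function(Q1, rewarded_type, feedback, alpha_win, alpha_loss) {
  if (is.na(rewarded_type) || identical(feedback, "missed")) return(Q1)
  stopifnot(feedback %in% c("win", "loss"))
  a <- if (feedback == "win") alpha_win else alpha_loss
  rl_step(Q1, rewarded_type, a)
}

#' Uncoupled learner belief and step
#'
#' The uncoupled learner keeps four independent action values, one per
#' (color, button) cell, each starting at the unbiased prior 0.5.  Only the
#' cell experienced on a trial is updated, with `R = 1` on a win and 0 on a
#' loss; the other three values are carried forward without forgetting.
#'
#' @param Q 2 x 2 belief matrix (rows `red`, `blue`; columns buttons 1, 2).
#' @param color `"red"` or `"blue"`.
#' @param button 1 or 2; `NA` for a missed trial.
#' @param feedback `"win"`, `"loss"` or `"missed"`.
#' @param alpha learning rate in \[0, 1\].
#' @return `init_unc_belief()` the initial matrix; `unc_step()` the updated
#'   matrix.
#' @export
init_unc_belief <- function() {
  matrix(0.5, 2, 2, dimnames = list(c("red", "blue"), c("1", "2")))
}

#' @rdname init_unc_belief
#' @export
unc_step <- function(Q, color, button, feedback, alpha) {
  if (is.na(button) || identical(feedback, "missed")) return(Q)
  stopifnot(color %in% c("red", "blue"), button %in% c(1L, 2L),
            feedback %in% c("win", "loss"))
  Q[color, button] <- delta_update(Q[color, button],
                                   as.numeric(feedback == "win"), alpha)
  Q
}
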