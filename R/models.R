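#' Model registry
#'
#' Five trial-by-trial learning models are supported:
#' \describe{
#'   \item{`"UNC"`}{uncoupled delta-rule learner: four independent action
#'     values, one per (color, button) cell; parameters `alpha`, `T`.}
#'   \item{`"RL"`}{standard coupled delta-rule learner on response types;
#'     parameters `alpha`, `T`.}
#'   \item{`"WL"`}{win/loss-split coupled learner with separate learning
#'     rates and temperatures after rewards and punishments; parameters
#'     `alpha_win`, `alpha_loss`, `T_win`, `T_loss`.}
#'   \item{`"HMM"`}{two-state hidden Markov forward filter; parameters
#'     `p_switch`, `p_error`, `T_win`, `T_loss`.}
#'   \item{`"VOL"`}{hierarchical volatility filter over a discretized
#'     reward-probability/volatility grid; the filter itself has no fitted
#'     parameters, only the temperatures `T_win`, `T_loss`.}
#' }
#'
#' @return `model_ids()` returns the character vector of model identifiers;
#'   `model_param_names()` the free-parameter names of one model;
#'   `model_k()` its free-parameter count; `model_bounds()` a list with
#'   numeric vectors `lower` and `upper` (the fitting box).
#' @param model one of `model_ids()`.
#' @param t_max upper search bound for softmax temperatures.  The model
#'   itself only bounds temperatures below (at 0.01); an upper cap keeps the
#'   optimizer out of the flat random-responding regime.
#' @export
model_ids <- function() c("UNC", "RL", "WL", "HMM", "VOL")

# canonical order used to break best-model ties deterministically
.model_order <- c("RL", "WL", "HMM", "VOL", "UNC")

#' @rdname model_ids
#' @export
model_param_names <- function(model) {
  switch(match.arg(model, model_ids()),
    UNC = c("alpha", "T"),
    RL  = c("alpha", "T"),
    WL  = c("alpha_win", "alpha_loss", "T_win", "T_loss"),
    HMM = c("p_switch", "p_error", "T_win", "T_loss"),
    VOL = c("T_win", "T_loss")
  )
}

#' @rdname model_ids
#' @export
model_k <- function(model) length(model_param_names(model))

#' @rdname model_ids
#' @export
model_bounds <- function(model, t_max = 20) {
  model <- match.arg(model, model_ids())
  nm <- model_param_names(model)
  lower <- vapply(nm, function(p) switch(p,
    alpha = 1e-4, alpha_win = 1e-4, alpha_loss = 1e-4,
    p_switch = 1e-5, p_error = 1e-5,
    T = 0.01, T_win = 0.01, T_loss = 0.01
  ), numeric(1))
  upper <- vapply(nm, function(p) switch(p,
    alpha = 1, alpha_win = 1, alpha_loss = 1,
    p_switch = 0.5, p_error = 0.5,
    T = t_max, T_win = t_max, T_loss = t_max
  ), numeric(1))
  list(lower = lower, upper = upper)
}

#' Validate a parameter vector for a model
#'
#' Checks names and the fitting bounds (learning rates in \[0.0001, 1\],
#' switch/error probabilities in \[0.00001, 0.5\], temperatures >= 0.01).
#' Temperatures are not checked against the search cap: the cap is an
#' optimizer setting, not part of the model.
#'
#' @inheritParams model_ids
#' @param params named numeric vector with entries `model_param_names(model)`.
#' @return the parameter vector, reordered canonically, invisibly usable.
#' @export
validate_params <- function(model, params) {
  model <- match.arg(model, model_ids())
  nm <- model_param_names(model)
  if (is.list(params)) params <- unlist(params)
  if (is.null(names(params)) && length(params) == length(nm)) {
    names(params) <- nm
  }
  missing <- setdiff(nm, names(params))
  if (length(missing) > 0) {
    stop(sprintf("missing %s parameter(s): %s", model,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- params[nm]
  b <- model_bounds(model, t_max = Inf)
  bad <- params < b$lower | params > b$upper | !is.finite(params)
  if (any(bad)) {
    stop(sprintf("%s parameter(s) out of bounds: %s", model,
                 paste(nm[bad], collapse = ", ")), call. = FALSE)
  }
  params
}

# previous-trial feedback labels for a trial sequence ("none" on trial 1)
.prev_feedback <- function(feedback) {
  n <- length(feedback)
  if (n == 0) return(character(0))
  c("none", feedback[-n])
}
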