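#' Default "typical participant" generating parameter sets
#'
#' Generator values for the recovery experiments: the WL set is the cohort
#' mean of the fitted parameters, the RL and HMM sets are plausible
#' mid-range values, `HMM_degenerate` is the near-uninformative set
#' (`p_error = 0.49`, `p_switch = 0.35`) whose behavior collapses onto a
#' biased coin and is mimicked by RL, and VOL carries only temperatures.
#'
#' @return named list; each element has `model` and `params`.
#' @export
default_generators <- function() {
  list(
    RL = list(model = "RL", params = c(alpha = 0.6, T = 0.5)),
    WL = list(model = "WL", params = c(alpha_win = 0.77, alpha_loss = 0.52,
                                       T_win = 0.35, T_loss = 0.87)),
    HMM = list(model = "HMM", params = c(p_switch = 0.021, p_error = 0.2,
                                         T_win = 0.35, T_loss = 0.87)),
    VOL = list(model = "VOL", params = c(T_win = 0.35, T_loss = 0.87)),
    HMM_degenerate = list(model = "HMM",
                          params = c(p_switch = 0.35, p_error = 0.49,
                                     T_win = 0.35, T_loss = 0.87))
  )
}

#' Parameter recovery experiment
#'
#' Simulates responders with known parameters on synthetic schedules, refits
#' the same model, and tabulates generating against recovered values.  Two
#' simulated response sets per generator set and schedule is the
#' experiment's convention (`n_reps = 2`).
#'
#' @inheritParams fit_participant
#' @param gen_param_sets a named parameter vector or a list of them.
#' @param schedules a schedule or list of schedules from
#'   [generate_schedule()].
#' @param n_reps simulated response sets per parameter set and schedule.
#' @param seed master seed; all simulation and fitting seeds derive from it.
#' @param miss_rate miss probability passed to [simulate_agent()].
#' @return object of class `revlearn_recovery`: list with `results` (long
#'   data.frame: `set`, `schedule`, `rep`, `parameter`, `true`,
#'   `recovered`) and `fits`.
#' @export
parameter_recovery <- function(model, gen_param_sets, schedules,
                               n_reps = 2, seed = 1, n_starts = 10,
                               miss_rate = 0, t_max = 20) {
  model <- match.arg(model, model_ids())
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.list(gen_param_sets)) gen_param_sets <- list(gen_param_sets)
  if (is.data.frame(schedules)) schedules <- list(schedules)
  set.seed(seed)
  n_runs <- length(gen_param_sets) * length(schedules) * n_reps
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n_runs),
                  ncol = 2)
  rows <- list(); fits <- list(); run <- 0L
  for (i in seq_along(gen_param_sets)) {
    true <- validate_params(model, gen_param_sets[[i]])
    for (s in seq_along(schedules)) {
      for (r in seq_len(n_reps)) {
        run <- run + 1L
        sim <- simulate_agent(model, true, schedules[[s]],
                              seed = seeds[run, 1], miss_rate = miss_rate)
        fit <- fit_participant(model, sim, n_starts = n_starts,
                               seed = seeds[run, 2], t_max = t_max)
        fits[[run]] <- fit
        rows[[run]] <- data.frame(
          set = i, schedule = s, rep = r,
          parameter = names(true), true = unname(true),
          recovered = unname(fit$params),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(model = model, results = do.call(rbind, rows),
                 fits = fits, seed = seed),
            class = "revlearn_recovery")
}

#' Model recovery experiment
#'
#' Simulates data from each generator, fits every candidate model, selects
#' the best by BIC (ties toward fewer parameters), and tabulates the
#' percentage of simulations per generator won by each candidate -- the
#' model-confusion matrix.  Rows sum to 100.
#'
#' @inheritParams parameter_recovery
#' @param generators named list as from [default_generators()].
#' @param fit_models candidate model ids fitted to every simulation.
#' @return object of class `revlearn_recovery`: list with `confusion`
#'   (percentage matrix, generators x fitted models) and `details` (one row
#'   per simulation with per-model BICs and the winner).
#' @export
model_recovery <- function(generators = default_generators(),
                           fit_models = c("RL", "WL", "HMM", "VOL"),
                           schedules, n_reps = 10, seed = 1,
                           n_starts = 10, miss_rate = 0, t_max = 20) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  fit_models <- match.arg(fit_models, model_ids(), several.ok = TRUE)
  if (is.data.frame(schedules)) schedules <- list(schedules)
  set.seed(seed)
  n_runs <- length(generators) * n_reps
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             n_runs * (1 + length(fit_models))),
                  nrow = n_runs)
  details <- list(); run <- 0L
  for (g in names(generators)) {
    gen <- generators[[g]]
    for (r in seq_len(n_reps)) {
      run <- run + 1L
      sched <- schedules[[(run - 1L) %% length(schedules) + 1L]]
      sim <- simulate_agent(gen$model, gen$params, sched,
                            seed = seeds[run, 1], miss_rate = miss_rate)
      bics <- ks <- setNames(numeric(length(fit_models)), fit_models)
      for (j in seq_along(fit_models)) {
        fit <- fit_participant(fit_models[j], sim, n_starts = n_starts,
                               seed = seeds[run, 1 + j], t_max = t_max)
        bics[j] <- fit$bic
        ks[j] <- fit$k
      }
      ord <- order(bics, ks, match(fit_models, .model_order))
      row <- data.frame(generator = g, rep = r, best = fit_models[ord[1]],
                        stringsAsFactors = FALSE)
      for (m in fit_models) row[[paste0("bic_", m)]] <- bics[[m]]
      details[[run]] <- row
    }
  }
  details <- do.call(rbind, details)
  confusion <- 100 * prop.table(
    table(factor(details$generator, levels = names(generators)),
          factor(details$best, levels = fit_models)), 1)
  structure(list(confusion = confusion, details = details, seed = seed),
            class = "revlearn_recovery")
}
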