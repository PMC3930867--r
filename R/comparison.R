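#' Bayesian Information Criterion
#'
#' `BIC = -2 logL + k log N` with natural logarithms; lower is better.  `N`
#' is the number of responded trials (missed trials are excluded from the
#' likelihood, so they do not count as data points).
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of responded trials; must be >= 1.
#' @return the BIC value.
#' @export
bic <- function(log_likelihood, k, n) {
  if (any(n < 1)) stop("BIC requires n >= 1", call. = FALSE)
  -2 * log_likelihood + k * log(n)
}

#' Bayes factor from a BIC difference
#'
#' `exp((BIC_a - BIC_b) / 2)`, the evidence in favor of model `b` over
#' model `a` from the same participant's data.  Values above 10 are
#' conventionally read as strong evidence, 3-10 as moderate.
#'
#' @param bic_a,bic_b BIC values of the two models on the same data.
#' @return the Bayes factor favoring model `b`.
#' @export
bayes_factor_from_bic <- function(bic_a, bic_b) {
  exp((bic_a - bic_b) / 2)
}

#' Cohort-level model comparison
#'
#' Takes a long table of per-participant, per-model fits, computes BIC for
#' every row, and summarizes: mean and summed BIC per model, each
#' participant's best model (ties broken toward fewer parameters, then by
#' the canonical model order), best-model counts, paired two-sided t tests
#' on per-participant BIC differences between a reference model and every
#' other model, and per-participant Bayes factors between a chosen pair.
#'
#' @param fits data.frame with columns `participant`, `model`,
#'   `log_likelihood`, `n_responded`, and optionally `k` (defaults to
#'   [model_k()] of the model id).  Every participant must be fitted under
#'   every model.
#' @param reference model id used in the t tests; defaults to the model
#'   with the lowest mean BIC.
#' @param bf_pair length-2 character vector `c(a, b)`: Bayes factors
#'   favoring `b` over `a` are reported per participant.  Defaults to
#'   `c("HMM", "WL")` when both are present.
#' @return list with `table` (the input plus `bic`), `mean_bic`, `sum_bic`,
#'   `best` (per-participant best model), `best_counts`, `t_tests`, and
#'   `bayes_factors`.
#' @export
compare_models <- function(fits, reference = NULL, bf_pair = NULL) {
  stopifnot(all(c("participant", "model", "log_likelihood",
                  "n_responded") %in% names(fits)))
  if (is.null(fits$k)) {
    fits$k <- vapply(fits$model, model_k, numeric(1))
  }
  combos <- table(fits$participant, fits$model)
  if (any(combos != 1)) {
    gaps <- which(combos != 1, arr.ind = TRUE)
    stop("missing or duplicated fits: ",
         paste(sprintf("%s x %s", rownames(combos)[gaps[, 1]],
                       colnames(combos)[gaps[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  fits$bic <- bic(fits$log_likelihood, fits$k, fits$n_responded)
  models <- intersect(.model_order, unique(fits$model))
  models <- c(models, setdiff(unique(fits$model), models))

  mean_bic <- vapply(models, function(m) mean(fits$bic[fits$model == m]),
                     numeric(1))
  sum_bic <- vapply(models, function(m) sum(fits$bic[fits$model == m]),
                    numeric(1))

  # per-participant best model: lowest BIC, ties toward fewer parameters
  best <- do.call(rbind, lapply(split(fits, fits$participant), function(d) {
    d <- d[order(d$bic, d$k, match(d$model, models)), , drop = FALSE]
    data.frame(participant = d$participant[1], best_model = d$model[1],
               bic = d$bic[1], stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  best_counts <- table(factor(best$best_model, levels = models))

  if (is.null(reference)) reference <- models[which.min(mean_bic)]
  t_tests <- NULL
  if (length(models) < 2) {
    warning("only one model supplied; no t tests computed")
  } else {
    wide <- do.call(cbind, lapply(models, function(m) {
      d <- fits[fits$model == m, ]
      d$bic[order(d$participant)]
    }))
    colnames(wide) <- models
    others <- setdiff(models, reference)
    t_tests <- do.call(rbind, lapply(others, function(m) {
      diffs <- wide[, m] - wide[, reference]
      if (nrow(wide) < 2 || stats::sd(diffs) == 0) {
        data.frame(reference = reference, model = m,
                   mean_diff = mean(diffs), t = 0, df = nrow(wide) - 1,
                   p = 1, stringsAsFactors = FALSE)
      } else {
        tt <- t.test(diffs)
        data.frame(reference = reference, model = m,
                   mean_diff = mean(diffs),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, stringsAsFactors = FALSE)
      }
    }))
  }

  if (is.null(bf_pair) && all(c("HMM", "WL") %in% models)) {
    bf_pair <- c("HMM", "WL")
  }
  bayes_factors <- NULL
  if (!is.null(bf_pair) && all(bf_pair %in% models)) {
    a <- fits[fits$model == bf_pair[1], ]
    b <- fits[fits$model == bf_pair[2], ]
    a <- a[order(a$participant), ]
    b <- b[order(b$participant), ]
    bayes_factors <- data.frame(
      participant = a$participant,
      favoring = bf_pair[2], over = bf_pair[1],
      bf = bayes_factor_from_bic(a$bic, b$bic),
      stringsAsFactors = FALSE
    )
  }

  list(table = fits, mean_bic = mean_bic, sum_bic = sum_bic, best = best,
       best_counts = best_counts, reference = reference, t_tests = t_tests,
       bayes_factors = bayes_factors)
}
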