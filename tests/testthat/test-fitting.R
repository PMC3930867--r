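test_that("a single symmetric-prior trial always has log-likelihood ln(0.5)", {
  tr <- make_trials(1L, 1L)
  for (m in model_ids()) {
    p <- switch(m,
      UNC = c(alpha = 0.3, T = 0.4), RL = c(alpha = 0.3, T = 0.4),
      WL = wl_mean_params,
      HMM = c(p_switch = 0.1, p_error = 0.2, T_win = 0.3, T_loss = 0.6),
      VOL = c(T_win = 0.3, T_loss = 0.6))
    expect_equal(sequence_loglik(m, p, tr), log(0.5), tolerance = 1e-9)
  }
})

test_that("WL nests RL exactly in the likelihood", {
  s <- generate_schedule(3)
  sim <- simulate_agent("WL", wl_mean_params, s, seed = 6, miss_rate = 0.03)
  ll_rl <- sequence_loglik("RL", c(alpha = 0.37, T = 0.55), sim)
  ll_wl <- sequence_loglik("WL", c(alpha_win = 0.37, alpha_loss = 0.37,
                                   T_win = 0.55, T_loss = 0.55), sim)
  expect_identical(ll_rl, ll_wl)
})

test_that("HMM response likelihood matches the path-sum oracle's conditionals", {
  set.seed(5)
  y <- sample(1:2, 8, replace = TRUE)
  resp <- sample(1:2, 8, replace = TRUE)
  tr <- make_trials(y, resp)
  params <- c(p_switch = 0.1, p_error = 0.2, T_win = 0.4, T_loss = 0.9)
  # predictive belief on trial t from prefix marginal-likelihood ratios
  B <- 0.5
  for (t in 2:8) {
    lp_prefix <- hmm_path_sum_loglik(y[1:(t - 1)], params)
    lp_with1 <- hmm_path_sum_loglik(c(y[1:(t - 1)], 1L), params)
    B <- c(B, exp(lp_with1 - lp_prefix))
  }
  temps <- select_temperature("HMM", params, c("none", tr$feedback[-8]))
  p1 <- softmax_prob(B, temps)
  ll_oracle <- sum(log(ifelse(resp == 1, p1, 1 - p1)))
  expect_equal(sequence_loglik("HMM", params, tr), ll_oracle, tolerance = 1e-10)
})

test_that("missed trials freeze beliefs, switch to the loss temperature, and drop out", {
  rewarded <- c(1L, 1L, 2L, 1L, 2L, 1L)
  response <- c(1L, NA, 2L, 1L, NA, 2L)
  tr <- make_trials(rewarded, response)
  p <- c(alpha_win = 0.6, alpha_loss = 0.3, T_win = 0.4, T_loss = 0.8)
  # independent reference computation with scalar steps
  q <- 0.5; prev <- "none"; ll <- 0
  for (t in 1:6) {
    temp <- if (prev %in% c("loss", "missed")) 0.8 else 0.4
    if (!is.na(response[t])) {
      pr1 <- softmax_prob(q, temp)
      ll <- ll + log(if (response[t] == 1) pr1 else 1 - pr1)
      fb <- if (response[t] == rewarded[t]) "win" else "loss"
      q <- wl_step(q, rewarded[t], fb, 0.6, 0.3)
      prev <- fb
    } else {
      prev <- "missed"
    }
  }
  expect_equal(sequence_loglik("WL", p, tr), ll, tolerance = 1e-12)
  expect_identical(sum(!is.na(response)), 4L)
})

test_that("degenerate inputs are rejected", {
  tr <- make_trials(c(1L, 2L), c(NA, NA))
  expect_error(sequence_loglik("RL", c(alpha = 0.3, T = 0.4), tr), "responded")
  expect_error(fit_participant("RL", tr), "responded")
  expect_error(sequence_loglik("RL", c(alpha = 2, T = 0.4), make_trials(1L, 1L)),
               "bounds")
  expect_error(sequence_loglik("RL", c(alpha = 0.3), make_trials(1L, 1L)),
               "missing")
})

test_that("fitting recovers at least the generating likelihood and is reproducible", {
  s <- generate_schedule(5)
  gen <- c(alpha_win = 0.6, alpha_loss = 0.3, T_win = 0.3, T_loss = 0.7)
  sim <- simulate_agent("WL", gen, s, seed = 101)
  f1 <- fit_participant("WL", sim, n_starts = 5, seed = 3)
  f2 <- fit_participant("WL", sim, n_starts = 5, seed = 3)
  expect_identical(f1[names(f1) != "seed"], f2[names(f2) != "seed"])
  expect_gte(f1$log_likelihood, sequence_loglik("WL", gen, sim) - 1e-6)
  expect_identical(f1$n_responded, 960L)
  expect_lte(f1$log_likelihood, 0)
  # nested models: best WL likelihood can never fall below best RL
  f_rl <- fit_participant("RL", sim, n_starts = 5, seed = 3)
  expect_gte(f1$log_likelihood, f_rl$log_likelihood - 1e-6)
})

test_that("a purely random responder fits a large temperature and coin-flip likelihood", {
  s <- generate_schedule(6)
  sim <- simulate_agent("RL", c(alpha = 0.5, T = 19), s, seed = 8)
  f <- fit_participant("RL", sim, n_starts = 5, seed = 2)
  expect_gt(f$params[["T"]], 2)
  expect_equal(f$log_likelihood, 960 * log(0.5), tolerance = 0.01 * 960 * log(2))
})
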