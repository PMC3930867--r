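test_that("R and C++ greedy engines agree exactly", {
  s <- generate_schedule(12)
  cases <- list(
    list(model = "RL", params = c(alpha = 0.2, T = 1)),
    list(model = "WL", params = c(alpha_win = 0.48, alpha_loss = 0.24,
                                  T_win = 1, T_loss = 1)),
    list(model = "HMM", params = c(p_switch = 0.021, p_error = 0.2,
                                   T_win = 1, T_loss = 1))
  )
  for (cs in cases) {
    w_cpp <- ideal_run(cs$model, cs$params, s, seed = 3, engine = "cpp")
    w_r <- ideal_run(cs$model, cs$params, s, seed = 3, engine = "R")
    expect_identical(as.integer(w_cpp), as.integer(w_r))
  }
  # VOL on a short block (the R reference loop is slow)
  short <- generate_schedule(4, blocks = data.frame(
    rule_start = 1L, fv = 25 / 30, volatile = TRUE, n_trials = 60L),
    strict = FALSE)
  expect_identical(as.integer(ideal_run("VOL", NULL, short, seed = 2)),
                   as.integer(ideal_run("VOL", NULL, short, seed = 2,
                                        engine = "R")))
})

test_that("perfect feedback validity yields near-perfect greedy harvest", {
  s <- fv1_schedule(6)
  wins <- ideal_run("RL", c(alpha = 0.5, T = 1), s, seed = 1)
  expect_gte(wins, nrow(s) - 1L)  # at most the first (tie) trial lost
})

test_that("greedy choice beats softmax responding with the same beliefs", {
  set.seed(40)
  seeds <- sample.int(1e6, 10)
  p <- c(alpha = 0.2, T = 1)
  diff <- sapply(seeds, function(sd) {
    s <- generate_schedule(sd)
    greedy <- ideal_run("RL", p, s, seed = sd)
    soft <- sum(simulate_agent("RL", p, s, seed = sd)$feedback == "win")
    greedy - soft
  })
  expect_gt(mean(diff), 0)
})

test_that("grid search returns the literal argmax with grid edge cases", {
  scheds <- lapply(1:3, generate_schedule)
  gs <- grid_search_ideal("RL", scheds, grid = list(alpha = c(0.1, 0.2, 0.5)),
                          seed = 2)
  expect_identical(nrow(gs$surface), 3L)
  expect_identical(unname(gs$best_params),
                   gs$surface$alpha[which.max(gs$surface$mean_wins)])
  expect_equal(gs$best_mean_wins, max(gs$surface$mean_wins))
  one <- grid_search_ideal("RL", scheds, grid = list(alpha = 0.3), seed = 2)
  expect_identical(unname(one$best_params), 0.3)
  expect_error(grid_search_ideal("RL", scheds, grid = list(alpha = numeric(0))),
               "empty")
  # reproducible surface
  gs2 <- grid_search_ideal("RL", scheds, grid = list(alpha = c(0.1, 0.2, 0.5)),
                           seed = 2)
  expect_identical(gs$surface, gs2$surface)
})

test_that("maximizing curves align post-switch segments and split by FV", {
  s <- generate_schedule(21)
  # rule-following responder: flat 100%
  s$response_type <- s$rule
  s$feedback <- ifelse(s$response_type == s$rewarded_type, "win", "loss")
  mc <- maximizing_curve(s)
  expect_true(all(mc$curve$pct == 100))
  expect_identical(sort(unique(mc$curve$fv)), sort(c(22 / 30, 25 / 30)))
  expect_equal(range(mc$curve$position), c(1, 30))
  expect_identical(nrow(mc$window), 2L)

  # uniform random responders sit near 50% everywhere
  set.seed(31)
  sims <- lapply(sample.int(1e6, 10), function(sd) {
    sch <- generate_schedule(sd)
    sch$response_type <- sample(1:2, nrow(sch), replace = TRUE)
    sch$feedback <- ifelse(sch$response_type == sch$rewarded_type,
                           "win", "loss")
    sch
  })
  mc <- maximizing_curve(sims)
  expect_true(all(abs(mc$window$pct - 50) < 5))

  stable_only <- s[!s$volatile, ]
  expect_error(maximizing_curve(stable_only), "volatile")
})
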