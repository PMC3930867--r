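test_that("schedules hit the per-segment reward proportions exactly, every seed", {
  for (seed in c(1, 7, 123)) {
    s <- generate_schedule(seed)
    seg <- split(s, interaction(s$block, s$segment, drop = TRUE))
    for (d in seg) {
      n_cons <- sum(d$rewarded_type == d$rule)
      expected <- round(d$fv[1] * nrow(d))
      expect_identical(n_cons, as.integer(expected))
      # 25/30 or 22/30 per volatile segment, 100/120 or 88/120 stable
      expect_true(n_cons %in% c(22L, 25L, 88L, 100L))
    }
  }
})

test_that("the strict design has 8 blocks, one per condition, with correct switches", {
  s <- generate_schedule(11)
  blocks <- attr(s, "blocks")
  expect_identical(nrow(blocks), 8L)
  expect_identical(nrow(unique(blocks[, c("rule_start", "fv", "volatile")])), 8L)
  expect_identical(nrow(s), 960L)
  for (b in unique(s$block)) {
    d <- s[s$block == b, ]
    switches <- sum(diff(d$rule) != 0)
    expect_identical(switches, if (d$volatile[1]) 3L else 0L)
    expect_identical(length(unique(d$segment)), if (d$volatile[1]) 4L else 1L)
  }
})

test_that("generation and simulation are byte-identical under a fixed seed", {
  s1 <- generate_schedule(42)
  s2 <- generate_schedule(42)
  expect_identical(s1, s2)
  a1 <- simulate_agent("WL", wl_mean_params, s1, seed = 5, miss_rate = 0.05)
  a2 <- simulate_agent("WL", wl_mean_params, s2, seed = 5, miss_rate = 0.05)
  expect_identical(a1, a2)
})

test_that("degenerate and invalid designs are handled", {
  expect_identical(unique(with(fv1_schedule(3), rewarded_type == rule)), TRUE)
  bad <- data.frame(rule_start = 1L, fv = 0.8, volatile = FALSE, n_trials = 45L)
  expect_error(generate_schedule(1, blocks = bad, strict = FALSE), "divisible")
  dup <- data.frame(rule_start = 1L, fv = 0.8, volatile = FALSE, n_trials = 120L)
  expect_error(generate_schedule(1, blocks = dup[c(1, 1), ]), "8 blocks")
  seven <- default_blocks()[1:7, ]
  expect_error(generate_schedule(1, blocks = seven), "8 blocks")
})

test_that("simulated responders obey the feedback and miss rules", {
  s <- generate_schedule(8)
  sim <- simulate_agent("WL", wl_mean_params, s, seed = 2)
  expect_false(any(sim$feedback == "missed"))
  resp <- !is.na(sim$response_type)
  expect_identical(sim$feedback[resp] == "win",
                   (sim$response_type == sim$rewarded_type)[resp])

  simm <- simulate_agent("RL", c(alpha = 0.4, T = 0.5), s, seed = 3,
                         miss_rate = 0.05)
  n_miss <- sum(simm$feedback == "missed")
  expect_true(n_miss > 10 && n_miss < 100)  # ~48 expected of 960
  expect_true(all(is.na(simm$response_type[simm$feedback == "missed"])))
  expect_error(simulate_agent("RL", c(alpha = 0.4, T = 0.5), s, miss_rate = 0.5),
               "miss_rate")
  expect_error(simulate_agent("RL", c(alpha = 1.4, T = 0.5), s), "bounds")
})

test_that("near-greedy WL on perfectly valid feedback locks onto the rule", {
  s <- fv1_schedule(4)
  sim <- simulate_agent("WL", c(alpha_win = 0.5, alpha_loss = 0.5,
                                T_win = 0.01, T_loss = 0.01), s, seed = 1)
  expect_true(all(sim$response_type[-1] == sim$rule[-1]))
})

test_that("relabeling types mirrors beliefs and preserves feedback (coupling symmetry)", {
  s <- generate_schedule(15)
  sim <- simulate_agent("WL", wl_mean_params, s, seed = 9)
  mir <- mirror_schedule(sim)
  expect_identical(sim$feedback, mir$feedback)
  for (m in c("RL", "WL")) {
    p <- if (m == "RL") c(alpha = 0.3, T = 0.5) else wl_mean_params
    b <- belief_trajectory(m, p, sim)
    bm <- belief_trajectory(m, p, mir)
    expect_equal(bm, 1 - b, tolerance = 1e-12)
  }
})
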