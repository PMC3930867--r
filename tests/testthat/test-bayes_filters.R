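test_that("one HMM forward step matches the hand-computed example", {
  st <- hmm_step(c(0.5, 0.5), 1L, c(p_switch = 0.021, p_error = 0.2))
  expect_equal(st$posterior, c(0.8, 0.2))
  # transition: (0.979*0.8 + 0.021*0.2, ...) = (0.7874, 0.2126)
  expect_equal(st$p_type1, 0.8 * 0.7874 + 0.2 * 0.2126, tolerance = 1e-12)
  expect_equal(st$p_type1, 0.672, tolerance = 1e-3)
})

test_that("degenerate HMM parameters behave as expected", {
  set.seed(2)
  y <- sample(1:2, 50, replace = TRUE)
  # uniform transition erases all information
  b <- hmm_filter(y, c(p_switch = 0.5, p_error = 0.2))$belief
  expect_equal(b, rep(0.5, 50), tolerance = 1e-12)
  # uninformative likelihood freezes the posterior
  post <- c(0.5, 0.5)
  for (t in 1:10) {
    st <- hmm_step(post, y[t], c(p_switch = 0.1, p_error = 0.5))
    post <- st$posterior
  }
  expect_equal(post, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(hmm_step(c(0.5, 0.5), 1L, c(p_switch = 0.6, p_error = 0.2)),
               "probabilities")
})

test_that("the forward filter equals the exhaustive path-sum oracle (<= 10 trials)", {
  set.seed(7)
  for (n in 1:10) {
    y <- sample(1:2, n, replace = TRUE)
    params <- c(p_switch = runif(1, 1e-5, 0.5), p_error = runif(1, 1e-5, 0.5))
    expect_equal(hmm_filter(y, params)$loglik,
                 hmm_path_sum_loglik(y, params), tolerance = 1e-10)
  }
  expect_error(hmm_path_sum_loglik(rep(1L, 13), c(p_switch = 0.1, p_error = 0.2)),
               "length")
})

test_that("with no switching the likelihood is a two-component Bernoulli mixture", {
  y <- c(1L, 1L, 2L, 1L, 1L, 1L, 2L, 1L)
  pe <- 0.2
  k <- sum(y == 1)
  mix <- 0.5 * (1 - pe)^k * pe^(8 - k) + 0.5 * pe^k * (1 - pe)^(8 - k)
  expect_equal(hmm_filter(y, c(p_switch = 0, p_error = pe))$loglik, log(mix),
               tolerance = 1e-12)
})

test_that("the near-uninformative HMM hugs 0.5 with a last-outcome tilt", {
  set.seed(12)
  y <- sample(1:2, 200, replace = TRUE)
  b <- hmm_filter(y, c(p_switch = 0.35, p_error = 0.49))$belief
  expect_true(all(abs(b - 0.5) < 0.05))
  tilt <- sign(b[-1] - 0.5)
  expect_true(all(tilt == ifelse(y[-length(y)] == 1, 1, -1)))
})

test_that("volatility kernels are normalized with variance increasing in v", {
  k <- vol_kernels(n_x = 21, n_v = 11, k_grid = c(0.01, 0.1, 0.3))
  expect_equal(colSums(k$Xker[, , 5]), rep(1, 21), tolerance = 1e-12)
  expect_equal(colSums(k$Vker[, , 2]), rep(1, 11), tolerance = 1e-12)
  mid <- (length(k$x_grid) + 1) / 2   # previous X = 0.5
  vars <- apply(k$Xker[, mid, ], 2, function(p) {
    sum(p * k$x_grid^2) - sum(p * k$x_grid)^2
  })
  expect_true(all(diff(vars) > 0))
  # lowest volatility: mass concentrated on the previous value
  expect_gt(k$Xker[mid, mid, 1], 0.95)
})

test_that("the joint stays a probability distribution and mirrors under relabeling", {
  k <- vol_kernels(n_x = 15, n_v = 9, k_grid = c(0.02, 0.2))
  set.seed(3)
  y <- sample(1:2, 12, replace = TRUE)
  st <- vol_init(k)
  for (t in seq_along(y)) {
    r <- vol_step(st, y[t], k)
    st <- r$state
    expect_equal(sum(st), 1, tolerance = 1e-12)
    expect_true(all(st >= 0))
  }
  b <- vol_filter(y, kernels = k)
  b_mir <- vol_filter(3L - y, kernels = k)
  expect_equal(b_mir, 1 - b, tolerance = 1e-10)
  expect_error(vol_step(st * 2, 1L, k), "normalized")
})

test_that("the R step function and the C++ filter agree", {
  k <- vol_kernels(n_x = 15, n_v = 9, k_grid = c(0.02, 0.2))
  y <- c(2L, 2L, 1L, 2L, 2L, 1L, 2L)
  b_cpp <- vol_filter(y, kernels = k)
  st <- vol_init(k)
  b_r <- 0.5
  for (t in seq_along(y)) {
    expect_equal(b_cpp[t], b_r, tolerance = 1e-12)
    r <- vol_step(st, y[t], k)
    st <- r$state
    b_r <- r$e_x
  }
})

test_that("E[X] rises monotonically under sustained type-2 reward and tracks rates", {
  b <- vol_filter(rep(2L, 30))
  expect_true(all(diff(b) > 0))
  expect_gt(b[30], 0.8)
  # long stationary block: posterior mean near the empirical reward rate
  set.seed(9)
  y <- ifelse(runif(400) < 0.7, 2L, 1L)
  b <- vol_filter(y)
  expect_equal(mean(b[301:400]), mean(y[301:400] == 2), tolerance = 0.1)
})
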