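#' Two-state hidden Markov filter
#'
#' The hidden state is the current rule (state 1: type 1 mostly rewarded;
#' state 2: type 2).  Both the transition matrix and the outcome likelihood
#' are symmetric `[[p, 1-p], [1-p, p]]` matrices built from `1 - p_switch`
#' and `1 - p_error`, where `p_switch` is the per-trial rule-switch
#' probability and `p_error` the probability of a loss when responding with
#' the rule-consistent type.
#'
#' `hmm_step()` performs one forward step: the transition matrix is applied
#' to the posterior, the column of outcome likelihoods for the observed
#' rewarded type multiplies in, and the result is renormalized.  The
#' returned predictive probability that a type-1 response is rewarded on
#' the *next* trial applies one further transition, so the choice on trial
#' t+1 is based on `P(X_{t+1} | y_1..y_t)`.
#'
#' `hmm_filter()` runs the filter over a whole outcome sequence and returns
#' the per-trial predictive belief (the belief used *on* each trial, 0.5 on
#' trial 1) together with the marginal log-likelihood of the outcome
#' sequence (the summed log normalizers).  Missed trials leave the
#' posterior untouched.
#'
#' @param posterior length-2 probability vector over the two rules.
#' @param outcome observed rewarded type, 1 or 2.
#' @param params named vector with at least `p_switch` and `p_error`, both
#'   in \[0.00001, 0.5\].
#' @param rewarded integer vector of rewarded types (1/2).
#' @param responded logical vector; `FALSE` marks missed trials.
#' @return `hmm_step()`: list with the updated `posterior` and `p_type1`,
#'   the predictive reward probability of a type-1 response.
#'   `hmm_filter()`: list with `belief` (per-trial predictive `p_type1`)
#'   and `loglik` (marginal log-likelihood of the responded outcomes).
#' @export
hmm_step <- function(posterior, outcome, params) {
  stopifnot(length(posterior) == 2, all(posterior >= 0),
            abs(sum(posterior) - 1) < 1e-8, outcome %in% c(1L, 2L))
  ps <- params[["p_switch"]]; pe <- params[["p_error"]]
  .check_hmm_probs(ps, pe)
  trans <- matrix(c(1 - ps, ps, ps, 1 - ps), 2, 2)
  lik <- if (outcome == 1L) c(1 - pe, pe) else c(pe, 1 - pe)
  pred <- as.vector(trans %*% posterior)
  post <- lik * pred
  norm <- sum(post)
  if (norm <= 0) stop("zero normalizer in HMM step", call. = FALSE)
  post <- post / norm
  pred_next <- as.vector(trans %*% post)
  list(posterior = post,
       p_type1 = (1 - pe) * pred_next[1] + pe * pred_next[2])
}

#' @rdname hmm_step
#' @export
hmm_filter <- function(rewarded, params, responded = NULL) {
  ps <- params[["p_switch"]]; pe <- params[["p_error"]]
  .check_hmm_probs(ps, pe)
  if (is.null(responded)) responded <- rep(TRUE, length(rewarded))
  cpp_hmm_filter(ps, pe, as.integer(rewarded), responded)
}

# the filter itself tolerates the degenerate endpoints 0 and 0.5; the
# tighter [0.00001, 0.5] box applies to fitting (see model_bounds)
.check_hmm_probs <- function(ps, pe) {
  if (any(c(ps, pe) < 0) || any(c(ps, pe) > 0.5)) {
    stop("HMM probabilities must lie in [0, 0.5]", call. = FALSE)
  }
}

#' Exhaustive path-sum oracle for the HMM likelihood
#'
#' Computes the marginal likelihood of an outcome sequence by summing the
#' joint probability over all `2^t` hidden-state paths.  This is the
#' independent check for the recursive forward filter; it refuses sequences
#' longer than 12 outcomes.
#'
#' @inheritParams hmm_step
#' @return the log marginal likelihood `log P(y_1, ..., y_t)`.
#' @export
hmm_path_sum_loglik <- function(rewarded, params) {
  n <- length(rewarded)
  if (n > 12) stop("path-sum oracle limited to sequences of length <= 12",
                   call. = FALSE)
  ps <- params[["p_switch"]]; pe <- params[["p_error"]]
  .check_hmm_probs(ps, pe)
  hit <- 1 - pe
  total <- 0
  for (code in 0:(2^n - 1)) {
    states <- bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) + 1L  # 1 or 2
    p <- 0.5
    for (t in seq_len(n)) {
      if (t > 1) {
        p <- p * if (states[t] == states[t - 1]) 1 - ps else ps
      }
      p <- p * if (rewarded[t] == states[t]) hit else pe
    }
    total <- total + p
  }
  log(total)
}

#' Discretized transition kernels for the volatility filter
#'
#' The hierarchical filter tracks `X`, the reward probability of a type-2
#' response, and `V`, the volatility governing how fast `X` drifts, each on
#' the 49 equally spaced interior grid points of (0, 1); the confidence
#' parameter `K` (spread of the volatility random walk) has a log-spaced
#' grid with a uniform prior and is marginalized rather than fitted.
#'
#' The `X` kernel rows are discretized beta densities with mean equal to
#' the previous `X` and precision `a + b = exp(precision_scale * (1 - v))`,
#' so the smallest grid volatility freezes `X` (near-identity kernel) and
#' the largest approaches a fresh draw.  The `V` kernel rows are
#' discretized normal densities centered on the previous `V` with standard
#' deviation `k`.  All rows are renormalized over the grid.  Degenerate
#' beta shapes are clipped at `1e-8` with a warning.
#'
#' @param n_x,n_v number of interior grid points for `X` and `V`.
#' @param k_grid grid for the confidence parameter `K` (standard deviation
#'   of the volatility walk, grid units).
#' @param precision_scale scale `c` linking volatility to beta precision.
#' @return list with `x_grid`, `v_grid`, `k_grid`, `Xker` (array
#'   `[x_next, x_prev, v]`) and `Vker` (array `[v_next, v_prev, k]`);
#'   every kernel column (fixed previous state) sums to 1.
#' @export
vol_kernels <- function(n_x = 49, n_v = 49,
                        k_grid = exp(seq(log(0.005), log(0.5),
                                         length.out = 30)),
                        precision_scale = 10) {
  x_grid <- seq_len(n_x) / (n_x + 1)
  v_grid <- seq_len(n_v) / (n_v + 1)
  Xker <- array(0, c(n_x, n_x, n_v))
  for (vi in seq_len(n_v)) {
    s <- exp(precision_scale * (1 - v_grid[vi]))
    a <- x_grid * s
    b <- (1 - x_grid) * s
    if (any(a < 1e-8 | b < 1e-8)) {
      warning("clipping degenerate beta shapes in X kernel")
      a <- pmax(a, 1e-8); b <- pmax(b, 1e-8)
    }
    # column j: density of X_next given X_prev = x_grid[j]
    dens <- outer(x_grid, seq_len(n_x),
                  function(x, j) dbeta(x, a[j], b[j]))
    Xker[, , vi] <- sweep(dens, 2, colSums(dens), "/")
  }
  Vker <- array(0, c(n_v, n_v, length(k_grid)))
  for (ki in seq_along(k_grid)) {
    dens <- outer(v_grid, v_grid, function(v, m) dnorm(v, m, k_grid[ki]))
    Vker[, , ki] <- sweep(dens, 2, colSums(dens), "/")
  }
  list(x_grid = x_grid, v_grid = v_grid, k_grid = k_grid,
       Xker = Xker, Vker = Vker)
}

# memoised default kernels (fixed grids; building them costs ~1 s)
.default_vol_kernels <- function() {
  if (is.null(.revlearn_env$vol_kernels)) {
    .revlearn_env$vol_kernels <- vol_kernels()
  }
  .revlearn_env$vol_kernels
}

#' Volatility-filter state and stepping
#'
#' `vol_init()` returns the uniform joint prior over the `X` x `V` x `K`
#' grid.  `vol_step()` advances it one trial: the volatility propagates
#' under its `K`-conditioned kernel, `X` propagates under its
#' `V`-conditioned beta kernel, the Bernoulli outcome likelihood
#' (`P(type-2 rewarded | X = x) = x`) multiplies in, and the joint is
#' renormalized.  The returned `e_x`, the posterior mean of the `X`
#' marginal, is the belief that a type-2 response is rewarded; because the
#' beta kernel is mean-preserving, this is also the predictive belief for
#' the next choice.
#'
#' `vol_filter()` runs the filter over a whole sequence (C++ fast path) and
#' returns the belief used *on* each trial, starting at 0.5; missed trials
#' leave the state untouched.
#'
#' @param kernels kernel set from [vol_kernels()]; defaults to the
#'   memoised standard grids.
#' @param state joint probability array from `vol_init()`/`vol_step()`.
#' @inheritParams hmm_step
#' @return `vol_step()`: list with the updated `state` and `e_x`;
#'   `vol_filter()`: numeric vector of per-trial beliefs that a type-2
#'   response is rewarded.
#' @export
vol_init <- function(kernels = .default_vol_kernels()) {
  d <- c(length(kernels$x_grid), length(kernels$v_grid),
         length(kernels$k_grid))
  array(1 / prod(d), d)
}

#' @rdname vol_init
#' @export
vol_step <- function(state, outcome, kernels = .default_vol_kernels()) {
  stopifnot(outcome %in% c(1L, 2L))
  if (abs(sum(state) - 1) > 1e-6) {
    stop("volatility-filter state must be normalized", call. = FALSE)
  }
  nk <- length(kernels$k_grid)
  nv <- length(kernels$v_grid)
  lik <- if (outcome == 2L) kernels$x_grid else 1 - kernels$x_grid
  for (k in seq_len(nk)) {
    J <- state[, , k] %*% t(kernels$Vker[, , k])     # propagate V
    for (v in seq_len(nv)) {                          # propagate X
      J[, v] <- kernels$Xker[, , v] %*% J[, v]
    }
    state[, , k] <- J * lik
  }
  z <- sum(state)
  if (z <= 0) stop("zero normalizer in volatility filter", call. = FALSE)
  state <- state / z
  e_x <- sum(kernels$x_grid * apply(state, 1, sum))
  list(state = state, e_x = e_x)
}

#' @rdname vol_init
#' @export
vol_filter <- function(rewarded, responded = NULL,
                       kernels = .default_vol_kernels()) {
  if (is.null(responded)) responded <- rep(TRUE, length(rewarded))
  cpp_vol_filter(kernels$Xker, kernels$Vker, kernels$x_grid,
                 as.integer(rewarded), responded)
}

# belief that a *type-2* response is rewarded, default kernels
cpp_vol_filter_default <- function(rewarded, responded) {
  vol_filter(rewarded, responded)
}
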