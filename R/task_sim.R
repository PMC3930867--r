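#' Block specifications for the reversal-learning task
#'
#' The task crosses starting rule (1/2), feedback validity (25/30 vs 22/30,
#' i.e. 83.3% vs 73.3%) and volatility (stable: one rule for all 120 trials;
#' volatile: the rule switches every 30 trials), giving eight 120-trial
#' blocks, one per condition.  `default_blocks()` returns the eight
#' conditions; when `seed` is given the block order is a seeded random
#' permutation (the experiment used a randomized order).
#'
#' @param seed optional integer; permutes the block order reproducibly.
#' @param fv_high,fv_low the two feedback-validity levels.
#' @param n_trials trials per block; must be divisible by 30.
#' @return data.frame with columns `rule_start`, `fv`, `volatile`, `n_trials`.
#' @export
default_blocks <- function(seed = NULL, fv_high = 25 / 30, fv_low = 22 / 30,
                           n_trials = 120L) {
  blocks <- expand.grid(
    rule_start = c(1L, 2L),
    fv = c(fv_high, fv_low),
    volatile = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE
  )
  blocks$n_trials <- as.integer(n_trials)
  if (!is.null(seed)) {
    set.seed(seed)
    blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
  }
  rownames(blocks) <- NULL
  blocks
}

#' Generate a synthetic task schedule
#'
#' Builds a trial table with the rewarded response type assigned per trial.
#' Within every constant-rule segment (30 trials in volatile blocks, the
#' whole 120-trial block when stable), exactly `round(fv * segment length)`
#' trials have the rule-consistent type rewarded -- outcomes are randomized
#' to meet the feedback-validity percentages exactly, not in expectation.
#' Stimulus colors are i.i.d. uniform; color carries no information for
#' coupled models but is required by the uncoupled learner.
#'
#' @param seed integer RNG seed; the schedule is byte-identical across runs
#'   with the same seed and blocks.
#' @param blocks block specification as from [default_blocks()]; by default
#'   the eight conditions in a `seed`-permuted order.
#' @param strict if `TRUE` (default) require exactly the eight-condition
#'   design: 8 blocks covering every rule x FV x volatility combination once.
#' @return data.frame of class `revlearn_schedule` with one row per trial:
#'   `trial`, `block`, `segment`, `color`, `rule`, `fv`, `volatile`,
#'   `rewarded_type`, and unfilled `response_type`/`feedback` columns.
#'   The block table is attached as attribute `"blocks"`.
#' @export
generate_schedule <- function(seed, blocks = NULL, strict = TRUE) {
  if (is.null(blocks)) blocks <- default_blocks(seed)
  stopifnot(is.data.frame(blocks),
            all(c("rule_start", "fv", "volatile", "n_trials") %in% names(blocks)))
  if (any(blocks$n_trials %% 30L != 0L)) {
    stop("block n_trials must be divisible by 30", call. = FALSE)
  }
  if (any(blocks$fv <= 0.5 | blocks$fv > 1)) {
    stop("feedback validity must lie in (0.5, 1]", call. = FALSE)
  }
  if (strict) {
    if (nrow(blocks) != 8L) {
      stop("strict design requires exactly 8 blocks", call. = FALSE)
    }
    combos <- unique(blocks[, c("rule_start", "fv", "volatile")])
    if (nrow(combos) != 8L) {
      stop("strict design requires all 2 x 2 x 2 conditions exactly once",
           call. = FALSE)
    }
  }
  set.seed(seed)
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    nb <- blocks$n_trials[b]
    seg_len <- if (blocks$volatile[b]) 30L else nb
    n_seg <- nb %/% seg_len
    rule0 <- blocks$rule_start[b]
    rows <- vector("list", n_seg)
    for (s in seq_len(n_seg)) {
      # volatile blocks alternate the rule every segment
      rule <- if (s %% 2L == 1L) rule0 else 3L - rule0
      n_cons <- as.integer(round(blocks$fv[b] * seg_len))
      rewarded <- rep.int(3L - rule, seg_len)
      rewarded[sample.int(seg_len, n_cons)] <- rule
      rows[[s]] <- data.frame(
        block = b,
        segment = s,
        color = sample(c("red", "blue"), seg_len, replace = TRUE),
        rule = rule,
        fv = blocks$fv[b],
        volatile = blocks$volatile[b],
        rewarded_type = rewarded,
        stringsAsFactors = FALSE
      )
    }
    out[[b]] <- do.call(rbind, rows)
  }
  sched <- do.call(rbind, out)
  sched <- cbind(trial = seq_len(nrow(sched)), sched)
  sched$response_type <- NA_integer_
  sched$feedback <- NA_character_
  attr(sched, "blocks") <- blocks
  attr(sched, "seed") <- seed
  class(sched) <- c("revlearn_schedule", "data.frame")
  sched
}

#' Simulate a model-driven responder on a schedule
#'
#' Fills `response_type` and `feedback` by drawing each response from the
#' model's softmax choice probability given its current belief, then
#' updating beliefs with the realized feedback.  Win/loss feedback follows
#' the coupled outcome rule: a response wins iff it matches the trial's
#' rewarded type.  With probability `miss_rate` a trial is missed: no
#' response, no belief update, and the after-loss temperature applies to
#' the next choice (models with a temperature pair).
#'
#' @inheritParams validate_params
#' @param schedule schedule from [generate_schedule()].
#' @param seed integer RNG seed for the response draws.
#' @param miss_rate probability in \[0, 0.1\] of a missed trial.
#' @return the schedule with `response_type`, `feedback` and `p_type1`
#'   (the model's per-trial probability of a type-1 response) filled.
#' @export
simulate_agent <- function(model, params, schedule, seed = 1,
                           miss_rate = 0) {
  model <- match.arg(model, model_ids())
  params <- validate_params(model, params)
  if (miss_rate < 0 || miss_rate > 0.1) {
    stop("miss_rate must lie in [0, 0.1]", call. = FALSE)
  }
  n <- nrow(schedule)
  set.seed(seed)
  missed <- runif(n) < miss_rate
  responded <- !missed

  # belief trajectories of the Bayes filters and the plain coupled learner
  # depend only on the outcome sequence, so they can be precomputed
  B <- switch(model,
    RL  = cpp_rl_belief(params[["alpha"]], schedule$rewarded_type, responded),
    HMM = cpp_hmm_filter(params[["p_switch"]], params[["p_error"]],
                         schedule$rewarded_type, responded)$belief,
    VOL = 1 - cpp_vol_filter_default(schedule$rewarded_type, responded),
    NULL
  )

  resp <- rep(NA_integer_, n)
  fb <- rep(NA_character_, n)
  p1 <- rep(NA_real_, n)
  prev <- "none"
  q1 <- 0.5                    # WL belief
  q <- init_unc_belief()       # UNC beliefs

  for (t in seq_len(n)) {
    temp <- select_temperature(model, params, prev)
    if (model == "UNC") {
      ci <- if (schedule$color[t] == "red") 1L else 2L
      pb1 <- unc_softmax_prob(q[ci, 1L], q[ci, 2L], temp)
      # probability of a *type-1* response given the displayed color
      p1[t] <- if (ci == 1L) pb1 else 1 - pb1
    } else {
      b <- if (model == "WL") q1 else B[t]
      p1[t] <- softmax_prob(b, temp)
    }
    if (missed[t]) {
      fb[t] <- "missed"
      prev <- "missed"
      next
    }
    resp[t] <- if (runif(1) < p1[t]) 1L else 2L
    win <- resp[t] == schedule$rewarded_type[t]
    fb[t] <- if (win) "win" else "loss"
    prev <- fb[t]
    if (model == "WL") {
      a <- if (win) params[["alpha_win"]] else params[["alpha_loss"]]
      q1 <- q1 + a * ((schedule$rewarded_type[t] == 1L) - q1)
    } else if (model == "UNC") {
      ci <- if (schedule$color[t] == "red") 1L else 2L
      bi <- if (ci == 1L) resp[t] else 3L - resp[t]
      q[ci, bi] <- q[ci, bi] + params[["alpha"]] * (win - q[ci, bi])
    }
  }
  schedule$response_type <- resp
  schedule$feedback <- fb
  schedule$p_type1 <- p1
  schedule
}
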