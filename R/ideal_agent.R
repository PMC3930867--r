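#' Run a greedy (reward-maximizing) agent on a schedule
#'
#' An ideal agent always takes the response type its model currently rates
#' most likely to be rewarded -- no softmax -- and updates beliefs from the
#' realized feedback.  Exact ties at belief 0.5 (always the first trial)
#' are broken by a seeded fair coin.  Temperatures in `params` are ignored;
#' for the VOL model `params` may be `NULL`.
#'
#' @inheritParams validate_params
#' @param schedule schedule with `rewarded_type` filled.
#' @param seed RNG seed for tie-breaking coin flips.
#' @param engine `"cpp"` (fast path) or `"R"` (reference implementation);
#'   both consume the same RNG stream and return identical win counts.
#' @return total number of rewarded trials (integer).
#' @export
ideal_run <- function(model, params = NULL, schedule, seed = 1,
                      engine = c("cpp", "R")) {
  model <- match.arg(model, c("RL", "WL", "HMM", "VOL"))
  engine <- match.arg(engine)
  rewarded <- as.integer(schedule$rewarded_type)
  set.seed(seed)
  if (engine == "cpp") {
    return(switch(model,
      RL  = cpp_rl_ideal_wins(params[["alpha"]], rewarded)[1],
      WL  = cpp_wl_ideal_wins(params[["alpha_win"]], params[["alpha_loss"]],
                              rewarded)[1],
      HMM = cpp_hmm_ideal_wins(params[["p_switch"]], params[["p_error"]],
                               rewarded)[1],
      VOL = .vol_ideal_wins(rewarded)
    ))
  }
  .ideal_run_r(model, params, rewarded)
}

# greedy response given belief in a type-1 reward; coin at exact ties
.greedy_type1 <- function(b) {
  if (b > 0.5) 1L else if (b < 0.5) 2L else if (runif(1) < 0.5) 1L else 2L
}

.ideal_run_r <- function(model, params, rewarded) {
  n <- length(rewarded)
  wins <- 0L
  if (model == "VOL") {
    state <- vol_init()
    b <- 0.5
    for (t in seq_len(n)) {
      resp <- .greedy_type1(b)
      wins <- wins + (resp == rewarded[t])
      st <- vol_step(state, rewarded[t])
      state <- st$state
      b <- 1 - st$e_x
    }
    return(wins)
  }
  if (model == "HMM") {
    post <- c(0.5, 0.5)
    b <- 0.5
    for (t in seq_len(n)) {
      resp <- .greedy_type1(b)
      wins <- wins + (resp == rewarded[t])
      st <- hmm_step(post, rewarded[t], params)
      post <- st$posterior
      b <- st$p_type1
    }
    return(wins)
  }
  q <- 0.5
  for (t in seq_len(n)) {
    resp <- .greedy_type1(q)
    win <- resp == rewarded[t]
    wins <- wins + win
    a <- if (model == "RL") params[["alpha"]]
         else if (win) params[["alpha_win"]] else params[["alpha_loss"]]
    q <- q + a * ((rewarded[t] == 1L) - q)
  }
  wins
}

# VOL greedy wins via the (response-independent) filtered belief trajectory
.vol_ideal_wins <- function(rewarded) {
  b2 <- vol_filter(rewarded)         # belief that type 2 is rewarded
  resp <- integer(length(rewarded))
  for (t in seq_along(rewarded)) {
    resp[t] <- if (b2[t] > 0.5) 2L else if (b2[t] < 0.5) 1L
               else if (runif(1) < 0.5) 1L else 2L
  }
  sum(resp == rewarded)
}

#' Default parameter grids for the ideal-agent search
#'
#' RL and WL learning rates on the full 0.01-step grid; the HMM switch and
#' error probabilities on a grid bracketing the generative environment
#' (switch rate 0.021, i.e. 5 switches in 240 trials; average error
#' probability 0.22 across the two feedback-validity levels).
#'
#' @inheritParams validate_params
#' @return named list of grid vectors for the model's searchable
#'   parameters.
#' @export
default_ideal_grid <- function(model) {
  switch(match.arg(model, c("RL", "WL", "HMM")),
    RL = list(alpha = seq(0.01, 1, by = 0.01)),
    WL = list(alpha_win = seq(0.01, 1, by = 0.01),
              alpha_loss = seq(0.01, 1, by = 0.01)),
    HMM = list(p_switch = sort(unique(c(seq(0.005, 0.05, by = 0.005),
                                        0.021))),
               p_error = seq(0.10, 0.30, by = 0.01))
  )
}

#' Grid search for reward-maximizing ideal-agent parameters
#'
#' Evaluates the greedy agent's mean total wins at every grid point across
#' all supplied schedules (the same outcome sequences are reused for every
#' grid point, so the surface is a deterministic function of the
#' schedules), and returns the argmax together with the full surface.
#'
#' Distinct parameter settings can induce identical greedy policies (for
#' the HMM, switch/error probabilities trade off in the posterior odds), so
#' exact ties in total wins do occur.  Among exactly tied maxima the point
#' nearest `anchor` (normalized by each grid's span) is returned; the
#' default anchor for the HMM is the generative environment approximation
#' (switch rate 0.021, mean error probability 0.22), mirroring the search's
#' anchoring on the generative structure.  Without an anchor the first
#' tied point in grid order wins.
#'
#' @inheritParams ideal_run
#' @param grid named list of parameter value vectors (expanded to their
#'   Cartesian product); defaults to [default_ideal_grid()].
#' @param schedules a schedule or list of schedules.
#' @param anchor optional named vector used to break exact win ties.
#' @return object of class `revlearn_ideal`: list with `model`, `surface`
#'   (data.frame of grid points and `mean_wins`), `best_params`,
#'   `best_mean_wins`, `n_tied`, and `wins` (schedules x grid matrix).
#' @export
grid_search_ideal <- function(model, schedules,
                              grid = default_ideal_grid(model), seed = 1,
                              anchor = if (model == "HMM")
                                c(p_switch = 0.021, p_error = 0.22)) {
  model <- match.arg(model, c("RL", "WL", "HMM"))
  if (is.data.frame(schedules)) schedules <- list(schedules)
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop("empty ideal-agent search grid", call. = FALSE)
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  wins <- matrix(0L, nrow = length(schedules), ncol = nrow(pts))
  for (s in seq_along(schedules)) {
    rewarded <- as.integer(schedules[[s]]$rewarded_type)
    wins[s, ] <- switch(model,
      RL  = cpp_rl_ideal_wins(pts$alpha, rewarded),
      WL  = cpp_wl_ideal_wins(pts$alpha_win, pts$alpha_loss, rewarded),
      HMM = cpp_hmm_ideal_wins(pts$p_switch, pts$p_error, rewarded)
    )
  }
  surface <- pts
  total <- colSums(wins)
  surface$mean_wins <- total / length(schedules)
  tied <- which(total == max(total))
  best <- tied[1]
  if (length(tied) > 1 && !is.null(anchor)) {
    span <- vapply(grid, function(g) max(diff(range(g)), 1e-12), numeric(1))
    d2 <- rowSums(sweep(sweep(as.matrix(pts[tied, names(grid), drop = FALSE]),
                              2, anchor[names(grid)]),
                        2, span, "/")^2)
    best <- tied[which.min(d2)]
  }
  structure(list(
    model = model, surface = surface,
    best_params = unlist(pts[best, , drop = FALSE]),
    best_mean_wins = surface$mean_wins[best],
    n_tied = length(tied),
    wins = wins, seed = seed
  ), class = "revlearn_ideal")
}

#' Post-switch maximizing curve
#'
#' Aligns the constant-rule segments of volatile blocks at rule switches
#' and computes the percentage of rule-consistent responses at each
#' post-switch trial position (1-30), split by feedback validity.  Only
#' segments preceded by a switch (segments 2-4 of a volatile block) enter;
#' missed trials are excluded.  A probability-matching responder plateaus
#' near the block's feedback validity; an ideal agent approaches 100% in
#' high-validity blocks.
#'
#' @param trials trial data.frame with responses filled, or a list of them
#'   (e.g. several simulated participants), row-bound internally.
#' @param window trial positions after a switch to average over for the
#'   summary (default 21:30).
#' @return list with `curve` (data.frame `fv`, `position`, `pct`, `n`) and
#'   `window` (data.frame `fv`, `pct`, `n` pooled over `window` positions).
#' @export
maximizing_curve <- function(trials, window = 21:30) {
  if (is.data.frame(trials)) trials <- list(trials)
  trials <- do.call(rbind, lapply(seq_along(trials), function(i) {
    d <- as.data.frame(trials[[i]])
    d$.sched <- i
    d
  }))
  d <- trials[trials$volatile & trials$segment > 1, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("no post-switch volatile segments in the supplied trials",
         call. = FALSE)
  }
  key <- interaction(d$.sched, d$block, d$segment, drop = TRUE)
  d$position <- ave(seq_len(nrow(d)), key, FUN = seq_along)
  d <- d[!is.na(d$response_type), , drop = FALSE]
  d$consistent <- d$response_type == d$rule
  curve <- aggregate(consistent ~ fv + position, data = d,
                     FUN = function(x) 100 * mean(x))
  names(curve)[names(curve) == "consistent"] <- "pct"
  counts <- aggregate(consistent ~ fv + position, data = d, FUN = length)
  curve$n <- counts$consistent
  w <- d[d$position %in% window, , drop = FALSE]
  window_df <- aggregate(consistent ~ fv, data = w,
                         FUN = function(x) 100 * mean(x))
  names(window_df)[names(window_df) == "consistent"] <- "pct"
  wc <- aggregate(consistent ~ fv, data = w, FUN = length)
  window_df$n <- wc$consistent
  list(curve = curve[order(curve$fv, curve$position), ],
       window = window_df, window_range = range(window))
}
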