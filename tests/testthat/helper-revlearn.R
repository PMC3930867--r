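# shared fixtures: everything is generated in code, no stored data

# minimal trial table in the schedule dialect; feedback derived from the
# coupled rule (win iff response matches the rewarded type) unless given
make_trials <- function(rewarded_type, response_type = NULL, feedback = NULL,
                        color = NULL) {
  n <- length(rewarded_type)
  if (is.null(response_type)) response_type <- rep(1L, n)
  if (is.null(feedback)) {
    feedback <- ifelse(is.na(response_type), "missed",
                       ifelse(response_type == rewarded_type, "win", "loss"))
  }
  if (is.null(color)) color <- rep("red", n)
  data.frame(
    trial = seq_len(n), block = 1L, segment = 1L, color = color,
    rule = 1L, fv = 25 / 30, volatile = FALSE,
    rewarded_type = as.integer(rewarded_type),
    response_type = as.integer(response_type), feedback = feedback,
    stringsAsFactors = FALSE
  )
}

# single stable block with perfectly valid feedback (testing dialect)
fv1_schedule <- function(seed = 1, n_trials = 120L) {
  blocks <- data.frame(rule_start = 1L, fv = 1, volatile = FALSE,
                       n_trials = n_trials)
  generate_schedule(seed, blocks = blocks, strict = FALSE)
}

# swap response types / rules 1 <-> 2 everywhere (coupling mirror)
mirror_schedule <- function(sched) {
  sched$rule <- 3L - sched$rule
  sched$rewarded_type <- 3L - sched$rewarded_type
  if (any(!is.na(sched$response_type))) {
    sched$response_type <- 3L - sched$response_type
  }
  sched
}

wl_mean_params <- c(alpha_win = 0.77, alpha_loss = 0.52,
                    T_win = 0.35, T_loss = 0.87)
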