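# Shared fixtures built in code at test time.

noiseless_params <- function(...) {
  pre <- agent_preset("noiseless")
  pre <- utils::modifyList(pre, lapply(list(...), function(v) c(v, 0)))
  p <- lapply(pre, function(v) if (length(v) >= 2) v[1] else v)
  do.call(agent_params, p)
}

# A single noiseless trial (normal ball, uncued) plus its raw data.
make_clean_trial <- function(params = noiseless_params(), belief = 0,
                             seed = 42, elasticity = 0.65, cued = FALSE,
                             bouncy_pct = NA) {
  traj <- simulate_trajectory(launch_spec(elasticity = elasticity))
  trial <- list(trial_index = 0L,
                ball_type = if (elasticity == 0.65) "normal" else "bouncy",
                elasticity = elasticity, cued = cued, bouncy_pct = bouncy_pct,
                label = NA)
  list(raw = generate_trial(trial, traj, belief, params, seed), traj = traj,
       trial = trial)
}

# Long outcome table for the 2 x 2 design with given cell means.
make_outcome_table <- function(n1 = 8, n2 = 8, means = c(0, 0, 0, 0), sd = 1,
                               seed = 1) {
  withr::with_seed(seed, {
    ids <- paste0("p", seq_len(n1 + n2))
    grp <- rep(c("ASD", "NT"), c(n1, n2))
    d <- expand.grid(participant_id = ids, condition = c("control", "cued"),
                     stringsAsFactors = FALSE)
    d$group <- grp[match(d$participant_id, ids)]
    mu <- matrix(means, 2, 2, dimnames = list(c("ASD", "NT"),
                                              c("control", "cued")))
    d$value <- stats::rnorm(nrow(d), mu[cbind(d$group, d$condition)], sd)
    d$AQ_total <- round(ifelse(grp == "ASD", 36, 16) +
                          stats::rnorm(n1 + n2, 0, 5))[match(d$participant_id, ids)]
    d$IUS_total <- round(39 + stats::rnorm(n1 + n2, 0, 8))[match(d$participant_id, ids)]
    tibble::as_tibble(d)
  })
}

# Uniform gaze-angle tibble at 120 Hz.
make_angles <- function(yaw, pitch, valid = TRUE, rate = 120) {
  n <- length(yaw)
  tibble::tibble(t = (seq_len(n) - 1) / rate, yaw = yaw, pitch = pitch,
                 valid = rep_len(valid, n))
}
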