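#' Cohort simulation
#'
#' Builds synthetic participant cohorts matching the study's composition:
#' 22 autistic (ASD) and 22 neurotypical (NT) adults, AQ and IUS-S totals
#' drawn from truncated normals matching the reported group distributions
#' (ASD AQ 35.86 +- 5.37 truncated at the clinical screening cut-off of 26;
#' NT 15.59 +- 7.96; IUS-S 38.86 +- 9.98 vs 27.00 +- 10.14), and agent
#' parameters drawn from group-level preset distributions.
#'
#' The two calibrated presets encode the study's qualitative pattern through
#' two mechanistic dials: the ASD-like agent learns fast (high delta-rule
#' rate, so its belief - and hence its fixation pitch - fluctuates
#' trial-to-trial) but leans little on the explicit cue, while the NT-like
#' agent learns slowly from a normal-ball prior (so its average bouncy
#' belief, and fixation pitch, rises once cues arrive) and weights cues
#' heavily. ROM shrinks with belief entropy at a much steeper slope in the
#' ASD-like preset, producing the control-to-cued ROM restriction, and
#' ASD-like arrival-timing noise is larger and more heterogeneous,
#' producing the lower, more dispersed interception rates.
#'
#' @name cohort
NULL

#' Group-level agent presets
#'
#' Each preset gives the between-participant mean and sd of every agent
#' parameter (sd 0 for parameters held fixed); `timing_noise_sd` is
#' lognormal across participants, specified as `c(median, sdlog)`, giving
#' the heavy low-performance tail seen in interception data. `"null"`
#' makes both groups identical with all belief-driven effects switched
#' off, for null calibration; `"noiseless"` removes every noise source,
#' for parameter-recovery checks.
#'
#' @param name one of `"asd_like"`, `"nt_like"`, `"null"`, `"noiseless"`.
#' @return list of `c(mean, sd)` pairs plus fixed fields.
#' @export
agent_preset <- function(name = c("asd_like", "nt_like", "null", "noiseless")) {
  name <- match.arg(name)
  base <- list(
    learning_rate = c(0.30, 0.05), cue_weight = c(0.50, 0.10),
    gaze_noise_sd = c(0.30, 0.05), pitch_gain = c(9, 0.5), pitch_bias = c(-32, 1),
    rom_base = c(85, 5), rom_uncertainty_slope = c(20, 5), rom_noise_sd = c(2, 0),
    swing_peak_velocity_mean = c(2.0, 0.2), swing_peak_velocity_sd = c(0.15, 0),
    timing_noise_sd = c(0.05, 0.01), fixation_hold_s = c(0.4, 0),
    dropout_rate = c(0.01, 0), gap_rate = c(0.03, 0)
  )
  presets <- list(
    asd_like = utils::modifyList(base, list(
      learning_rate = c(0.60, 0.10), cue_weight = c(0.25, 0.10),
      gaze_noise_sd = c(0.35, 0.05),
      rom_base = c(95, 6), rom_uncertainty_slope = c(45, 8),
      swing_peak_velocity_mean = c(1.9, 0.20),
      timing_noise_sd = c(0.180, 0.62)
    )),
    nt_like = utils::modifyList(base, list(
      learning_rate = c(0.035, 0.015), cue_weight = c(0.80, 0.10),
      gaze_noise_sd = c(0.25, 0.05),
      rom_base = c(76, 6), rom_uncertainty_slope = c(5, 3),
      swing_peak_velocity_mean = c(2.1, 0.20),
      timing_noise_sd = c(0.100, 0.50)
    )),
    null = utils::modifyList(base, list(
      learning_rate = c(0.30, 0), cue_weight = c(0.50, 0),
      rom_uncertainty_slope = c(0, 0)
    )),
    noiseless = utils::modifyList(base, list(
      learning_rate = c(0.30, 0), cue_weight = c(0.50, 0),
      gaze_noise_sd = c(0, 0), pitch_gain = c(9, 0), pitch_bias = c(-32, 0),
      rom_base = c(85, 0), rom_uncertainty_slope = c(0, 0), rom_noise_sd = c(0, 0),
      swing_peak_velocity_mean = c(2.0, 0), swing_peak_velocity_sd = c(0, 0),
      timing_noise_sd = c(0, 0),
      dropout_rate = c(0, 0), gap_rate = c(0, 0)
    ))
  )
  presets[[name]]
}

#' Draw one participant's agent parameters from a preset
#'
#' Truncated-normal draws for most parameters; `timing_noise_sd` is drawn
#' lognormally (see [agent_preset()]).
#'
#' @param preset an [agent_preset()] list.
#' @return an [agent_params()].
#' @export
sample_agent_params <- function(preset) {
  draw <- function(field, lower = -Inf, upper = Inf) {
    m <- preset[[field]][1]; s <- preset[[field]][2]
    if (s == 0) return(m)
    rtruncnorm(1, m, s, lower, upper)
  }
  agent_params(
    learning_rate = draw("learning_rate", 0.005, 0.95),
    cue_weight = draw("cue_weight", 0, 1),
    gaze_noise_sd = draw("gaze_noise_sd", 0, Inf),
    pitch_gain = draw("pitch_gain", 0, Inf),
    pitch_bias = draw("pitch_bias"),
    rom_base = draw("rom_base", 50, 115),
    rom_uncertainty_slope = draw("rom_uncertainty_slope", 0, Inf),
    rom_noise_sd = draw("rom_noise_sd", 0, Inf),
    swing_peak_velocity_mean = draw("swing_peak_velocity_mean", 0.9, Inf),
    swing_peak_velocity_sd = draw("swing_peak_velocity_sd", 0, Inf),
    # lognormal across participants: c(median, sdlog); the right tail yields
    # the occasional low-performing participant seen in interception data
    timing_noise_sd = {
      m <- preset$timing_noise_sd[1]; s <- preset$timing_noise_sd[2]
      if (s == 0) m else exp(rnorm(1, log(m), s))
    },
    fixation_hold_s = draw("fixation_hold_s", 0.1, Inf),
    dropout_rate = draw("dropout_rate", 0, 0.5),
    gap_rate = draw("gap_rate", 0, Inf)
  )
}

# Draw questionnaire covariates for one participant.
sample_covariates <- function(group) {
  if (group == "ASD") {
    aq <- rtruncnorm(1, 35.86, 5.37, 26, 50)
    ius <- rtruncnorm(1, 38.86, 9.98, 12, 60)
  } else {
    aq <- rtruncnorm(1, 15.59, 7.96, 0, 50)
    ius <- rtruncnorm(1, 27.00, 10.14, 12, 60)
  }
  list(AQ_total = round(aq), IUS_total = round(ius))
}

#' Simulate one participant over a full session
#'
#' Runs the baseline, control and cued blocks in order, carrying the
#' delta-rule belief across trials within each experimental block (reset at
#' each block start, reflecting the normal-ball prior built at baseline).
#'
#' @param participant_id identifier string.
#' @param group `"ASD"` or `"NT"` (labels only; behaviour comes from params).
#' @param params an [agent_params()].
#' @param design a [make_study_design()] list.
#' @param seed integer seed for this participant.
#' @param detail `"streams"` (full raw data) or `"metrics"` (ground-truth
#'   per-trial metrics only, no stream synthesis).
#' @param contact in `"metrics"` mode, whether to run the analytic contact
#'   geometry (slower) or skip interception.
#' @return list with `participant_id`, `group`, `params` and `blocks`; each
#'   block holds per-trial raw data (streams mode) or a `trial_truth` tibble
#'   (metrics mode).
#' @export
simulate_participant <- function(participant_id, group, params, design, seed,
                                 detail = c("streams", "metrics"),
                                 contact = TRUE) {
  detail <- match.arg(detail)
  trajs <- list(
    normal = simulate_trajectory(launch_spec(elasticity = 0.65)),
    bouncy = simulate_trajectory(launch_spec(elasticity = 0.85))
  )
  blocks <- lapply(names(design), function(bk) {
    block <- design[[bk]]
    tr <- block$trials
    b <- 0 # normal-ball prior from baseline experience
    out <- vector("list", nrow(tr))
    truths <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      trial <- tr[i, ]
      traj <- trajs[[trial$ball_type]]
      tseed <- derive_seed(seed, bk, i)
      if (detail == "streams") {
        raw <- generate_trial(trial, traj, b, params, tseed)
        out[[i]] <- raw
        truths[[i]] <- c(list(trial_index = trial$trial_index,
                              ball_type = trial$ball_type,
                              intercepted = raw$events$intercepted),
                         raw$truth[c("rom", "pitch_fix", "v_peak", "tau",
                                     "belief", "effective_belief")])
      } else {
        beh <- draw_trial_behavior(trial, b, params, tseed)
        hit <- NA
        v_peak <- beh$v_peak
        if (contact) {
          plan <- plan_swing(beh$rom, beh$v_peak, traj, beh$tau)
          hit <- !is.na(analytic_contact(plan, traj, traj$t_end))
          v_peak <- plan$v_peak_eff
        }
        truths[[i]] <- list(trial_index = trial$trial_index,
                            ball_type = trial$ball_type, intercepted = hit,
                            rom = beh$rom, pitch_fix = beh$pitch_fix,
                            v_peak = v_peak, tau = beh$tau,
                            belief = beh$belief,
                            effective_belief = beh$effective_belief)
      }
      b <- update_belief(b, as.integer(trial$ball_type == "bouncy"),
                         params$learning_rate)
    }
    list(block_kind = block$block_kind,
         trials = if (detail == "streams") out else NULL,
         trial_truth = dplyr::bind_rows(lapply(truths, tibble::as_tibble)))
  })
  names(blocks) <- names(design)
  list(participant_id = participant_id, group = group, params = params,
       blocks = blocks)
}

#' Simulate a cohort of synthetic participants
#'
#' @param n_per_group participants per group (the study used 22).
#' @param seed master seed; all randomness derives from it via named
#'   substreams (design, covariates, per-participant, per-trial).
#' @param groups named list mapping group label to preset name or preset
#'   list; default the calibrated `asd_like` / `nt_like` pair.
#' @param sequence_id canonical trial-order sequence shared by the cohort.
#' @param detail,contact passed to [simulate_participant()].
#' @return list with `design`, `manifest` (tibble: participant_id, group,
#'   AQ_total, IUS_total, handedness) and `participants`.
#' @export
simulate_cohort <- function(n_per_group = 22, seed = 1,
                            groups = list(ASD = "asd_like", NT = "nt_like"),
                            sequence_id = 1,
                            detail = c("streams", "metrics"), contact = TRUE) {
  detail <- match.arg(detail)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  design <- make_study_design(seed, sequence_id)
  manifest <- list()
  participants <- list()
  for (g in names(groups)) {
    preset <- groups[[g]]
    if (is.character(preset)) preset <- agent_preset(preset)
    for (j in seq_len(n_per_group)) {
      pid <- sprintf("%s%02d", g, j)
      pseed <- derive_seed(seed, "participant", pid)
      drawn <- with_seed(derive_seed(pseed, "cov"), {
        cov <- sample_covariates(g)
        par <- sample_agent_params(preset)
        hand <- if (runif(1) < 1 / 22) "left" else "right"
        list(cov = cov, par = par, hand = hand)
      })
      manifest[[pid]] <- tibble::tibble(
        participant_id = pid, group = g,
        AQ_total = drawn$cov$AQ_total, IUS_total = drawn$cov$IUS_total,
        handedness = drawn$hand
      )
      participants[[pid]] <- simulate_participant(
        pid, g, drawn$par, design, pseed, detail = detail, contact = contact
      )
    }
  }
  list(design = design, manifest = dplyr::bind_rows(manifest),
       participants = participants)
}
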