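#' Participant summaries and the full results battery
#'
#' `summarize_participants()` reduces per-trial pipeline metrics to the
#' per-participant-per-condition outcomes the study analyses;
#' `run_full_battery()` then mirrors the structure of its Results: a
#' manipulation check (paired t of baseline vs control bounce-fixation
#' pitch), seven mixed ANOVAs (interception rate, peak velocity, ROM,
#' fixation onset, duration, pitch, pitch SD), post-hoc follow-ups where an
#' effect is significant (nonparametric when the outcome failed
#' normality), and AQ/IUS-S trait correlations per condition, all with
#' Bayes factors.
#'
#' @name full_battery
NULL

OUTCOME_NAMES <- c("interception_rate", "peak_velocity", "rom",
                   "median_onset", "mean_duration", "mean_pitch", "sd_pitch")

#' Summarize per-trial metrics per participant and block
#'
#' @param trial_metrics tibble with one row per trial: participant_id,
#'   group, block_kind, intercepted, peak_velocity, rom, flagged, plus the
#'   gaze columns excluded, has_fixation, onset_rel_launch, duration,
#'   pitch.
#' @param min_gaze_trials minimum unexcluded fixation trials per cell for
#'   the gaze outcomes (default 2).
#' @return tibble with one row per participant x block and one column per
#'   outcome.
#' @export
summarize_participants <- function(trial_metrics, min_gaze_trials = 2) {
  split_by <- interaction(trial_metrics$participant_id,
                          trial_metrics$block_kind, drop = TRUE)
  rows <- lapply(split(trial_metrics, split_by), function(d) {
    kin_ok <- !d$flagged
    gz <- aggregate_gaze(d, min_trials = min_gaze_trials)
    tibble::tibble(
      participant_id = d$participant_id[1],
      group = d$group[1],
      block_kind = d$block_kind[1],
      n_trials = nrow(d),
      interception_rate = interception_rate(ifelse(kin_ok, d$intercepted, NA)),
      peak_velocity = mean(d$peak_velocity[kin_ok], na.rm = TRUE),
      rom = mean(d$rom[kin_ok], na.rm = TRUE),
      median_onset = gz$median_onset,
      mean_duration = gz$mean_duration,
      mean_pitch = gz$mean_pitch,
      sd_pitch = gz$sd_pitch,
      n_gaze_trials = gz$n_trials
    )
  })
  dplyr::bind_rows(rows)
}

# Long outcome table for one outcome over the two experimental conditions.
outcome_table <- function(summary, outcome,
                          conditions = c("control", "cued")) {
  s <- summary[summary$block_kind %in% conditions, ]
  tibble::tibble(
    participant_id = s$participant_id,
    group = s$group,
    condition = s$block_kind,
    value = s[[outcome]],
    AQ_total = s$AQ_total,
    IUS_total = s$IUS_total
  )
}

#' Run the full inferential battery
#'
#' @param summary per-participant summary from [summarize_participants()],
#'   joined with the cohort manifest (AQ_total, IUS_total).
#' @param alpha significance level (default 0.05) for assumption routing
#'   and post-hoc triggering.
#' @return list with `manipulation_check`, `anovas`, `posthocs`,
#'   `correlations`, `assumptions`, `missing_outcomes` and `alpha`.
#' @export
run_full_battery <- function(summary, alpha = 0.05) {
  stopifnot(all(c("AQ_total", "IUS_total") %in% names(summary)))

  # Manipulation check: bounce-fixation pitch, baseline vs control, paired t
  manip <- NULL
  widep <- tidyr::pivot_wider(
    summary[summary$block_kind %in% c("baseline", "control"),
            c("participant_id", "block_kind", "mean_pitch")],
    names_from = "block_kind", values_from = "mean_pitch")
  widep <- widep[stats::complete.cases(widep), ]
  if (nrow(widep) >= 3) {
    tt <- stats::t.test(widep$control, widep$baseline, paired = TRUE)
    manip <- tibble::tibble(
      outcome = "mean_pitch", effect = "control vs baseline",
      statistic_name = "t", value = unname(tt$statistic),
      df1 = unname(tt$parameter), df2 = NA_real_, p = tt$p.value,
      effect_size = NA_real_,
      bf10 = bf_ttest_jzs(unname(tt$statistic), nrow(widep), paired = TRUE),
      correction = "none", degenerate = FALSE,
      mean_difference = unname(tt$estimate)
    )
  }

  anovas <- list(); posthocs <- list(); correlations <- list()
  assumptions <- list(); missing <- character()
  for (oc in OUTCOME_NAMES) {
    tab <- outcome_table(summary, oc)
    tab <- tab[!is.na(tab$value), ]
    counts <- table(tab$group[!duplicated(tab$participant_id)])
    if (length(counts) < 2 || any(counts < 3)) {
      missing <- c(missing, oc)
      next
    }
    chk <- assumption_checks(tab, oc, alpha)
    assumptions[[oc]] <- chk
    an <- mixed_anova_2x2(tab, oc)
    anovas[[oc]] <- an
    if (any(an$p < alpha, na.rm = TRUE)) {
      posthocs[[oc]] <- posthoc_tests(tab, oc, nonparametric = chk$nonnormal)
    }
    correlations[[oc]] <- trait_correlations(tab, oc,
                                             nonparametric = chk$nonnormal)
  }
  list(
    manipulation_check = manip,
    anovas = dplyr::bind_rows(anovas),
    posthocs = dplyr::bind_rows(posthocs),
    correlations = dplyr::bind_rows(correlations),
    assumptions = assumptions,
    missing_outcomes = missing,
    alpha = alpha
  )
}
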