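#' Trial-sequence design for the virtual racquetball task
#'
#' The task presents balls whose elasticity is either "normal" (coefficient of
#' restitution 0.65, as at baseline) or "bouncy" (0.85). In the two
#' experimental blocks the probability of facing a normal ball changes every
#' 6, 9 or 12 trials (between 0.83, 0.67 and 0.50), creating a volatile
#' sequence. Each experimental block has exactly 45 trials, two thirds normal,
#' and ends with a 9-trial cue-free "catch" level. In the cued block every
#' level opens with a "hawkeye" display (10 s) and each trial is preceded by a
#' "bounceometer" cue (3 s) stating whether a bouncy ball is "low" (17%),
#' "medium" (33%) or "high" (50%) in likelihood.
#'
#' A block plan is a list with class `"block_plan"` holding a `trials` tibble
#' (one row per trial) and a `levels` tibble (one row per game level).
#'
#' @name task_design
NULL

BALL_ELASTICITY <- c(normal = 0.65, bouncy = 0.85)
P_NORMAL_SET <- c(0.83, 0.67, 0.50)
CATCH_P_NORMAL <- 0.67 # the underlying probability of the final level is not cued

#' Probabilistic cue for a game level
#'
#' Maps the level's normal-ball probability to the explicit cue shown to
#' participants: the projected bouncy-ball percentage and its verbal label.
#'
#' @param p_normal probability of a normal ball; one of 0.83, 0.67, 0.50.
#' @return list with `bouncy_pct` (17, 33 or 50), `label` ("low", "medium" or
#'   "high"), `hawkeye_duration_s` (10) and `bounceometer_lead_s` (3).
#' @examples
#' cue_for_level(0.83) # 17% "low"
#' @export
cue_for_level <- function(p_normal) {
  if (length(p_normal) != 1 || !any(abs(p_normal - P_NORMAL_SET) < 1e-9)) {
    stop("p_normal must be one of 0.83, 0.67, 0.50")
  }
  pct <- round(100 * (1 - p_normal))
  label <- c(`17` = "low", `33` = "medium", `50` = "high")[[as.character(pct)]]
  list(bouncy_pct = pct, label = label,
       hawkeye_duration_s = 10, bounceometer_lead_s = 3)
}

# Partition the 36 cued trials into 5 levels with lengths in {6, 9, 12}.
# Only two multisets work: {6,6,6,6,12} and {6,6,6,9,9}.
level_partitions <- list(c(6, 6, 6, 6, 12), c(6, 6, 6, 9, 9))

# Assign p_normal values so that consecutive levels (including the final
# catch level at CATCH_P_NORMAL) always differ.
assign_probabilities <- function(n_levels) {
  p <- numeric(n_levels)
  prev <- NA_real_
  for (i in seq_len(n_levels)) {
    choices <- P_NORMAL_SET
    if (!is.na(prev)) choices <- setdiff(choices, prev)
    if (i == n_levels) choices <- setdiff(choices, CATCH_P_NORMAL)
    p[i] <- choices[sample.int(length(choices), 1)]
    prev <- p[i]
  }
  p
}

# Per-level bouncy quotas: round((1 - p) * length), then spread at most a
# +-1 adjustment across levels so the block total is exactly 15 bouncy.
solve_quotas <- function(lengths, p_normal, total_bouncy = 15) {
  raw <- (1 - p_normal) * lengths
  q <- round(raw)
  resid <- raw - q
  delta <- total_bouncy - sum(q)
  if (abs(delta) > length(q)) {
    stop("no level composition satisfying the bouncy-ball quota: need ",
         total_bouncy, ", nearest attainable ", sum(q), " +- ", length(q))
  }
  # adjust levels with the largest residual in the needed direction
  while (delta != 0) {
    step <- sign(delta)
    ord <- order(step * resid, decreasing = TRUE)
    adjusted <- FALSE
    for (i in ord) {
      cand <- q[i] + step
      if (cand >= 0 && cand <= lengths[i] && abs(cand - round(raw[i])) <= 1) {
        q[i] <- cand
        resid[i] <- resid[i] - step
        delta <- delta - step
        adjusted <- TRUE
        break
      }
    }
    if (!adjusted) stop("no level composition satisfying the bouncy-ball quota",
                        " (per-level +-1 adjustment exhausted)")
  }
  q
}

#' Generate an experimental block plan
#'
#' Builds a 45-trial volatile sequence: five cueable levels over the first 36
#' trials plus a final 9-trial catch level without cues. Per-level bouncy
#' counts are fixed quotas, `round((1 - p_normal) * length)`, adjusted by at
#' most one trial per level so each block has exactly 30 normal and 15 bouncy
#' balls. The ball ordering depends only on `(seed, sequence_id)`, so control
#' and cued blocks built from the same pair share an identical ball sequence;
#' `block_kind` only toggles the cue annotations.
#'
#' @param seed integer master seed.
#' @param sequence_id which of the three canonical trial-order sequences to
#'   emulate (1, 2 or 3); each shifts the design RNG stream.
#' @param block_kind `"control"` (no cues) or `"cued"`.
#' @return a `block_plan`: list with `block_kind`, `sequence_id`, `seed`,
#'   `levels` (tibble: level_id, length, p_normal, is_catch, n_bouncy) and
#'   `trials` (tibble: trial_index, block_kind, level_id, p_normal, ball_type,
#'   elasticity, cued, bouncy_pct, label).
#' @export
generate_block <- function(seed, sequence_id = 1, block_kind = c("control", "cued")) {
  block_kind <- match.arg(block_kind)
  if (!sequence_id %in% 1:3) stop("sequence_id must be 1, 2 or 3")
  with_seed(derive_seed(seed, "design", sequence_id), {
    lens <- sample(level_partitions, 1)[[1]]
    lens <- sample(lens) # order of level lengths
    lens <- c(lens, 9)   # final catch level
    n_levels <- length(lens)
    p <- c(assign_probabilities(n_levels - 1), CATCH_P_NORMAL)
    quotas <- solve_quotas(lens, p)
    ball_type <- unlist(lapply(seq_len(n_levels), function(i) {
      sample(rep(c("bouncy", "normal"), c(quotas[i], lens[i] - quotas[i])))
    }))
    build_block(block_kind, sequence_id, seed, lens, p, quotas, ball_type)
  })
}

build_block <- function(block_kind, sequence_id, seed, lens, p, quotas, ball_type) {
  n_levels <- length(lens)
  levels <- tibble::tibble(
    level_id = seq_len(n_levels) - 1L,
    length = as.integer(lens),
    p_normal = p,
    is_catch = seq_len(n_levels) == n_levels,
    n_bouncy = as.integer(quotas)
  )
  level_of_trial <- rep(levels$level_id, levels$length)
  p_of_trial <- rep(p, lens)
  cued <- block_kind == "cued" & !rep(levels$is_catch, levels$length)
  cues <- lapply(seq_along(p_of_trial), function(i) {
    if (any(abs(p_of_trial[i] - P_NORMAL_SET) < 1e-9)) cue_for_level(p_of_trial[i])
    else list(bouncy_pct = NA_integer_, label = NA_character_)
  })
  trials <- tibble::tibble(
    trial_index = seq_along(ball_type) - 1L,
    block_kind = block_kind,
    level_id = level_of_trial,
    p_normal = p_of_trial,
    ball_type = ball_type,
    elasticity = unname(BALL_ELASTICITY[ball_type]),
    cued = cued,
    bouncy_pct = ifelse(cued, vapply(cues, `[[`, 0, "bouncy_pct"), NA_integer_),
    label = ifelse(cued, vapply(cues, `[[`, "", "label"), NA_character_)
  )
  structure(
    list(block_kind = block_kind, sequence_id = sequence_id, seed = seed,
         levels = levels, trials = trials),
    class = "block_plan"
  )
}

#' Baseline block: thirty normal-ball trials without cues
#'
#' All baseline balls use standard tennis-ball elasticity (0.65) and follow
#' the same pre- and post-bounce trajectory.
#'
#' @return a `block_plan` with 30 trials, a single level, no cues.
#' @export
make_baseline_block <- function() {
  build_block("baseline", sequence_id = 0L, seed = NA_integer_,
              lens = 30, p = 1.0, quotas = 0L,
              ball_type = rep("normal", 30))
}

# Internal constructor used by make_baseline_block: baseline is exempt from
# the experimental-block invariants, so validate_design special-cases it.

#' Validate a block plan against the design invariants
#'
#' Checks every structural rule of the task design and reports violations as
#' character messages naming the offending trial or level; an empty character
#' vector means the plan is valid. The validator never throws.
#'
#' @param block a `block_plan`.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_design <- function(block) {
  v <- character()
  tr <- block$trials
  lv <- block$levels
  if (block$block_kind == "baseline") {
    if (nrow(tr) != 30) v <- c(v, sprintf("baseline has %d trials, expected 30", nrow(tr)))
    if (any(tr$ball_type != "normal")) v <- c(v, "baseline contains non-normal balls")
    if (any(tr$cued)) v <- c(v, "baseline contains cued trials")
    return(v)
  }
  if (nrow(tr) != 45) v <- c(v, sprintf("block has %d trials, expected 45", nrow(tr)))
  n_bouncy <- sum(tr$ball_type == "bouncy")
  if (n_bouncy != 15) v <- c(v, sprintf("block has %d bouncy trials, expected 15 (quota)", n_bouncy))
  if (sum(tr$ball_type == "normal") != nrow(tr) - n_bouncy) {
    v <- c(v, "ball_type contains values other than normal/bouncy")
  }
  for (i in seq_len(nrow(lv))) {
    len <- lv$length[i]
    if (lv$is_catch[i]) {
      if (len != 9) v <- c(v, sprintf("level %d: catch level length %d != 9", lv$level_id[i], len))
    } else if (!len %in% c(6, 9, 12)) {
      v <- c(v, sprintf("level %d: length %d not in {6,9,12}", lv$level_id[i], len))
    }
    if (!any(abs(lv$p_normal[i] - P_NORMAL_SET) < 1e-9)) {
      v <- c(v, sprintf("level %d: p_normal %.2f not in {0.83,0.67,0.50}", lv$level_id[i], lv$p_normal[i]))
    }
    if (i > 1 && lv$p_normal[i] == lv$p_normal[i - 1]) {
      v <- c(v, sprintf("level %d: p_normal unchanged from previous level", lv$level_id[i]))
    }
  }
  if (!lv$is_catch[nrow(lv)] || any(lv$is_catch[-nrow(lv)])) {
    v <- c(v, "catch level must be the final level and only the final level")
  }
  catch_trials <- tr$level_id == lv$level_id[nrow(lv)]
  if (sum(catch_trials) && any(which(catch_trials) != (nrow(tr) - sum(catch_trials) + 1):nrow(tr))) {
    v <- c(v, "catch-level trials are not the final trials of the block")
  }
  if (any(tr$cued & catch_trials)) v <- c(v, "catch trials must not be cued")
  if (block$block_kind == "control" && any(tr$cued)) v <- c(v, "control block contains cued trials")
  if (block$block_kind == "cued" && any(!tr$cued & !catch_trials)) {
    v <- c(v, "cued block has uncued non-catch trials")
  }
  mism <- which(abs(tr$elasticity - BALL_ELASTICITY[tr$ball_type]) > 1e-12)
  for (i in mism) v <- c(v, sprintf("trial %d: elasticity %.2f inconsistent with ball_type %s",
                                    tr$trial_index[i], tr$elasticity[i], tr$ball_type[i]))
  v
}

#' Longest run of trials with unchanged normal-ball probability
#'
#' @param block a `block_plan`.
#' @return integer run length.
#' @export
max_probability_run <- function(block) {
  r <- rle(block$trials$p_normal)
  max(r$lengths)
}

#' Full study design: baseline plus order-matched control and cued blocks
#'
#' @param seed integer master seed.
#' @param sequence_id canonical sequence (1-3) shared by both experimental blocks.
#' @return list with `baseline`, `control` and `cued` block plans.
#' @export
make_study_design <- function(seed, sequence_id = 1) {
  list(
    baseline = make_baseline_block(),
    control = generate_block(seed, sequence_id, "control"),
    cued = generate_block(seed, sequence_id, "cued")
  )
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf("<block_plan: %s, %d trials, %d levels, sequence %s>\n",
              x$block_kind, nrow(x$trials), nrow(x$levels),
              as.character(x$sequence_id)))
  invisible(x)
}
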