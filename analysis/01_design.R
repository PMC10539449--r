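#!/usr/bin/env Rscript
# Step 1: build and validate the trial-order designs.
#
# Generates the baseline block and the three canonical volatile 45-trial
# sequences (control + cued views of each), checks every design invariant,
# and writes the trial tables under results/design/.

suppressPackageStartupMessages(library(vrracquet))

seed <- 20260924L
out <- "results/design"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat("== Task design ==\n")
baseline <- make_baseline_block()
stopifnot(length(validate_design(baseline)) == 0)
cat(sprintf("baseline: %d normal-ball trials, no cues\n",
            nrow(baseline$trials)))

baseline_tr <- baseline$trials
baseline_tr$sequence_id <- 0L
all_trials <- list(baseline_tr)
for (sid in 1:3) {
  for (kind in c("control", "cued")) {
    b <- generate_block(seed, sid, kind)
    v <- validate_design(b)
    stopifnot(length(v) == 0)
    cat(sprintf(
      "sequence %d (%s): %d trials, levels %s, p_normal %s, max run %d\n",
      sid, kind, nrow(b$trials),
      paste(b$levels$length, collapse = "+"),
      paste(format(b$levels$p_normal), collapse = "/"),
      max_probability_run(b)))
    tr <- b$trials
    tr$sequence_id <- sid
    all_trials[[length(all_trials) + 1]] <- tr
  }
}
design_tab <- do.call(rbind, lapply(all_trials, as.data.frame))
utils::write.csv(design_tab, file.path(out, "trial_plans.csv"),
                 row.names = FALSE)
cat(sprintf("wrote %s (%d rows)\n", file.path(out, "trial_plans.csv"),
            nrow(design_tab)))

# the cue system, as shown to participants
for (p in c(0.83, 0.67, 0.50)) {
  cue <- cue_for_level(p)
  cat(sprintf("p_normal %.2f -> bounceometer '%s' (%d%% bouncy)\n",
              p, cue$label, cue$bouncy_pct))
}
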