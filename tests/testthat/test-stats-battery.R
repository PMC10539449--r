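test_that("the mixed ANOVA matches aov and the textbook SS decomposition", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      tab <- make_outcome_table(n1 = 7 + rep, n2 = 7 + rep,
                                means = rnorm(4, 0, 0.8), sd = 1, seed = rep)
      mine <- mixed_anova_2x2(tab)
      fit <- stats::aov(value ~ group * condition +
                          Error(participant_id / condition), data = tab)
      s <- summary(fit)
      bt <- s[["Error: participant_id"]][[1]]
      wt <- s[["Error: participant_id:condition"]][[1]]
      expect_equal(mine$value[mine$effect == "group"], bt$`F value`[1],
                   tolerance = 1e-10)
      expect_equal(mine$value[mine$effect == "condition"], wt$`F value`[1],
                   tolerance = 1e-10)
      expect_equal(mine$value[mine$effect == "interaction"], wt$`F value`[2],
                   tolerance = 1e-10)
      expect_equal(mine$p[mine$effect == "interaction"], wt$`Pr(>F)`[2],
                   tolerance = 1e-10)
      # direct cell-mean SS oracle (balanced case)
      w <- vrracquet:::complete_wide(tab)
      ss <- oracle_mixed_ss(w[[1]], w[[2]])
      n <- nrow(w[[1]])
      expect_equal(mine$value[mine$effect == "group"],
                   ss$group / (ss$subj / (2 * n - 2)), tolerance = 1e-10)
      expect_equal(mine$value[mine$effect == "interaction"],
                   ss$int / (ss$werr / (2 * n - 2)), tolerance = 1e-10)
      # partial eta squared reproduces F through the SS identity
      pes <- mine$effect_size[mine$effect == "interaction"]
      df_err <- mine$df2[mine$effect == "interaction"]
      expect_equal(pes / (1 - pes) * df_err,
                   mine$value[mine$effect == "interaction"], tolerance = 1e-10)
      # SS identity: total = sum of all effect and error strata
      expect_equal(ss$total, ss$group + ss$subj + ss$cond + ss$int + ss$werr,
                   tolerance = 1e-10)
    }
  })
})

test_that("degenerate constant data are flagged, not crashed on", {
  tab <- make_outcome_table(means = c(3, 3, 3, 3), sd = 0)
  res <- mixed_anova_2x2(tab)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$value)))
})

test_that("interaction type-I error stays near alpha under the null", {
  withr::with_seed(17, {
    n_sim <- 2000
    rej <- 0
    ids <- paste0("p", 1:16)
    grp <- rep(c("ASD", "NT"), each = 8)
    for (i in seq_len(n_sim)) {
      tab <- tibble::tibble(
        participant_id = rep(ids, 2), group = rep(grp, 2),
        condition = rep(c("control", "cued"), each = 16),
        value = rnorm(32))
      p <- mixed_anova_2x2(tab)$p[3]
      if (p < 0.05) rej <- rej + 1
    }
    expect_gt(rej / n_sim, 0.035)
    expect_lt(rej / n_sim, 0.065)
  })
})

test_that("post-hoc families run the right tests with Bonferroni adjustment", {
  tab <- make_outcome_table(n1 = 10, n2 = 10, means = c(2, 0, 0, 0), seed = 2)
  ph <- posthoc_tests(tab)
  expect_equal(nrow(ph), 4)
  expect_true(all(ph$correction == "bonferroni"))
  expect_true(all(ph$statistic_name == "t"))
  # adjusted p = min(4 * raw, 1): recompute one raw test
  w <- vrracquet:::complete_wide(tab)
  raw <- stats::t.test(w[[1]][, 1], w[[2]][, 1], var.equal = FALSE)$p.value
  expect_equal(ph$p[1], min(4 * raw, 1), tolerance = 1e-12)
  # identical paired samples: t = 0, adjusted p = 1
  tab2 <- withr::with_seed(3, {
    ids <- paste0("p", 1:12)
    v <- rnorm(12, rep(c(1, 0), each = 6))
    tibble::tibble(participant_id = rep(ids, 2),
                   group = rep(rep(c("ASD", "NT"), each = 6), 2),
                   condition = rep(c("control", "cued"), each = 12),
                   value = rep(v, 2))
  })
  ph2 <- posthoc_tests(tab2)
  within_rows <- grepl("control vs cued", ph2$effect)
  expect_equal(ph2$value[within_rows], c(0, 0), tolerance = 1e-12)
  expect_equal(ph2$p[within_rows], c(1, 1))
  # nonparametric routing emits U statistics for the between comparisons
  ph3 <- posthoc_tests(tab, nonparametric = TRUE)
  expect_setequal(unique(ph3$statistic_name), c("U", "W"))
})

test_that("Mann-Whitney U equals the exhaustive rank count and U + U' = n1 n2", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      x <- sample(0:8, 7, replace = TRUE)
      y <- sample(0:8, 9, replace = TRUE)
      u <- mann_whitney_u(x, y)
      expect_equal(u, oracle_u(x, y))
      expect_equal(u + mann_whitney_u(y, x), length(x) * length(y))
      # and matches wilcox.test's W statistic
      w <- suppressWarnings(stats::wilcox.test(x, y))$statistic
      expect_equal(unname(w), u)
    }
  })
})

test_that("trait correlations behave like their definitions", {
  tab <- make_outcome_table(n1 = 12, n2 = 12, seed = 5)
  tab$value <- tab$AQ_total # outcome equals the trait itself
  tc <- trait_correlations(tab)
  aq_rows <- grepl("AQ_total", tc$effect)
  expect_equal(tc$value[aq_rows], rep(1, sum(aq_rows)), tolerance = 1e-12)
  # spearman invariant under a monotone transform, equals rank-formula oracle
  tab2 <- make_outcome_table(n1 = 10, n2 = 10, seed = 6)
  tc_a <- trait_correlations(tab2, nonparametric = TRUE)
  tab3 <- tab2; tab3$value <- exp(tab3$value)
  tc_b <- trait_correlations(tab3, nonparametric = TRUE)
  expect_equal(tc_a$value, tc_b$value, tolerance = 1e-12)
  sub <- tab2[tab2$condition == "control", ]
  rx <- rank(sub$AQ_total); ry <- rank(sub$value)
  oracle_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(tc_a$value[tc_a$effect == "value ~ AQ_total (control)" |
                            grepl("AQ_total \\(control\\)", tc_a$effect)][1],
               oracle_rho, tolerance = 1e-12)
})

test_that("assumption checks route outcomes and tolerate degenerate cells", {
  # large normal samples rarely fail Shapiro-Wilk
  withr::with_seed(23, {
    fails <- 0
    for (i in 1:60) {
      if (stats::shapiro.test(rnorm(5000))$p.value < 0.05) fails <- fails + 1
    }
    expect_lte(fails / 60, 0.06 + 0.06) # near the nominal alpha
  })
  # equal-variance groups: Levene rejection near alpha
  withr::with_seed(29, {
    rej <- 0
    for (i in 1:500) {
      tab <- make_outcome_table(n1 = 12, n2 = 12, seed = 2900 + i)
      if (levene_test(tab)$p < 0.05) rej <- rej + 1
    }
    expect_gt(rej / 500, 0.02); expect_lt(rej / 500, 0.09)
  })
  # skewed data flip the nonnormal flag
  tab <- make_outcome_table(n1 = 15, n2 = 15, seed = 7)
  tab$value <- exp(2 * tab$value)
  expect_true(assumption_checks(tab)$nonnormal)
  # constant cell: degenerate, no crash
  tabc <- make_outcome_table(means = c(1, 1, 1, 1), sd = 0)
  chk <- assumption_checks(tabc)
  expect_true(all(chk$shapiro$degenerate))
})

test_that("levene agrees with the car reference implementation", {
  skip_if_not_installed("car")
  tab <- make_outcome_table(n1 = 11, n2 = 13, means = c(0, 0, 1, 1),
                            sd = 1.5, seed = 8)
  agg <- stats::aggregate(value ~ participant_id + group, data = tab, FUN = mean)
  ref <- car::leveneTest(value ~ factor(group), data = agg, center = mean)
  got <- levene_test(tab)
  expect_equal(got$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("the full battery mirrors the study's report structure", {
  withr::with_seed(31, {
    coh <- simulate_cohort(6, seed = 60, detail = "metrics", contact = TRUE)
    rows <- list()
    for (p in coh$participants) for (bk in c("baseline", "control", "cued")) {
      tt <- p$blocks[[bk]]$trial_truth
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = p$participant_id, group = p$group, block_kind = bk,
        n_trials = nrow(tt),
        interception_rate = 100 * mean(tt$intercepted),
        peak_velocity = mean(tt$v_peak), rom = mean(tt$rom),
        median_onset = 1.33, mean_duration = 0.4,
        mean_pitch = mean(tt$pitch_fix), sd_pitch = sd(tt$pitch_fix),
        n_gaze_trials = nrow(tt))
    }
    summ <- dplyr::bind_rows(rows)
    summ <- dplyr::left_join(summ,
      coh$manifest[, c("participant_id", "AQ_total", "IUS_total")],
      by = "participant_id")
    res <- run_full_battery(summ)
    expect_equal(sort(unique(res$anovas$outcome)),
                 sort(c("interception_rate", "peak_velocity", "rom",
                        "median_onset", "mean_duration", "mean_pitch",
                        "sd_pitch")))
    expect_equal(nrow(res$anovas), 21) # 7 outcomes x 3 effects
    expect_false(is.null(res$manipulation_check))
    # manipulation check: control pitch above baseline pitch
    expect_gt(res$manipulation_check$mean_difference, 0)
    expect_true(all(res$anovas$p >= 0 & res$anovas$p <= 1, na.rm = TRUE))
    expect_true(all(res$anovas$effect_size >= 0 & res$anovas$effect_size <= 1,
                    na.rm = TRUE))
    expect_true(all(res$anovas$bf10 > 0, na.rm = TRUE))
    # correlations present for both traits and conditions
    expect_equal(nrow(res$correlations), 7 * 4)
  })
})
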