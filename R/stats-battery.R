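#' Inferential battery
#'
#' The study's statistical layer: 2 (group: ASD vs NT) x 2 (condition:
#' control vs cued) mixed-model ANOVAs with partial eta squared and Bayes
#' factors, Bonferroni-corrected post-hoc t tests (Mann-Whitney U when the
#' outcome failed normality), Pearson/Spearman trait correlations,
#' Shapiro-Wilk and Levene assumption checks, JZS Bayes factors for t
#' tests, a BIC-approximation Bayes factor for ANOVA effects, and the
#' noncentral-F a-priori power computation.
#'
#' Outcome tables are in long format: one row per participant x condition
#' with columns `participant_id`, `group`, `condition`, `value` (plus
#' `AQ_total`, `IUS_total` for correlations).
#'
#' @name stats_battery
NULL

# Listwise-complete wide split of a long outcome table. Returns a list with
# per-group matrices of (control, cued) values.
complete_wide <- function(table) {
  w <- tidyr::pivot_wider(table[, c("participant_id", "group", "condition", "value")],
                          names_from = "condition", values_from = "value")
  w <- w[stats::complete.cases(w), ]
  conds <- sort(setdiff(names(w), c("participant_id", "group")))
  if (length(conds) != 2) stop("expected exactly 2 conditions, got: ",
                               paste(conds, collapse = ", "))
  groups <- sort(unique(w$group))
  if (length(groups) != 2) stop("expected exactly 2 groups")
  out <- lapply(groups, function(g) as.matrix(w[w$group == g, conds]))
  names(out) <- groups
  attr(out, "conditions") <- conds
  out
}

#' Two-by-two mixed-model ANOVA
#'
#' Classical sums-of-squares decomposition for one between-subjects factor
#' (group) and one within-subjects factor (condition): the group effect is
#' tested against the subjects-within-groups error, condition and the
#' group-by-condition interaction against the condition-by-subjects error.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)` using each
#' effect's own error term. Unequal group sizes use the unweighted
#' (type-III) cell means. Participants missing a condition are dropped
#' listwise. Bayes factors are BIC approximations comparing the model with
#' and without the effect (see [bf_bic()]).
#'
#' @param table long outcome table.
#' @param outcome optional outcome name recorded in the results.
#' @return tibble with one row per effect (group, condition, interaction):
#'   statistic_name, value (F), df1, df2, p, effect_size (partial eta
#'   squared), bf10, degenerate flag.
#' @export
mixed_anova_2x2 <- function(table, outcome = NA_character_) {
  wide <- complete_wide(table)
  g1 <- wide[[1]]; g2 <- wide[[2]]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 complete participants per group")
  # per-subject sum and difference recast the design as two univariate models
  s1 <- rowMeans(g1); s2 <- rowMeans(g2)        # subject means (between part)
  d1 <- g1[, 2] - g1[, 1]; d2 <- g2[, 2] - g2[, 1] # condition differences (within part)
  k <- 2 # conditions
  # between-subjects stratum (on subject means, scaled by k)
  gm_u <- (mean(s1) + mean(s2)) / 2 # unweighted grand mean
  ss_group <- k * (mean(s1) - mean(s2))^2 / (1 / n1 + 1 / n2)
  ss_subj <- k * (sum((s1 - mean(s1))^2) + sum((s2 - mean(s2))^2))
  df_subj <- n1 + n2 - 2
  # within-subjects stratum (on condition differences, scaled back by k)
  ss_cond <- (mean(d1) + mean(d2))^2 / 4 / (1 / n1 + 1 / n2) * k
  ss_int <- (mean(d1) - mean(d2))^2 / 4 / (1 / n1 + 1 / n2) * k
  ss_werr <- (sum((d1 - mean(d1))^2) + sum((d2 - mean(d2))^2)) / k
  df_werr <- n1 + n2 - 2
  degenerate <- ss_subj < 1e-12 || ss_werr < 1e-12
  f_of <- function(ss_e, ss_err, df_err) {
    if (ss_err < 1e-12) return(NA_real_)
    (ss_e / 1) / (ss_err / df_err)
  }
  row <- function(effect, ss_e, ss_err, df_err, bf) {
    Fv <- f_of(ss_e, ss_err, df_err)
    tibble::tibble(
      outcome = outcome, effect = effect, statistic_name = "F",
      value = Fv, df1 = 1, df2 = df_err,
      p = if (is.na(Fv)) NA_real_ else stats::pf(Fv, 1, df_err, lower.tail = FALSE),
      effect_size = if (ss_e + ss_err < 1e-12) NA_real_ else ss_e / (ss_e + ss_err),
      bf10 = bf, correction = "none", degenerate = degenerate
    )
  }
  n_eff <- n1 + n2
  dplyr::bind_rows(
    row("group", ss_group, ss_subj, df_subj,
        bf_bic(ss_group, ss_subj, df_extra = 1, n = n_eff)),
    row("condition", ss_cond, ss_werr, df_werr,
        bf_bic(ss_cond, ss_werr, df_extra = 1, n = n_eff)),
    row("interaction", ss_int, ss_werr, df_werr,
        bf_bic(ss_int, ss_werr, df_extra = 1, n = n_eff))
  )
}

#' Post-hoc comparisons with Bonferroni correction
#'
#' The family comprises the between-group comparison within each condition
#' and the within-group comparison across conditions. Between-group tests
#' are independent-samples t tests, or Mann-Whitney U when `nonparametric`;
#' within-group tests are paired t tests (Wilcoxon signed-rank when
#' nonparametric). Raw p values are multiplied by the family size and
#' capped at 1.
#'
#' @param table long outcome table.
#' @param outcome optional outcome name.
#' @param nonparametric route the family to rank-based tests.
#' @return tibble of StatResult rows (one per comparison).
#' @export
posthoc_tests <- function(table, outcome = NA_character_, nonparametric = FALSE) {
  wide <- complete_wide(table)
  conds <- attr(wide, "conditions")
  groups <- names(wide)
  res <- list()
  # degenerate (zero-variance) comparisons report no evidence: t = 0, p = 1
  safe_t <- function(x, y, paired = FALSE) {
    degen <- list(statistic = c(t = 0), parameter = c(df = length(x) - 1),
                  p.value = 1)
    out <- tryCatch(stats::t.test(x, y, paired = paired, var.equal = FALSE),
                    error = function(e) degen)
    if (!is.finite(out$statistic)) degen else out
  }
  add <- function(comparison, stat_name, value, df, p, es, n_eff, paired) {
    res[[length(res) + 1]] <<- tibble::tibble(
      outcome = outcome, effect = comparison, statistic_name = stat_name,
      value = value, df1 = df, df2 = NA_real_, p = p, effect_size = es,
      bf10 = if (stat_name == "t") bf_ttest_jzs(value, n_eff,
                                                paired = paired) else NA_real_,
      correction = "bonferroni", degenerate = FALSE
    )
  }
  for (ci in 1:2) {
    x <- wide[[1]][, ci]; y <- wide[[2]][, ci]
    if (length(x) < 3 || length(y) < 3) stop("n < 3 in a post-hoc cell")
    nm <- sprintf("%s vs %s (%s)", groups[1], groups[2], conds[ci])
    if (nonparametric) {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      r_es <- 1 - 2 * wt$statistic / (length(x) * length(y)) # rank-biserial
      add(nm, "U", unname(wt$statistic), NA_real_, wt$p.value, unname(r_es),
          c(length(x), length(y)), FALSE)
    } else {
      tt <- safe_t(x, y)
      add(nm, "t", unname(tt$statistic), unname(tt$parameter), tt$p.value,
          NA_real_, c(length(x), length(y)), FALSE)
    }
  }
  for (gi in 1:2) {
    x <- wide[[gi]][, 1]; y <- wide[[gi]][, 2]
    if (length(x) < 3) stop("n < 3 in a post-hoc cell")
    nm <- sprintf("%s vs %s (%s)", conds[1], conds[2], groups[gi])
    if (nonparametric) {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      add(nm, "W", unname(wt$statistic), NA_real_, wt$p.value, NA_real_,
          length(x), TRUE)
    } else {
      tt <- safe_t(x, y, paired = TRUE)
      add(nm, "t", unname(tt$statistic), unname(tt$parameter), tt$p.value,
          NA_real_, length(x), TRUE)
    }
  }
  out <- dplyr::bind_rows(res)
  out$p <- pmin(out$p * nrow(out), 1)
  out
}

#' Mann-Whitney U statistic (count definition)
#'
#' Number of pairs (x_i, y_j) with x_i > y_j, counting ties as one half.
#' Satisfies `U + U' = n1 * n2`.
#'
#' @param x,y numeric samples.
#' @return U.
#' @export
mann_whitney_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Trait correlations
#'
#' Correlates AQ and IUS-S totals with the outcome within each condition;
#' Pearson's r by default, Spearman's rho when `nonparametric`. Bayes
#' factors convert the correlation to its t statistic and apply the JZS
#' integral.
#'
#' @param table long outcome table carrying `AQ_total` and `IUS_total`.
#' @param outcome optional outcome name.
#' @param nonparametric use Spearman's rho.
#' @return tibble of StatResult rows (trait x condition).
#' @export
trait_correlations <- function(table, outcome = NA_character_,
                               nonparametric = FALSE) {
  method <- if (nonparametric) "spearman" else "pearson"
  res <- list()
  for (cond in sort(unique(table$condition))) {
    sub <- table[table$condition == cond, ]
    for (trait in c("AQ_total", "IUS_total")) {
      ok <- stats::complete.cases(sub[[trait]], sub$value)
      x <- sub[[trait]][ok]; y <- sub$value[ok]
      n <- length(x)
      if (n < 4) stop("need at least 4 complete pairs")
      degenerate <- stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12
      if (degenerate) {
        r <- NA_real_; p <- NA_real_; bf <- NA_real_
      } else {
        ct <- suppressWarnings(stats::cor.test(x, y, method = method))
        r <- unname(ct$estimate); p <- ct$p.value
        tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
        bf <- bf_ttest_jzs(tstat, n - 1, paired = TRUE)
      }
      res[[length(res) + 1]] <- tibble::tibble(
        outcome = outcome, effect = sprintf("%s ~ %s (%s)", outcome, trait, cond),
        statistic_name = if (nonparametric) "rho" else "r",
        value = r, df1 = n - 2, df2 = NA_real_, p = p, effect_size = r,
        bf10 = bf, correction = "none", degenerate = degenerate
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk per group x condition cell and Levene's test (centre =
#' mean, on the per-subject condition means) across groups. An outcome is
#' routed to nonparametric follow-ups iff any cell's Shapiro-Wilk p falls
#' below `alpha`.
#'
#' @param table long outcome table.
#' @param outcome optional outcome name.
#' @param alpha routing threshold (default 0.05).
#' @return list with `shapiro` (tibble per cell), `levene` (tibble),
#'   `nonnormal` and `heteroscedastic` flags.
#' @export
assumption_checks <- function(table, outcome = NA_character_, alpha = 0.05) {
  cells <- split(table$value,
                 interaction(table$group, table$condition, drop = TRUE))
  sw <- lapply(names(cells), function(nm) {
    x <- cells[[nm]][!is.na(cells[[nm]])]
    if (length(x) < 3 || stats::sd(x) < 1e-12) {
      tibble::tibble(cell = nm, W = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      s <- stats::shapiro.test(x)
      tibble::tibble(cell = nm, W = unname(s$statistic), p = s$p.value,
                     degenerate = FALSE)
    }
  })
  sw <- dplyr::bind_rows(sw)
  lev <- levene_test(table)
  list(outcome = outcome, shapiro = sw, levene = lev,
       nonnormal = any(sw$p < alpha, na.rm = TRUE),
       heteroscedastic = isTRUE(lev$p < alpha))
}

#' Levene's test for homogeneity of variance (centre = mean)
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group mean, pooling conditions within participant first.
#'
#' @param table long outcome table.
#' @return tibble with F, df1, df2, p.
#' @export
levene_test <- function(table) {
  agg <- stats::aggregate(value ~ participant_id + group, data = table,
                          FUN = mean)
  groups <- split(agg$value, agg$group)
  absdev <- unlist(lapply(groups, function(x) abs(x - mean(x))))
  grp <- factor(rep(names(groups), vapply(groups, length, 0L)))
  fit <- stats::aov(absdev ~ grp)
  an <- summary(fit)[[1]]
  tibble::tibble(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                 p = an$`Pr(>F)`[1])
}
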