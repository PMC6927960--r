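#' Per-subject response-time cell means
#'
#' Computes, for every subject, the mean stage-2 RT by the current trial's
#' transition (common, rare) and the mean stage-1 RT by the previous
#' trial's outcome (reward, no-reward). Stage-1 means use pairs of adjacent
#' trials whose previous trial was fully completed (so its outcome is
#' defined) and whose current stage-1 response was given. Only completed
#' responses enter; no outlier trimming is applied.
#'
#' @param cohort A `twostep_cohort`.
#' @return A data.frame, one row per subject: `rt2_common`, `rt2_rare`,
#'   `rt1_reward`, `rt1_noreward` (ms) with matching cell counts `n2_*`,
#'   `n1_*`; empty cells are `NA` with count 0.
#' @export
rt_cell_means <- function(cohort) {
  stopifnot(inherits(cohort, "twostep_cohort"))
  tr <- cohort$trials[order(cohort$trials$subject_id, cohort$trials$trial), ]

  cell <- function(x) {
    if (length(x)) c(mean(x), length(x)) else c(NA_real_, 0)
  }
  per_subject <- split(tr, tr$subject_id)
  rows <- lapply(per_subject, function(d) {
    ok2 <- !is.na(d$s2_rt_ms)
    common <- cell(d$s2_rt_ms[ok2 & d$transition == "common"])
    rare <- cell(d$s2_rt_ms[ok2 & d$transition == "rare"])

    n <- nrow(d)
    prev_done <- d$missed_stage[-n] == "none"
    adjacent <- d$trial[-1] == d$trial[-n] + 1L
    cur_rt <- d$s1_rt_ms[-1]
    prev_rwd <- d$reward[-n]
    use <- prev_done & adjacent & !is.na(cur_rt)
    after_r <- cell(cur_rt[use & prev_rwd == 1L])
    after_n <- cell(cur_rt[use & prev_rwd == 0L])

    data.frame(
      subject_id = d$subject_id[1], group = d$group[1],
      severity = d$severity[1],
      rt2_common = common[1], n2_common = common[2],
      rt2_rare = rare[1], n2_rare = rare[2],
      rt1_reward = after_r[1], n1_reward = after_r[2],
      rt1_noreward = after_n[1], n1_noreward = after_n[2],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# 2 x 2 mixed-design ANOVA on per-subject cell means via the
# sum/difference-score decomposition (Type III / unweighted means, matching
# SPSS-style reporting): with two within levels the interaction F is the
# squared pooled t on difference scores, the within main effect tests the
# unweighted mean of the group difference scores, and the between main
# effect is a squared pooled t on subject means. All effects have
# df (1, N - 2); partial eta squared follows from F * df1 / (F * df1 + df2).
mixed_anova_2x2 <- function(y1, y2, group) {
  stopifnot(length(y1) == length(y2), length(group) == length(y1))
  ok <- stats::complete.cases(y1, y2, group)
  y1 <- y1[ok]; y2 <- y2[ok]; group <- group[ok]
  levs <- sort(unique(group))
  stopifnot(length(levs) == 2)
  i1 <- group == levs[1]; i2 <- group == levs[2]
  n1 <- sum(i1); n2 <- sum(i2); N <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  d <- y2 - y1
  s <- (y1 + y2) / 2

  pooled_ms <- function(x) {
    (sum((x[i1] - mean(x[i1]))^2) + sum((x[i2] - mean(x[i2]))^2)) / (N - 2)
  }
  ms_d <- pooled_ms(d)
  ms_s <- pooled_ms(s)
  inv_n <- 1 / n1 + 1 / n2

  f_of <- function(est, var_est) {
    if (var_est > 0) return(est^2 / var_est)
    if (est == 0) 0 else Inf   # zero effect with zero error is a true null
  }
  F_int <- f_of(mean(d[i1]) - mean(d[i2]), ms_d * inv_n)
  F_within <- f_of((mean(d[i1]) + mean(d[i2])) / 2, ms_d * inv_n / 4)
  F_between <- f_of(mean(s[i1]) - mean(s[i2]), ms_s * inv_n)

  df2 <- N - 2
  mk <- function(effect, F) {
    data.frame(effect = effect, F = F, df1 = 1, df2 = df2,
               p = stats::pf(F, 1, df2, lower.tail = FALSE),
               eta_p2 = F / (F + df2), stringsAsFactors = FALSE)
  }
  list(
    table = rbind(mk("within", F_within), mk("between", F_between),
                  mk("interaction", F_int)),
    groups = levs, n = c(n1, n2), d = d, s = s, group = group
  )
}

# Pooled-variance two-sample t with Cohen's d_s (Welch variant optional).
two_sample_t <- function(x1, x2, welch = FALSE) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  d_s <- (mean(x1) - mean(x2)) / sqrt(sp2)
  if (welch) {
    ht <- stats::t.test(x1, x2)
  } else {
    ht <- stats::t.test(x1, x2, var.equal = TRUE)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d_s = d_s)
}

# Paired t with Cohen's d_z = mean(diff) / sd(diff) = t / sqrt(n).
paired_t <- function(diff) {
  n <- length(diff)
  sdd <- stats::sd(diff)
  if (sdd == 0) {
    message("paired contrast: zero variance in difference scores; ",
            "t is degenerate")
    return(list(t = Inf * sign(mean(diff)), df = n - 1, p = 0, d_z = Inf,
                degenerate = TRUE))
  }
  t <- mean(diff) / (sdd / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), n - 1),
       d_z = mean(diff) / sdd, degenerate = FALSE)
}

#' Mixed ANOVA: stage-2 RT by current transition and group
#'
#' Two-factor mixed-design ANOVA on per-subject stage-2 RT cell means
#' (within: transition common/rare; between: group), with F, df, p and
#' partial eta squared per effect. Rare-transition slowing indexes
#' model-based control, so the interaction asks whether that slowing is
#' smaller in one group. Post-hoc: pooled-variance two-sample t on the
#' per-subject (rare - common) difference scores with Cohen's d_s.
#'
#' @param cohort A `twostep_cohort`.
#' @param welch Use the Welch two-sample t for the post-hoc contrast.
#' @return Object of class `mixed_anova` with the effects `table`,
#'   `posthoc`, per-group difference-score summaries, cell means, and the
#'   number of subjects dropped for empty cells.
#' @export
rt2_transition_anova <- function(cohort, welch = FALSE) {
  cells <- rt_cell_means(cohort)
  usable <- !is.na(cells$rt2_common) & !is.na(cells$rt2_rare)
  if (any(!usable)) {
    message(sum(!usable), " subject(s) dropped: empty transition cell")
  }
  cells <- cells[usable, ]
  an <- mixed_anova_2x2(cells$rt2_common, cells$rt2_rare, cells$group)
  an$table$effect <- c("transition", "group", "transition:group")
  i1 <- an$group == an$groups[1]
  ph <- two_sample_t(an$d[i1], an$d[!i1], welch = welch)
  diff_by_group <- data.frame(
    group = an$groups,
    mean_diff = c(mean(an$d[i1]), mean(an$d[!i1])),
    sd_diff = c(stats::sd(an$d[i1]), stats::sd(an$d[!i1])),
    n = an$n, stringsAsFactors = FALSE
  )
  structure(
    list(table = an$table,
         posthoc = data.frame(
           contrast = sprintf("(rare - common): %s vs %s",
                              an$groups[1], an$groups[2]),
           t = ph$t, df = ph$df, p = ph$p, d_s = ph$d_s,
           stringsAsFactors = FALSE),
         diff_by_group = diff_by_group,
         cell_means = c(common = mean(cells$rt2_common),
                        rare = mean(cells$rt2_rare)),
         n_dropped = sum(!usable), cells = cells,
         within = "transition"),
    class = "mixed_anova"
  )
}

#' Mixed ANOVA: stage-1 RT by previous outcome and group
#'
#' Two-factor mixed-design ANOVA on per-subject stage-1 RT cell means
#' (within: previous outcome reward/no-reward; between: group). Post-loss
#' speeding appears as faster first-stage choices after a non-reward.
#' Post-hoc: paired t (reward vs no-reward) within each group with Cohen's
#' d_z.
#'
#' @param cohort A `twostep_cohort`.
#' @return Object of class `mixed_anova`; `posthoc` has one row per group
#'   (positive t = slower after reward, i.e. post-loss speeding).
#' @export
rt1_outcome_anova <- function(cohort) {
  cells <- rt_cell_means(cohort)
  usable <- !is.na(cells$rt1_reward) & !is.na(cells$rt1_noreward)
  if (any(!usable)) {
    message(sum(!usable), " subject(s) dropped: empty outcome cell")
  }
  cells <- cells[usable, ]
  an <- mixed_anova_2x2(cells$rt1_reward, cells$rt1_noreward, cells$group)
  an$table$effect <- c("prev_outcome", "group", "prev_outcome:group")
  ph <- lapply(an$groups, function(gr) {
    diff <- cells$rt1_reward[cells$group == gr] -
      cells$rt1_noreward[cells$group == gr]
    res <- paired_t(diff)
    data.frame(contrast = sprintf("%s: reward vs no-reward", gr),
               t = res$t, df = res$df, p = res$p, d_z = res$d_z,
               mean_diff = mean(diff), stringsAsFactors = FALSE)
  })
  structure(
    list(table = an$table, posthoc = do.call(rbind, ph),
         cell_means = c(reward = mean(cells$rt1_reward),
                        noreward = mean(cells$rt1_noreward)),
         n_dropped = sum(!usable), cells = cells,
         within = "prev_outcome"),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA (within: %s, between: group)\n", x$within))
  tab <- x$table
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  tab$eta_p2 <- round(tab$eta_p2, 3)
  print(tab, row.names = FALSE)
  cat("post-hoc:\n")
  ph <- x$posthoc
  ph$t <- round(ph$t, 2); ph$p <- signif(ph$p, 3)
  print(ph, row.names = FALSE)
  invisible(x)
}

#' Correlation between gambling severity and post-loss speeding
#'
#' Pearson correlation, within problem gamblers, between the DSM-style
#' severity count and the per-subject stage-1 RT difference
#' (mean RT after reward - mean RT after non-reward; positive values mean
#' faster responding after a loss). p is two-sided from
#' t = r sqrt((n - 2) / (1 - r^2)).
#'
#' @param cohort A `twostep_cohort` containing PG subjects with severity.
#' @return List with `r`, `p`, `n`, `t`, `df` and the per-subject scores.
#' @export
severity_rt_correlation <- function(cohort) {
  cells <- rt_cell_means(cohort)
  pg <- cells[cells$group == "PG" & !is.na(cells$rt1_reward) &
                !is.na(cells$rt1_noreward) & !is.na(cells$severity), ]
  if (nrow(pg) < 3) stop("need at least 3 PG subjects with defined cells")
  speedup <- pg$rt1_reward - pg$rt1_noreward
  if (stats::sd(speedup) == 0 || stats::sd(pg$severity) == 0) {
    stop("zero variance in severity or RT difference")
  }
  ct <- stats::cor.test(pg$severity, speedup, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pg),
       t = unname(ct$statistic), df = unname(ct$parameter),
       scores = data.frame(subject_id = pg$subject_id,
                           severity = pg$severity, speedup = speedup))
}
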