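# Deterministic per-subject trials whose cell means are exact: rt2 depends
# only on the transition, rt1 on the previous reward.
fx_rt_subject <- function(id, group, rt2_common, rt2_rare,
                          rt1_after_r, rt1_after_n, n = 12, severity = 0) {
  s1 <- rep(0L, n)
  s2s <- rep(c(0L, 1L), length.out = n)       # alternates common/rare
  rwd <- rep(c(1L, 0L), length.out = n)        # alternates reward/no-reward
  prev_r <- c(NA, rwd[-n])
  rt1 <- ifelse(is.na(prev_r), 500, ifelse(prev_r == 1, rt1_after_r,
                                           rt1_after_n))
  rt2 <- ifelse(s2s == 0L, rt2_common, rt2_rare)
  fx_trials(id, s1, s2s, s2c = rep(0:1, length.out = n), rwd,
            rt1 = rt1, rt2 = rt2, group = group, severity = severity)
}

test_that("cell means respect completion and adjacency conventions", {
  tr <- fx_trials("c1", s1 = rep(0, 6), s2s = c(0, 1, 0, 1, 0, 0),
                  s2c = rep(0, 6), rwd = c(1, 0, 1, 1, 0, 1),
                  rt1 = c(400, 410, 420, 430, 440, 450),
                  rt2 = c(600, 610, 620, 630, 640, 650),
                  missed = c("none", "none", "stage2", "none", "none",
                             "none"))
  cells <- rt_cell_means(fx_cohort(tr))
  # stage-2 means exclude the missed trial (index 2)
  expect_equal(cells$rt2_common, mean(c(600, 640, 650)))
  expect_equal(cells$rt2_rare, mean(c(610, 630)))
  expect_equal(cells$n2_common, 3)
  # stage-1 means require a fully completed previous trial: trial 3 follows
  # the stage2-missed trial 2 and is excluded
  expect_equal(cells$rt1_reward, mean(c(410, 440)))   # after trials 0 and 3
  expect_equal(cells$rt1_noreward, mean(c(420, 450))) # after trials 1 and 4
})

test_that("mixed ANOVA matches the classical sums-of-squares oracle", {
  # balanced 4-subject integer fixture, 2 per group
  y_common <- c(500, 520, 510, 530)
  y_rare <- c(540, 580, 530, 534)
  grp <- c("CP", "CP", "PG", "PG")
  co <- fx_cohort(do.call(rbind, lapply(1:4, function(i) {
    fx_rt_subject(sprintf("s%d", i), grp[i], y_common[i], y_rare[i],
                  450, 430)
  })))
  an <- rt2_transition_anova(co)
  orc <- oracle_mixed_anova(y_common, y_rare, grp)
  tab <- an$table
  expect_equal(tab$F[tab$effect == "transition"], orc$F_within)
  expect_equal(tab$F[tab$effect == "group"], orc$F_between)
  expect_equal(tab$F[tab$effect == "transition:group"], orc$F_int)
  expect_equal(tab$eta_p2[tab$effect == "transition"], orc$eta_within)
  expect_equal(tab$eta_p2[tab$effect == "group"], orc$eta_between)
  expect_equal(tab$eta_p2[tab$effect == "transition:group"], orc$eta_int)
  expect_true(all(tab$df1 == 1) && all(tab$df2 == 2))
  # zero within-effect: equal cell means give F = 0
  co0 <- fx_cohort(do.call(rbind, lapply(1:4, function(i) {
    fx_rt_subject(sprintf("s%d", i), grp[i], y_common[i], y_common[i],
                  450, 430)
  })))
  an0 <- rt2_transition_anova(co0)
  expect_equal(an0$table$F[an0$table$effect == "transition"], 0)
})

test_that("effect sizes satisfy their defining formulas", {
  set.seed(41)
  y1 <- round(rnorm(10, 500, 20)); y2 <- y1 + round(rnorm(10, 30, 15))
  grp <- rep(c("CP", "PG"), each = 5)
  co <- fx_cohort(do.call(rbind, lapply(1:10, function(i) {
    fx_rt_subject(sprintf("s%d", i), grp[i], y1[i], y2[i],
                  460 + 3 * i, 430 - 2 * i)
  })))
  an <- rt2_transition_anova(co)
  d <- y2 - y1
  d1 <- d[grp == "CP"]; d2 <- d[grp == "PG"]
  sp <- sqrt((4 * var(d1) + 4 * var(d2)) / 8)
  expect_equal(an$posthoc$d_s, (mean(d1) - mean(d2)) / sp)
  # d_z = paired t / sqrt(n) for the outcome post-hoc
  an1 <- rt1_outcome_anova(co)
  ph <- an1$posthoc[grepl("CP", an1$posthoc$contrast), ]
  expect_equal(ph$d_z, ph$t / sqrt(5))
  # eta_p2 within [0, 1]
  expect_true(all(an$table$eta_p2 >= 0 & an$table$eta_p2 <= 1))
})

test_that("between F equals squared two-sample t on subject means", {
  set.seed(43)
  y1 <- rnorm(12, 500, 25); y2 <- y1 + rnorm(12, 20, 10)
  grp <- rep(c("CP", "PG"), each = 6)
  an <- twosteptask:::mixed_anova_2x2(y1, y2, grp)
  s <- (y1 + y2) / 2
  tt <- t.test(s[grp == "CP"], s[grp == "PG"], var.equal = TRUE)
  expect_equal(an$table$F[an$table$effect == "between"],
               unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("ANOVA statistics are invariant to RT shifts", {
  set.seed(47)
  y1 <- rnorm(8, 500, 20); y2 <- y1 + rnorm(8, 25, 12)
  grp <- rep(c("CP", "PG"), each = 4)
  a <- twosteptask:::mixed_anova_2x2(y1, y2, grp)
  b <- twosteptask:::mixed_anova_2x2(y1 + 123, y2 + 123, grp)
  expect_equal(a$table$F, b$table$F, tolerance = 1e-10)
})

test_that("noiseless paired contrasts are flagged as degenerate", {
  grp <- rep(c("PG", "CP"), each = 3)
  co <- fx_cohort(do.call(rbind, lapply(1:6, function(i) {
    # every PG exactly 30 ms faster after non-reward, noiseless
    if (grp[i] == "PG") {
      fx_rt_subject(sprintf("s%d", i), "PG", 600, 640, 460, 430)
    } else {
      fx_rt_subject(sprintf("s%d", i), "CP", 600, 640, 445, 445)
    }
  })))
  expect_message(an <- rt1_outcome_anova(co), "zero variance")
  ph <- an$posthoc[grepl("PG", an$posthoc$contrast), ]
  expect_true(is.infinite(ph$t) && ph$t > 0)
  # with small noise the PG contrast is large and positive
  set.seed(51)
  co2 <- fx_cohort(do.call(rbind, lapply(1:6, function(i) {
    fast <- if (grp[i] == "PG") 30 else 0
    fx_rt_subject(sprintf("s%d", i), grp[i], 600, 640,
                  460 + rnorm(1, 0, 3), 460 - fast + rnorm(1, 0, 3))
  })))
  an2 <- rt1_outcome_anova(co2)
  ph2 <- an2$posthoc[grepl("PG", an2$posthoc$contrast), ]
  expect_gt(ph2$d_z, 2)
})

test_that("severity correlation reproduces the textbook formula", {
  sev <- c(3, 5, 7, 9)
  diffs <- c(10, 20, 30, 20)
  co <- fx_cohort(do.call(rbind, lapply(1:4, function(i) {
    fx_rt_subject(sprintf("pg%d", i), "PG", 600, 640,
                  rt1_after_r = 500, rt1_after_n = 500 - diffs[i],
                  severity = sev[i])
  })))
  res <- severity_rt_correlation(co)
  r_hand <- oracle_pearson(sev, diffs)
  expect_equal(res$r, r_hand, tolerance = 1e-10)
  expect_equal(r_hand, 40 / sqrt(20 * 200), tolerance = 1e-10)
  # p from t = r sqrt((n-2)/(1-r^2))
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 2), tolerance = 1e-10)
  expect_equal(res$n, 4)

  # perfectly linear difference scores give r = 1
  co2 <- fx_cohort(do.call(rbind, lapply(1:4, function(i) {
    fx_rt_subject(sprintf("pg%d", i), "PG", 600, 640,
                  500, 500 - 5 * sev[i], severity = sev[i])
  })))
  expect_equal(severity_rt_correlation(co2)$r, 1, tolerance = 1e-10)

  # zero variance errors
  co3 <- fx_cohort(do.call(rbind, lapply(1:4, function(i) {
    fx_rt_subject(sprintf("pg%d", i), "PG", 600, 640, 500, 480,
                  severity = sev[i])
  })))
  expect_error(severity_rt_correlation(co3), "zero variance")
})

test_that("subjects with empty cells are dropped with a message", {
  grp <- c("CP", "CP", "PG", "PG", "PG")
  rows <- lapply(1:5, function(i) {
    fx_rt_subject(sprintf("s%d", i), grp[i], 600 + i, 640 + 3 * i,
                  460 + i, 430 - i)
  })
  # subject 5: only common transitions -> empty rare cell
  rows[[5]] <- fx_trials("s5", s1 = rep(0, 6), s2s = rep(0, 6),
                         s2c = rep(0:1, 3), rwd = rep(c(1, 0), 3),
                         group = "PG")
  co <- fx_cohort(do.call(rbind, rows))
  expect_message(an <- rt2_transition_anova(co), "dropped")
  expect_equal(an$n_dropped, 1)
  expect_equal(nrow(an$cells), 4)
})
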