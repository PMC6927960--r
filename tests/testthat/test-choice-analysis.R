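# 300-row fixed-effects fixture with effect-coded predictors and known
# generating coefficients, reused across the oracle and property tests.
make_logit_fixture <- function(n = 300, seed = 17,
                               beta = c(0.6, 0.45, 0.25, 0.35)) {
  set.seed(seed)
  o <- sample(c(-1, 1), n, TRUE)
  tau <- sample(c(-1, 1), n, TRUE)
  eta <- beta[1] + beta[2] * o + beta[3] * tau + beta[4] * o * tau
  data.frame(subject_id = "s1", group = "CP",
             stay = rbinom(n, 1, plogis(eta)), o = o, tau = tau,
             g = 1, stringsAsFactors = FALSE)
}

test_that("fixed-effects logistic fits match the brute-force oracle", {
  lag <- make_logit_fixture()
  fit <- suppressMessages(
    fit_stay_regression(lag, terms = "o * tau", random = "none"))
  X <- cbind(1, lag$o, lag$tau, lag$o * lag$tau)
  expect_lt(max(abs(fit$coefficients$estimate - oracle_logistic(X, lag$stay))),
            1e-3)
})

test_that("label swaps flip exactly the coefficients containing the factor", {
  lag <- make_logit_fixture()
  f0 <- suppressMessages(
    fit_stay_regression(lag, terms = "o * tau", random = "none"))
  lag2 <- lag; lag2$o <- -lag2$o
  f1 <- suppressMessages(
    fit_stay_regression(lag2, terms = "o * tau", random = "none"))
  est <- function(f, term) twosteptask:::coef_row(f, term)$estimate
  expect_equal(est(f1, "o"), -est(f0, "o"), tolerance = 1e-8)
  expect_equal(est(f1, "o:tau"), -est(f0, "o:tau"), tolerance = 1e-8)
  expect_equal(est(f1, "tau"), est(f0, "tau"), tolerance = 1e-8)
  expect_equal(est(f1, "(Intercept)"), est(f0, "(Intercept)"),
               tolerance = 1e-8)
})

test_that("valence splits are consistent with an outcome-stratified model", {
  set.seed(23)
  n <- 400
  g <- sample(c(-1, 1), n, TRUE)
  o <- sample(c(-1, 1), n, TRUE)
  tau <- sample(c(-1, 1), n, TRUE)
  eta <- 0.5 + 0.2 * g - 0.1 * tau + 0.3 * o * tau + 0.15 * g * tau
  lag <- data.frame(subject_id = "s1", group = ifelse(g > 0, "CP", "PG"),
                    stay = rbinom(n, 1, plogis(eta)), o = o, tau = tau, g = g,
                    stringsAsFactors = FALSE)
  vs <- suppressMessages(lapply(
    list(rewarded = lag[lag$o == 1, ], unrewarded = lag[lag$o == -1, ]),
    fit_stay_regression, terms = "g * tau", random = "none"))
  full <- suppressMessages(
    fit_stay_regression(lag, terms = "(g * tau) * o", random = "none"))
  est <- function(f, term) twosteptask:::coef_row(f, term)$estimate
  # the full interacted model reproduces each stratum's tau coefficient
  expect_equal(est(vs$rewarded, "tau"), est(full, "tau") + est(full, "tau:o"),
               tolerance = 1e-6)
  expect_equal(est(vs$unrewarded, "tau"),
               est(full, "tau") - est(full, "tau:o"), tolerance = 1e-6)
  expect_equal(est(vs$rewarded, "g:tau"),
               est(full, "g:tau") + est(full, "g:tau:o"), tolerance = 1e-6)
})

test_that("a symmetric coin-flip table yields null coefficients", {
  set.seed(31)
  n <- 2000
  lag <- data.frame(subject_id = rep(sprintf("s%d", 1:10), each = n / 10),
                    group = "CP", stay = rbinom(n, 1, 0.5),
                    o = sample(c(-1, 1), n, TRUE),
                    tau = sample(c(-1, 1), n, TRUE), g = 1,
                    stringsAsFactors = FALSE)
  fit <- fit_stay_regression(lag, terms = "o * tau")
  expect_true(all(abs(fit$coefficients$estimate) < 0.15))
  nonint <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_true(all(abs(nonint$z) < 3))
})

test_that("the fallback ladder reaches fixed effects for one subject", {
  lag <- make_logit_fixture(n = 150)
  expect_message(
    fit <- fit_stay_regression(lag, terms = "o * tau", random = "slopes"),
    "single subject"
  )
  expect_equal(fit$random, "none")
})

test_that("random-effects structures are honored and reported", {
  co <- sample_cohort(list(uniform_group("CP", 8, w = 0.7)),
                      task_config(n_trials = 60), seed = 19)
  lag <- build_lagged_table(co)
  f_int <- fit_stay_regression(lag, random = "intercept")
  expect_equal(f_int$random, "intercept")
  expect_s4_class(f_int$model, "glmerMod")
  f_slp <- fit_stay_regression(lag, random = "slopes")
  expect_equal(f_slp$random, "slopes")
  expect_true(all(c("o", "tau", "ot") %in% f_slp$re_variance$var1 |
                    c("o", "tau", "ot") %in% f_slp$re_variance$grp))
})

test_that("covariate regressions standardize, fit, and reject degenerates", {
  co <- sample_cohort(list(uniform_group("CP", 6, w = 0.6)),
                      task_config(n_trials = 50), seed = 29)
  lag <- build_lagged_table(co)
  subj <- unique(lag$subject_id)
  score <- setNames(seq_along(subj) * 2 + 10, subj)
  lag$urgency <- score[lag$subject_id]
  fit <- suppressMessages(
    fit_covariate_regression(lag, "urgency", random = "none"))
  expect_true("cov_z:o:tau" %in% fit$coefficients$term)
  expect_equal(nrow(fit$coefficients), 8)

  # covariate equal to a scaled group code reproduces the group regression
  lag$g <- ifelse(lag$subject_id %in% subj[1:3], 1, -1)
  lag$gcopy <- lag$g * 3 + 5
  fg <- suppressMessages(
    fit_stay_regression(lag, terms = "g * o * tau", random = "none"))
  fc <- suppressMessages(
    fit_covariate_regression(lag, "gcopy", random = "none"))
  # z-scoring a +/-1 balanced code rescales it; z statistics agree
  expect_equal(fc$coefficients$z, fg$coefficients$z, tolerance = 1e-6)

  lag$flat <- 7
  expect_error(fit_covariate_regression(lag, "flat"), "zero-variance")
  expect_error(fit_covariate_regression(lag, "missing_col"), "not found")
})

test_that("reward-rate comparison matches closed-form ANOVA arithmetic", {
  mk <- function(rates, group) {
    n <- 50
    do.call(rbind, lapply(seq_along(rates), function(i) {
      k <- round(rates[i] * n)
      fx_trials(sprintf("%s%d", group, i),
                s1 = rep(0:1, n / 2), s2s = rep(0:1, n / 2),
                s2c = rep(c(0, 1, 1, 0), n / 4),
                rwd = c(rep(1, k), rep(0, n - k)), group = group)
    }))
  }
  co <- fx_cohort(rbind(mk(c(0.6, 0.62), "CP"), mk(c(0.5, 0.52), "PG")))
  rr <- reward_rate_comparison(co)
  # hand sums of squares: groups (0.6, 0.62) vs (0.5, 0.52)
  ss_between <- 2 * (0.61 - 0.56)^2 * 2
  ss_within <- sum((c(0.6, 0.62) - 0.61)^2) + sum((c(0.5, 0.52) - 0.51)^2)
  expect_equal(rr$F, (ss_between / 1) / (ss_within / 2), tolerance = 1e-8)
  expect_equal(rr$eta_p2, ss_between / (ss_between + ss_within),
               tolerance = 1e-8)
  expect_equal(rr$df1, 1); expect_equal(rr$df2, 2)

  # identical rates in both groups: F = 0
  co0 <- fx_cohort(rbind(mk(c(0.6, 0.64), "CP"), mk(c(0.6, 0.64), "PG")))
  expect_equal(reward_rate_comparison(co0)$F, 0, tolerance = 1e-10)

  # zero within-group variance flagged as degenerate
  cod <- fx_cohort(rbind(mk(c(0.6, 0.6), "CP"), mk(c(0.5, 0.5), "PG")))
  expect_message(rrd <- reward_rate_comparison(cod), "degenerate")
  expect_true(rrd$degenerate)

  # fewer than 2 subjects per group is an error
  co1 <- fx_cohort(rbind(mk(0.6, "CP"), mk(c(0.5, 0.52), "PG")))
  expect_error(reward_rate_comparison(co1), "2 subjects")
})
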