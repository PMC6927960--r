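#' Hierarchical logistic regression of stay probability
#'
#' Fits `logit P(stay) = X beta + Z b_subject` by maximum likelihood with
#' per-subject random effects, and reports Wald statistics per coefficient
#' (z = beta/SE, two-sided normal p). The default fixed-effects structure is
#' the full three-way model `g * o * tau` (group x previous outcome x
#' previous transition) when both groups are present, else `o * tau`; all
#' predictors are effect-coded \eqn{\pm}1, so under this coding model-free
#' control appears as a positive `o` main effect and model-based control as
#' a positive `o:tau` interaction.
#'
#' The default random-effects structure is a per-subject intercept plus
#' uncorrelated slopes for the within-subject terms. On failure or
#' non-convergence the fit falls back (with a message and a flag) to an
#' intercept-only random effect, then to a fixed-effects-only `glm`.
#'
#' @param lagged A lagged table from [build_lagged_table()].
#' @param terms Fixed-effects formula right-hand side as a string, e.g.
#'   `"g * o * tau"`. `NULL` chooses automatically.
#' @param random `"slopes"` (default), `"intercept"`, or `"none"`.
#' @param nagq Integration points for [lme4::glmer()]; the default 0 uses
#'   the fast penalized-likelihood approximation, suitable for the large
#'   cohort fits this package performs.
#' @return Object of class `stay_fit`: coefficient table (`term`,
#'   `estimate`, `se`, `z`, `p`), the random-effects structure actually
#'   used, convergence/fallback/separation flags, row and subject counts,
#'   and the underlying model object.
#' @export
fit_stay_regression <- function(lagged, terms = NULL, random = "slopes",
                                nagq = 0) {
  stopifnot(nrow(lagged) > 0, random %in% c("slopes", "intercept", "none"))
  if (is.null(terms)) {
    terms <- if (length(unique(lagged$g)) > 1) "g * o * tau" else "o * tau"
  }
  dat <- lagged
  dat$ot <- if (all(c("o", "tau") %in% names(dat))) dat$o * dat$tau else NULL
  n_subj <- length(unique(dat$subject_id))
  if (n_subj < 2 && random != "none") {
    message("single subject: random effects degenerate; fitting fixed ",
            "effects only")
    random <- "none"
  }

  # within-subject variables eligible for random slopes
  vars <- all.vars(stats::as.formula(paste("~", terms)))
  within <- intersect(vars, c("o", "tau"))
  slope_terms <- c("(1 | subject_id)",
                   sprintf("(0 + %s | subject_id)", within),
                   if (length(within) == 2) "(0 + ot | subject_id)")

  build <- function(re) {
    stats::as.formula(paste("stay ~", terms,
                            if (length(re)) paste("+", paste(re, collapse = " + "))))
  }
  ladder <- list()
  if (random == "slopes") ladder$slopes <- build(slope_terms)
  if (random %in% c("slopes", "intercept")) {
    ladder$intercept <- build("(1 | subject_id)")
  }
  ladder$none <- build(character(0))

  used <- NULL; fit <- NULL; fallback <- FALSE; converged <- TRUE
  for (level in names(ladder)) {
    if (level == "none") {
      fit <- stats::glm(ladder$none, family = stats::binomial(), data = dat)
      used <- "none"; converged <- fit$converged
      break
    }
    res <- tryCatch({
      f <- lme4::glmer(ladder[[level]], family = stats::binomial(),
                       data = dat, nAGQ = nagq,
                       control = lme4::glmerControl(
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
      msgs <- unlist(f@optinfo$conv$lme4$messages)
      bad <- any(grepl("converge", msgs, ignore.case = TRUE))
      list(fit = f, bad = bad)
    }, error = function(e) e, warning = function(w) w)
    if (inherits(res, "condition") || res$bad) {
      message("stay regression: random structure '", level,
              "' did not converge; falling back")
      fallback <- TRUE
      next
    }
    fit <- res$fit; used <- level
    break
  }

  if (inherits(fit, "glmerMod")) {
    cf <- summary(fit)$coefficients
    re_var <- as.data.frame(lme4::VarCorr(fit))
  } else {
    cf <- summary(fit)$coefficients
    colnames(cf) <- c("Estimate", "Std. Error", "z value", "Pr(>|z|)")
    re_var <- NULL
  }
  coefs <- data.frame(
    term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
    z = cf[, 1] / cf[, 2],
    p = 2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])),
    row.names = NULL, stringsAsFactors = FALSE
  )
  separation <- any(coefs$se > 10)
  if (separation) {
    message("stay regression: very large standard errors suggest ",
            "separation; interpret coefficients with caution")
  }
  structure(
    list(coefficients = coefs, random = used, converged = converged,
         fallback = fallback, separation = separation,
         re_variance = re_var, n_rows = nrow(dat), n_subjects = n_subj,
         terms = terms, model = fit),
    class = "stay_fit"
  )
}

#' @export
print.stay_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Stay regression (random effects: %s; %d rows, %d subjects)\n",
              x$random, x$n_rows, x$n_subjects))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  if (x$fallback) cat("note: fell back from a richer random structure\n")
  invisible(x)
}

# Convenience: extract one coefficient row by term name.
coef_row <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("no coefficient named '", term, "'")
  fit$coefficients[i, ]
}

#' Valence-split stay regressions
#'
#' Fits the outcome-free model `g * tau` separately on trials following a
#' reward and trials following a non-reward, asking whether the transition
#' effect (the model-based signature within each valence) differs by group.
#'
#' @inheritParams fit_stay_regression
#' @return List with elements `rewarded` and `unrewarded`, each a
#'   `stay_fit`.
#' @export
fit_valence_split <- function(lagged, random = "slopes", nagq = 0) {
  strata <- list(rewarded = lagged[lagged$o == 1, ],
                 unrewarded = lagged[lagged$o == -1, ])
  for (nm in names(strata)) {
    if (nrow(strata[[nm]]) == 0) stop("empty stratum: ", nm)
  }
  terms <- if (length(unique(lagged$g)) > 1) "g * tau" else "tau"
  lapply(strata, fit_stay_regression, terms = terms, random = random,
         nagq = nagq)
}

#' Stay regression with a clinical covariate
#'
#' Replaces the group factor by a standardized continuous covariate: model
#' `c * o * tau` where `c` is the z-scored subject-level covariate. Used to
#' test whether clinical variables (urgency, depression, ...) modulate the
#' model-free (`c:o`) or model-based (`c:o:tau`) signatures.
#'
#' @inheritParams fit_stay_regression
#' @param covariate Name of a subject-level column of `lagged`.
#' @return A `stay_fit` (coefficient terms use `cov_z` for the covariate).
#' @export
fit_covariate_regression <- function(lagged, covariate, random = "slopes",
                                     nagq = 0) {
  if (!covariate %in% names(lagged)) stop("covariate not found: ", covariate)
  subj <- unique(lagged[, c("subject_id", covariate)])
  if (anyNA(subj[[covariate]])) stop("covariate has missing values")
  s <- stats::sd(subj[[covariate]])
  if (s == 0) stop("zero-variance covariate: ", covariate)
  z <- (subj[[covariate]] - mean(subj[[covariate]])) / s
  lagged$cov_z <- z[match(lagged$subject_id, subj$subject_id)]
  fit_stay_regression(lagged, terms = "cov_z * o * tau", random = random,
                      nagq = nagq)
}

#' Between-group comparison of reward rates
#'
#' Per-subject reward rate (rewarded / completed trials), compared between
#' groups by one-way ANOVA; model-based control is the better harvesting
#' strategy in this task, so the more model-based group should earn more.
#'
#' @param cohort A `twostep_cohort` (after filtering).
#' @return List with the per-group means/SDs, `F`, `df1`, `df2`, `p`,
#'   `eta_p2`, per-subject rates, and a `degenerate` flag set when the
#'   within-group variance is zero.
#' @export
reward_rate_comparison <- function(cohort) {
  tr <- cohort$trials[cohort$trials$missed_stage == "none", ]
  rate <- stats::aggregate(reward ~ subject_id + group, tr, mean)
  counts <- table(rate$group)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need at least 2 subjects per group")
  }
  # a perfect fit is flagged as degenerate below; silence anova.lm's warning
  ss <- withCallingHandlers(
    stats::anova(stats::lm(reward ~ group, data = rate)),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ssb <- ss$`Sum Sq`[1]; ssw <- ss$`Sum Sq`[2]
  degenerate <- ssw <= 1e-12 * max(ssb, .Machine$double.eps)
  if (degenerate) {
    message("reward-rate comparison: zero within-group variance; ",
            "F is degenerate")
  }
  means <- stats::aggregate(reward ~ group, rate, mean)
  sds <- stats::aggregate(reward ~ group, rate, stats::sd)
  list(
    group_means = stats::setNames(means$reward, means$group),
    group_sds = stats::setNames(sds$reward, sds$group),
    F = ss$`F value`[1], df1 = ss$Df[1], df2 = ss$Df[2],
    p = ss$`Pr(>F)`[1],
    eta_p2 = ssb / (ssb + ssw),
    rates = rate, degenerate = degenerate
  )
}
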