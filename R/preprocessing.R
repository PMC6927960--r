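#' Engagement-based subject exclusion
#'
#' A subject is removed when at least one of three rules fires:
#' \enumerate{
#'   \item among trial pairs where the previous visit to the same
#'     second-stage state was rewarded, the rate of repeating that
#'     second-stage choice is below 50\% (strict: exactly 50\% is kept);
#'   \item more than 20 stages were missed (strict: exactly 20 is kept);
#'   \item some response option was never tried — either of the 2
#'     first-stage options or any of the 4 (state, option) second-stage
#'     responses. A subject with no completed trials falls under this rule
#'     and is reported distinctly.
#' }
#' The rewarded-repetition rule is evaluated within-state: it asks whether
#' the choice made at the previous visit to the same second-stage state is
#' repeated, given that visit was rewarded.
#'
#' @param cohort A `twostep_cohort`.
#' @return List with `cohort` (the retained subjects and their trials) and
#'   `report`, a data.frame with one row per subject: the rewarded-repeat
#'   rate (`NA` when no eligible pair exists), missed-stage count, an
#'   all-options-tried flag, the exclusion flag and a reason string.
#' @export
apply_engagement_filters <- function(cohort) {
  stopifnot(inherits(cohort, "twostep_cohort"))
  per_subject <- split(cohort$trials, cohort$trials$subject_id)
  rows <- lapply(names(per_subject), function(id) {
    d <- per_subject[[id]][order(per_subject[[id]]$trial), ]
    completed <- d[d$missed_stage == "none", ]
    n_missed <- sum(d$missed_stage != "none")

    # rewarded second-step repetition, within state
    last_choice <- c(NA_integer_, NA_integer_)
    last_reward <- c(NA_integer_, NA_integer_)
    pairs <- 0L; repeats <- 0L
    for (i in seq_len(nrow(completed))) {
      s <- completed$s2_state[i] + 1L
      if (!is.na(last_reward[s]) && last_reward[s] == 1L) {
        pairs <- pairs + 1L
        repeats <- repeats + (completed$s2_choice[i] == last_choice[s])
      }
      last_choice[s] <- completed$s2_choice[i]
      last_reward[s] <- completed$reward[i]
    }
    repeat_rate <- if (pairs > 0) repeats / pairs else NA_real_

    s1_seen <- unique(stats::na.omit(d$s1_choice))
    s2_seen <- unique(completed[, c("s2_state", "s2_choice")])
    tried_all <- length(s1_seen) == 2L && nrow(s2_seen) == 4L

    reasons <- character(0)
    if (!is.na(repeat_rate) && repeat_rate < 0.5) {
      reasons <- c(reasons, "rewarded-repeat rate < 50%")
    }
    if (n_missed > 20L) reasons <- c(reasons, "missed deadlines > 20")
    if (!tried_all) {
      reasons <- c(reasons,
                   if (nrow(completed) == 0L) "no completed trials"
                   else "untried response option")
    }
    data.frame(
      subject_id = id, rewarded_repeat_rate = repeat_rate,
      n_missed = n_missed, tried_all_options = tried_all,
      excluded = length(reasons) > 0,
      reason = paste(reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  keep <- report$subject_id[!report$excluded]
  filtered <- new_cohort(
    cohort$subjects[cohort$subjects$subject_id %in% keep, , drop = FALSE],
    cohort$trials[cohort$trials$subject_id %in% keep, , drop = FALSE]
  )
  list(cohort = filtered, report = report)
}

#' Build the lagged stay table
#'
#' One row per pair of consecutive fully completed trials per subject: the
#' current trial's stay indicator (current first-stage choice equals the
#' previous one) together with the previous trial's outcome and transition.
#' Pairs broken by a missed stage on either trial, or by non-adjacent trial
#' indices, contribute no row. Factors are effect-coded (\eqn{\pm}1):
#' `o` = +1 reward / -1 no-reward, `tau` = +1 common / -1 rare,
#' `g` = +1 CP / -1 PG. Subject-level columns (severity, covariates) are
#' carried onto each row.
#'
#' @param cohort A `twostep_cohort` (normally after
#'   [apply_engagement_filters()]).
#' @return A data.frame with columns `subject_id`, `group`, `stay`, `o`,
#'   `tau`, `g` plus subject covariates.
#' @export
build_lagged_table <- function(cohort) {
  stopifnot(inherits(cohort, "twostep_cohort"))
  tr <- cohort$trials[order(cohort$trials$subject_id, cohort$trials$trial), ]
  tr <- tr[tr$missed_stage == "none", ]
  same_subj <- tr$subject_id[-1] == tr$subject_id[-nrow(tr)]
  adjacent <- tr$trial[-1] == tr$trial[-nrow(tr)] + 1L
  idx <- which(same_subj & adjacent)   # previous-trial positions
  prev <- tr[idx, ]; cur <- tr[idx + 1L, ]
  out <- data.frame(
    subject_id = cur$subject_id,
    group = cur$group,
    stay = as.integer(cur$s1_choice == prev$s1_choice),
    o = ifelse(prev$reward == 1L, 1, -1),
    tau = ifelse(prev$transition == "common", 1, -1),
    g = ifelse(cur$group == "CP", 1, -1),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(cohort$subjects),
                   c("subject_id", "group",
                     grep("^true_", names(cohort$subjects), value = TRUE)))
  if (length(extra)) {
    m <- match(out$subject_id, cohort$subjects$subject_id)
    for (nm in extra) out[[nm]] <- cohort$subjects[[nm]][m]
  }
  out
}

#' Per-subject 2 x 2 stay-probability table
#'
#' Cell probabilities of repeating the previous first-stage choice by
#' previous outcome x previous transition. Cells with no observations are
#' reported with `NA` probability and excluded from cell-level summaries.
#'
#' @param lagged A lagged table from [build_lagged_table()].
#' @return A data.frame with one row per subject x outcome x transition
#'   cell: `n`, `n_stay`, `p_stay` and readable `prev_outcome` /
#'   `prev_transition` labels.
#' @export
stay_table <- function(lagged) {
  stopifnot(nrow(lagged) > 0)
  grid <- expand.grid(subject_id = unique(lagged$subject_id),
                      o = c(1, -1), tau = c(1, -1),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  agg_n <- stats::aggregate(stay ~ subject_id + o + tau, lagged, length)
  agg_s <- stats::aggregate(stay ~ subject_id + o + tau, lagged, sum)
  names(agg_n)[4] <- "n"; names(agg_s)[4] <- "n_stay"
  out <- merge(merge(grid, agg_n, all.x = TRUE), agg_s, all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  out$p_stay <- ifelse(out$n > 0, out$n_stay / out$n, NA_real_)
  out$prev_outcome <- ifelse(out$o == 1, "reward", "no-reward")
  out$prev_transition <- ifelse(out$tau == 1, "common", "rare")
  out[order(out$subject_id, -out$o, -out$tau), ]
}
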