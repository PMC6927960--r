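#' Task configuration for the two-step decision task
#'
#' Bundles every constant of the task environment: number of trials, the
#' common-transition probability, the Gaussian random-walk parameters of the
#' second-stage reward probabilities, and the trial timing. Defaults follow
#' the standard version of the task: 200 trials, 70/30 transitions, walk
#' SD 0.025 with reflecting bounds at 0.25 and 0.75, a 3 s choice deadline.
#'
#' @param n_trials Number of trials (>= 2).
#' @param p_common Probability that a first-stage choice leads to its common
#'   second-stage state (0 < p_common < 1).
#' @param walk_sd Standard deviation of the per-trial Gaussian increment
#'   applied to each reward probability.
#' @param walk_lower,walk_upper Reflecting bounds of the reward-probability
#'   walks; 0 <= walk_lower < walk_upper <= 1.
#' @param choice_deadline Response deadline per stage, seconds.
#' @param feedback_duration Feedback display duration, seconds.
#' @param inter_stage_interval,inter_trial_interval Intervals, seconds.
#' @param reward_magnitude Currency units delivered per rewarded trial.
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$p_common
#' @export
task_config <- function(n_trials = 200L,
                        p_common = 0.70,
                        walk_sd = 0.025,
                        walk_lower = 0.25,
                        walk_upper = 0.75,
                        choice_deadline = 3.0,
                        feedback_duration = 1.0,
                        inter_stage_interval = 1.0,
                        inter_trial_interval = 1.0,
                        reward_magnitude = 0.10) {
  n_trials <- as.integer(n_trials)
  stopifnot(
    n_trials >= 2L,
    p_common > 0, p_common < 1,
    walk_sd > 0,
    walk_lower >= 0, walk_upper <= 1, walk_lower <= walk_upper,
    choice_deadline > 0
  )
  structure(
    list(
      n_trials = n_trials, p_common = p_common, walk_sd = walk_sd,
      walk_lower = walk_lower, walk_upper = walk_upper,
      choice_deadline = choice_deadline,
      feedback_duration = feedback_duration,
      inter_stage_interval = inter_stage_interval,
      inter_trial_interval = inter_trial_interval,
      reward_magnitude = reward_magnitude
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-step task configuration\n")
  cat(sprintf("  trials: %d, p(common): %.2f\n", x$n_trials, x$p_common))
  cat(sprintf("  reward walks: SD %.3f, bounds [%.2f, %.2f]\n",
              x$walk_sd, x$walk_lower, x$walk_upper))
  cat(sprintf("  deadline: %.1f s\n", x$choice_deadline))
  invisible(x)
}

#' Fixed transition structure of the task
#'
#' First-stage option 0 leads commonly to second-stage state 0, option 1 to
#' state 1; the mapping is constant across trials (participants are told the
#' transition probabilities never change).
#'
#' @param p_common Common-transition probability.
#' @return Object of class `transition_structure` with the option-to-state
#'   mapping and `p_common`.
#' @export
transition_structure <- function(p_common = 0.70) {
  stopifnot(p_common > 0, p_common <= 1)
  structure(
    list(common_state = c(0L, 1L), p_common = p_common),
    class = "transition_structure"
  )
}

#' Initialize the four reward-probability walks
#'
#' One walk per (second-stage state, option) pair, drawn independently and
#' uniformly within the walk bounds.
#'
#' @param config A [task_config()].
#' @return Object of class `reward_walks`: a 2 x 2 matrix `p` (rows = states,
#'   columns = options), `trial_index = 0`, and `last_increments` (NULL until
#'   the first step).
#' @export
init_walks <- function(config = task_config()) {
  p <- matrix(stats::runif(4, config$walk_lower, config$walk_upper),
              nrow = 2, ncol = 2,
              dimnames = list(state = c("s0", "s1"), option = c("o0", "o1")))
  structure(
    list(p = p, trial_index = 0L, last_increments = NULL),
    class = "reward_walks"
  )
}

# Reflect values into [lo, hi]; loops because a large excursion can
# overshoot past the opposite bound.
reflect_into_bounds <- function(x, lo, hi) {
  stopifnot(hi >= lo)
  if (hi == lo) return(rep(lo, length(x)))
  for (i in seq_len(100L)) {
    over <- x > hi
    x[over] <- 2 * hi - x[over]
    under <- x < lo
    x[under] <- 2 * lo - x[under]
    if (!any(over) && !any(under)) return(x)
  }
  pmin(pmax(x, lo), hi)
}

# Core walk update with increments supplied by the caller (used by
# simulate_subject with its pre-drawn increment substream).
walk_step_core <- function(walks, increments, config) {
  walks$p[] <- reflect_into_bounds(walks$p + increments,
                                   config$walk_lower, config$walk_upper)
  walks$trial_index <- walks$trial_index + 1L
  walks$last_increments <- increments
  walks
}

#' Advance the reward-probability walks by one trial
#'
#' Each of the four probabilities receives an independent Gaussian increment
#' (mean 0, SD `walk_sd`) and is reflected at the bounds:
#' p' = 2 * bound - p_raw whenever p_raw crosses a bound. The raw increments
#' are kept in `last_increments` so their distribution can be inspected.
#'
#' @param walks A `reward_walks` object.
#' @param config A [task_config()].
#' @return The updated `reward_walks`.
#' @export
step_walks <- function(walks, config = task_config()) {
  eps <- matrix(stats::rnorm(4, 0, config$walk_sd), 2, 2)
  walk_step_core(walks, eps, config)
}

#' Sample second-stage states for first-stage choices
#'
#' Vectorized: with probability `p_common` each choice leads to its common
#' state (label `"common"`), otherwise to the other state (label `"rare"`).
#'
#' @param s1_choice Integer vector of first-stage choices (0 or 1).
#' @param structure A [transition_structure()].
#' @return A data.frame with columns `s2_state` (integer) and `transition`
#'   (character, `"common"` or `"rare"`).
#' @export
sample_transition <- function(s1_choice, structure = transition_structure()) {
  stopifnot(all(s1_choice %in% c(0L, 1L)))
  n <- length(s1_choice)
  common <- stats::runif(n) < structure$p_common
  home <- structure$common_state[s1_choice + 1L]
  state <- ifelse(common, home, 1L - home)
  data.frame(
    s2_state = as.integer(state),
    transition = ifelse(common, "common", "rare"),
    stringsAsFactors = FALSE
  )
}

#' Label a (choice, state) pair as common or rare
#'
#' @param s1_choice,s2_state Integer vectors (0/1).
#' @param structure A [transition_structure()].
#' @return Character vector `"common"`/`"rare"`.
#' @export
transition_label <- function(s1_choice, s2_state,
                             structure = transition_structure()) {
  ifelse(structure$common_state[s1_choice + 1L] == s2_state, "common", "rare")
}

#' Sample rewards for second-stage choices
#'
#' Bernoulli draw with the current walk probability of the chosen
#' (state, option) pair.
#'
#' @param s2_state,s2_choice Integer vectors (0/1).
#' @param walks A `reward_walks` object.
#' @return Integer vector of 0/1 rewards.
#' @export
sample_reward <- function(s2_state, s2_choice, walks) {
  stopifnot(all(s2_state %in% c(0L, 1L)), all(s2_choice %in% c(0L, 1L)))
  p <- walks$p[cbind(s2_state + 1L, s2_choice + 1L)]
  as.integer(stats::runif(length(p)) < p)
}
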