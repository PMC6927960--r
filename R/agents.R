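#' Response-time parameters of a simulated subject
#'
#' The generative response-time layer draws lognormal RTs around a median
#' that shifts additively with trial context: the stage-1 median decreases by
#' `delta_loss` after an unrewarded trial (post-loss speeding), and the
#' stage-2 median increases by `delta_rare`, scaled by the agent's effective
#' model-based weight, on rare transitions (rare-transition slowing, a
#' behavioral marker of model-based control).
#'
#' @param mu1 Median stage-1 RT in ms (before any shift).
#' @param delta_loss Stage-1 median speed-up (ms) after a previous non-reward.
#' @param mu2 Median stage-2 RT in ms.
#' @param delta_rare Stage-2 median slowing (ms) on rare transitions; the
#'   realized shift is `delta_rare * w_eff` where `w_eff` is the agent's
#'   effective model-based weight on that trial.
#' @param sigma_rt Lognormal shape parameter (>= 0; 0 gives deterministic RTs).
#' @param rt_floor Additive minimum RT in ms.
#' @return Object of class `rt_params`.
#' @export
rt_params <- function(mu1 = 430, delta_loss = 0, mu2 = 595, delta_rare = 60,
                      sigma_rt = 0.20, rt_floor = 0) {
  stopifnot(rt_floor >= 0, mu1 > rt_floor || rt_floor == 0, mu1 > 0, mu2 > 0,
            sigma_rt >= 0, mu1 - abs(delta_loss) > 0)
  structure(
    list(mu1 = mu1, delta_loss = delta_loss, mu2 = mu2,
         delta_rare = delta_rare, sigma_rt = sigma_rt, rt_floor = rt_floor),
    class = "rt_params"
  )
}

#' Parameters of a hybrid reinforcement-learning agent
#'
#' The agent mixes model-based (MB) and model-free (MF) first-stage values
#' with a weight that may depend on the previous trial's outcome valence:
#' `w_pos` applies after a reward, `w_neg` after a non-reward. Setting
#' `w_pos = w_neg = 0` yields a pure MF agent, `w_pos = w_neg = 1` a pure MB
#' agent, and `w_pos = w_neg = w` the standard valence-blind hybrid.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param lam Eligibility-trace parameter in \[0, 1\] passing the stage-2
#'   reward prediction error back to the stage-1 MF value.
#' @param beta1,beta2 Softmax inverse temperatures (>= 0) for stage 1 and 2.
#' @param w_pos,w_neg MB weights in \[0, 1\] applied on trials following a
#'   reward / a non-reward.
#' @param persev Perseveration bonus added to the previously chosen
#'   first-stage option inside the softmax.
#' @param rt An [rt_params()] object.
#' @param p_miss Per-stage probability of missing the response deadline,
#'   in \[0, 1).
#' @return Object of class `agent_params`.
#' @examples
#' pure_mf <- agent_params(w_pos = 0, w_neg = 0)
#' pure_mb <- agent_params(w_pos = 1, w_neg = 1)
#' @export
agent_params <- function(alpha = 0.6, lam = 0.6, beta1 = 4.5, beta2 = 4.5,
                         w_pos = 0.6, w_neg = 0.6, persev = 0.2,
                         rt = rt_params(), p_miss = 0) {
  stopifnot(
    alpha >= 0, alpha <= 1, lam >= 0, lam <= 1,
    beta1 >= 0, beta2 >= 0,
    w_pos >= 0, w_pos <= 1, w_neg >= 0, w_neg <= 1,
    is.finite(persev), p_miss >= 0, p_miss < 1,
    inherits(rt, "rt_params")
  )
  structure(
    list(alpha = alpha, lam = lam, beta1 = beta1, beta2 = beta2,
         w_pos = w_pos, w_neg = w_neg, persev = persev, rt = rt,
         p_miss = p_miss),
    class = "agent_params"
  )
}

#' Model-based first-stage values
#'
#' Prospective evaluation through the known transition structure:
#' `q_mb(a) = p_common * max_o q2(common(a), o) +
#'            (1 - p_common) * max_o q2(other(a), o)`.
#'
#' @param q2 2 x 2 matrix of stage-2 action values (rows = states,
#'   columns = options).
#' @param structure A [transition_structure()].
#' @return Numeric vector of length 2, one MB value per first-stage option.
#' @export
mb_values <- function(q2, structure = transition_structure()) {
  stopifnot(is.matrix(q2), all(dim(q2) == 2), all(is.finite(q2)))
  best <- apply(q2, 1, max)
  pc <- structure$p_common
  home <- structure$common_state + 1L   # common state per option, 1-based
  pc * best[home] + (1 - pc) * best[3L - home]
}

#' Outcome-dependent model-based weight
#'
#' Returns `w_pos` when the previous completed trial was rewarded, `w_neg`
#' when it was not, and their average on the first trial (no history).
#'
#' @param prev_outcome 1 (reward), 0 (no reward) or `NA` (no previous trial).
#' @param params An [agent_params()].
#' @return The effective MB weight.
#' @export
effective_w <- function(prev_outcome, params) {
  if (is.na(prev_outcome)) return((params$w_pos + params$w_neg) / 2)
  if (prev_outcome == 1) params$w_pos else params$w_neg
}

# Softmax choice probabilities over two options, with an optional
# perseveration bonus on the previously chosen option. Shift-invariant.
choice_prob <- function(values, beta, persev = 0, prev_choice = NA) {
  stopifnot(all(is.finite(values)), length(values) == 2L)
  x <- beta * values
  if (!is.na(prev_choice)) x[prev_choice + 1L] <- x[prev_choice + 1L] + persev
  e <- exp(x - max(x))
  e / sum(e)
}

#' Softmax choice with perseveration
#'
#' Samples an option with probability proportional to
#' `exp(beta * value + persev * 1[option == prev_choice])`. Stage-2 choices
#' use `persev = 0`.
#'
#' @param values Numeric vector of length 2.
#' @param beta Inverse temperature (>= 0).
#' @param persev Perseveration bonus.
#' @param prev_choice Previously chosen option (0/1) or `NA`.
#' @return The sampled option, 0 or 1.
#' @export
choose_option <- function(values, beta, persev = 0, prev_choice = NA) {
  p <- choice_prob(values, beta, persev, prev_choice)
  as.integer(stats::runif(1) >= p[1L])
}

#' SARSA(lambda)-style value update after a completed trial
#'
#' Stage-2 delta rule plus a stage-1 model-free update carrying the stage-2
#' value forward and, via `lam`, the reward prediction error:
#' `q2(s2, c2) += alpha * (r - q2(s2, c2))`;
#' `q_mf(c1) += alpha * (q2_old(s2, c2) - q_mf(c1)) +
#'              alpha * lam * (r - q2_old(s2, c2))`.
#' Unchosen entries are unchanged. Missed trials must not be passed here.
#'
#' @param q2 2 x 2 stage-2 value matrix.
#' @param q_mf Length-2 stage-1 model-free values.
#' @param s1_choice,s2_state,s2_choice Trial events (0/1).
#' @param reward 0 or 1.
#' @param params An [agent_params()].
#' @return List with updated `q2` and `q_mf`.
#' @export
td_update <- function(q2, q_mf, s1_choice, s2_state, s2_choice, reward,
                      params) {
  i <- s2_state + 1L; j <- s2_choice + 1L; k <- s1_choice + 1L
  q2_old <- q2[i, j]
  q2[i, j] <- q2_old + params$alpha * (reward - q2_old)
  q_mf[k] <- q_mf[k] + params$alpha * (q2_old - q_mf[k]) +
    params$alpha * params$lam * (reward - q2_old)
  list(q2 = q2, q_mf = q_mf)
}

# Lognormal RT around a median, shifted by rt_floor.
rt_draw <- function(z, median_ms, sigma, floor_ms) {
  floor_ms + exp(log(median_ms) + sigma * z)
}

#' Generate response times for one trial
#'
#' Stage-1 RT is lognormal with median `mu1 - delta_loss` after a previous
#' non-reward (else `mu1`); stage-2 RT is lognormal with median
#' `mu2 + delta_rare * w_eff` on rare transitions (else `mu2`); both are
#' shifted by `rt_floor`. Each stage is independently missed with
#' probability `p_miss`, or when the drawn RT exceeds the deadline.
#'
#' @param prev_outcome 1, 0 or `NA` (first trial).
#' @param transition `"common"` or `"rare"`.
#' @param w_eff Effective MB weight for the trial (scales `delta_rare`).
#' @param params An [agent_params()].
#' @param config A [task_config()] (supplies the deadline).
#' @return List with `rt1`, `rt2` (ms, `NA` when missed) and logical
#'   `missed1`, `missed2`.
#' @export
generate_rts <- function(prev_outcome, transition, w_eff, params,
                         config = task_config()) {
  r <- params$rt
  z <- stats::rnorm(2)
  u <- stats::runif(2)
  med1 <- r$mu1 - r$delta_loss * isTRUE(prev_outcome == 0)
  med2 <- r$mu2 + r$delta_rare * w_eff * (transition == "rare")
  rt1 <- rt_draw(z[1], med1, r$sigma_rt, r$rt_floor)
  rt2 <- rt_draw(z[2], med2, r$sigma_rt, r$rt_floor)
  deadline_ms <- config$choice_deadline * 1000
  missed1 <- u[1] < params$p_miss || rt1 > deadline_ms
  missed2 <- u[2] < params$p_miss || rt2 > deadline_ms
  list(rt1 = if (missed1) NA_real_ else rt1,
       rt2 = if (missed2) NA_real_ else rt2,
       missed1 = missed1, missed2 = missed2)
}

# Deterministic integer seed derivation for named substreams: one stream per
# (subject, role), all reproducible from the master seed.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in list(...)) {
    if (is.character(k)) {
      v <- utf8ToInt(k)
      k <- sum(v * seq_along(v))
    }
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Simulate one subject performing the two-step task
#'
#' Runs the full generative loop for `config$n_trials` trials: effective MB
#' weight, softmax first-stage choice (with perseveration), probabilistic
#' transition, softmax second-stage choice, Bernoulli reward from the current
#' walk probabilities, lognormal response times, SARSA(lambda) value update,
#' then one random-walk step. Each random component (walks, transitions,
#' rewards, choices, RTs) draws from its own seeded substream, so the whole
#' record is reproducible from `seed`. A missed stage aborts the trial: no
#' reward, no value update.
#'
#' @param params An [agent_params()].
#' @param config A [task_config()].
#' @param seed Integer master seed.
#' @param subject_id Subject identifier written into every row.
#' @param group,severity Optional labels carried into the output.
#' @return A data.frame with one row per trial and columns `subject_id`,
#'   `group`, `severity`, `trial` (0-based), `s1_choice`, `s1_rt_ms`,
#'   `transition`, `s2_state`, `s2_choice`, `s2_rt_ms`, `reward`,
#'   `missed_stage`.
#' @examples
#' d <- simulate_subject(agent_params(), task_config(n_trials = 10), seed = 1)
#' head(d)
#' @export
simulate_subject <- function(params, config = task_config(), seed = 1L,
                             subject_id = "s1", group = NA_character_,
                             severity = NA_real_) {
  stopifnot(inherits(params, "agent_params"), inherits(config, "task_config"))
  n <- config$n_trials
  structure_ <- transition_structure(config$p_common)
  deadline_ms <- config$choice_deadline * 1000
  r <- params$rt

  # named substreams: pre-draw every random number per role
  set.seed(derive_seed(seed, subject_id, "walks"))
  p_init <- stats::runif(4, config$walk_lower, config$walk_upper)
  walk_eps <- matrix(stats::rnorm(4L * n, 0, config$walk_sd), nrow = n)
  set.seed(derive_seed(seed, subject_id, "transitions"))
  u_trans <- stats::runif(n)
  set.seed(derive_seed(seed, subject_id, "rewards"))
  u_rew <- stats::runif(n)
  set.seed(derive_seed(seed, subject_id, "choices"))
  u_choice1 <- stats::runif(n); u_choice2 <- stats::runif(n)
  set.seed(derive_seed(seed, subject_id, "rts"))
  z_rt1 <- stats::rnorm(n); z_rt2 <- stats::rnorm(n)
  u_miss1 <- stats::runif(n); u_miss2 <- stats::runif(n)

  walks <- structure(
    list(p = matrix(p_init, 2, 2), trial_index = 0L, last_increments = NULL),
    class = "reward_walks"
  )

  q2 <- matrix(0.5, 2, 2)
  q_mf <- c(0.5, 0.5)
  prev_choice <- NA_integer_
  prev_outcome <- NA_integer_

  s1_choice <- integer(n); s1_rt <- numeric(n)
  trans <- character(n); s2_state <- integer(n)
  s2_choice <- integer(n); s2_rt <- numeric(n)
  reward <- integer(n); missed <- character(n)

  for (t in seq_len(n)) {
    w <- effective_w(prev_outcome, params)
    med1 <- r$mu1 - r$delta_loss * isTRUE(prev_outcome == 0L)
    rt1 <- rt_draw(z_rt1[t], med1, r$sigma_rt, r$rt_floor)
    m1 <- u_miss1[t] < params$p_miss || rt1 > deadline_ms

    if (m1) {
      s1_choice[t] <- NA_integer_; s1_rt[t] <- NA_real_
      trans[t] <- NA_character_; s2_state[t] <- NA_integer_
      s2_choice[t] <- NA_integer_; s2_rt[t] <- NA_real_
      reward[t] <- NA_integer_; missed[t] <- "stage1"
      walks <- walk_step_core(walks, matrix(walk_eps[t, ], 2, 2), config)
      next
    }

    q_mb <- mb_values(q2, structure_)
    q_net <- w * q_mb + (1 - w) * q_mf
    p1 <- choice_prob(q_net, params$beta1, params$persev, prev_choice)
    c1 <- as.integer(u_choice1[t] >= p1[1L])

    common <- u_trans[t] < structure_$p_common
    home <- structure_$common_state[c1 + 1L]
    s2 <- if (common) home else 1L - home

    rt2 <- rt_draw(z_rt2[t], r$mu2 + r$delta_rare * w * !common,
                   r$sigma_rt, r$rt_floor)
    m2 <- u_miss2[t] < params$p_miss || rt2 > deadline_ms

    s1_choice[t] <- c1; s1_rt[t] <- rt1
    trans[t] <- if (common) "common" else "rare"
    s2_state[t] <- s2
    prev_choice <- c1

    if (m2) {
      s2_choice[t] <- NA_integer_; s2_rt[t] <- NA_real_
      reward[t] <- NA_integer_; missed[t] <- "stage2"
      walks <- walk_step_core(walks, matrix(walk_eps[t, ], 2, 2), config)
      next
    }

    p2 <- choice_prob(q2[s2 + 1L, ], params$beta2)
    c2 <- as.integer(u_choice2[t] >= p2[1L])
    rwd <- as.integer(u_rew[t] < walks$p[s2 + 1L, c2 + 1L])

    s2_choice[t] <- c2; s2_rt[t] <- rt2
    reward[t] <- rwd; missed[t] <- "none"

    upd <- td_update(q2, q_mf, c1, s2, c2, rwd, params)
    q2 <- upd$q2; q_mf <- upd$q_mf
    prev_outcome <- rwd

    walks <- walk_step_core(walks, matrix(walk_eps[t, ], 2, 2), config)
  }

  data.frame(
    subject_id = subject_id, group = group, severity = severity,
    trial = 0:(n - 1L),
    s1_choice = s1_choice, s1_rt_ms = s1_rt,
    transition = trans, s2_state = s2_state,
    s2_choice = s2_choice, s2_rt_ms = s2_rt,
    reward = reward, missed_stage = missed,
    stringsAsFactors = FALSE
  )
}
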