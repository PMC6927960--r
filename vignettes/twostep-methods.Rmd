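---
title: "Models and methods behind twosteptask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twosteptask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative models, the statistical procedures,
and the design choices in `twosteptask` — the things a reader needs to judge
what a passing test suite does and does not establish.

## The task environment

The environment is the standard two-step paradigm: a first-stage choice
between two options, a probabilistic transition to one of two second-stage
states, a second-stage choice, and a Bernoulli reward. `task_config()`
holds every constant:

| parameter | default | units | rationale |
|---|---|---|---|
| `n_trials` | 200 | trials | standard session length |
| `p_common` | 0.70 | probability | 70/30 transitions; the mapping option 0 → state 0 is fixed and known to subjects |
| `walk_sd` | 0.025 | probability/trial | SD of the Gaussian increment on each reward probability |
| `walk_lower`, `walk_upper` | 0.25, 0.75 | probability | reflecting bounds; prevent degenerate always/never-rewarded options |
| `choice_deadline` | 3.0 | s | responses later than this are missed |
| `reward_magnitude` | 0.10 | currency | bookkeeping only; no payout logic |

Three points are genuinely open in the task description and are resolved
here as configurable defaults: the walks' *bounds* (0.25/0.75, the
canonical choice for this paradigm), their *initialization* (independent
uniform draws within the bounds, which avoids biasing early learning
toward any option), and their *mutual independence* (the simplest reading;
each of the four (state, option) probabilities drifts on its own). One walk
step is applied per trial, after reward delivery. Reflection uses
p′ = 2·bound − p_raw, iterated in the (practically impossible at
SD = 0.025) event that a single increment crosses both bounds. The raw
increments are retained on the walk object so their distribution can be
audited directly.

## The agents

Agents are hybrid learners in the tradition of the task's standard
computational treatment:

- stage 2: delta rule, `q2 ← q2 + α(r − q2)`;
- stage 1 model-free: SARSA(λ)-style,
  `q_mf ← q_mf + α(q2_old − q_mf) + αλ(r − q2_old)`;
- stage 1 model-based: recomputed each trial through the known transition
  matrix, `q_mb(a) = p·max_o q2(common(a), o) + (1−p)·max_o q2(other(a), o)`
  (the transition structure is announced to participants as constant, so
  treating it as known is the appropriate assumption);
- choice: softmax over `w·q_mb + (1−w)·q_mf` with inverse temperature β₁
  and a perseveration bonus for the previously chosen first-stage option;
  stage 2 uses β₂ without perseveration.

The single nonstandard ingredient is the *valence-dependent* MB weight:
`w_pos` applies on trials following a reward, `w_neg` on trials following a
non-reward, and their mean on the first trial. Setting `w_pos = w_neg`
recovers the standard hybrid model; `w = 0`/`w = 1` give pure MF/MB agents.
This weight is the package's mechanism for generating a loss-specific MB
deficit. It is a *data-generating device*, not a mechanistic claim about
gambling disorder: reduced weighting of the world model after losses and
distorted transition beliefs, among others, would produce similar choice
signatures, and the package deliberately fits no reinforcement-learning
model to recover `w` from data.

Value updates skip missed trials; there is no forgetting/decay of unchosen
values (fewer parameters, and nothing in the analyses depends on it).
Initial values are 0.5, the long-run mean of the reward walks.

Response times are lognormal around a context-shifted median:
stage 1 median `mu1 − delta_loss·1[previous non-reward]` (post-loss
speeding), stage 2 median `mu2 + delta_rare·w_eff·1[rare]` (rare-transition
slowing, scaled by the current effective MB weight so that slowing indexes
MB control), both plus an `rt_floor` and with lognormal shape `sigma_rt`.
A stage is missed with probability `p_miss`, or when the drawn RT exceeds
the deadline; a missed stage aborts the trial (no reward, no update) — the
conservative convention, applied consistently downstream.

Reproducibility contract: every random component (walks, transitions,
rewards, choices, RTs) draws from its own substream, seeded
deterministically from (master seed, subject id, role). Identical seeds
give bit-identical cohorts; components can be replayed independently.

## The synthetic cohorts

`default_specs()` describes 45 problem gamblers (PG) and 33 controls (CP),
200 trials each — the analyzed-sample sizes of the study design this
package emulates. Subject parameters are truncated-normal draws:

- shared: α = 0.65 (SD 0.10), λ = 0.65 (0.15), β₁ = 5.5 (1.0),
  β₂ = 5.0 (1.0), perseveration 0.20 (0.10), `p_miss` 0.01 (0.005),
  `mu1` 430 ms (55), `mu2` 595 ms (65), `sigma_rt` 0.20 (0.03);
- CP: `w_pos = w_neg` = 0.75 (0.10); `delta_loss` ~ N(0, 8) ms;
  `delta_rare` 59 ms (15);
- PG: `w_pos` = 0.75 (0.10) but `w_neg` = 0.10 (0.08); `delta_rare` 48 ms
  (15); `delta_loss` = 6·severity + N(0, 12) ms, with severity an integer
  DSM-style symptom count on 3–9 (discretized normal, mean 6, SD 1.4).

The calibration targets were the study's chronometric magnitudes — CP
rare-minus-common slowing near 44 ms, PG near 22 ms (delta_rare is scaled
by the mean effective w of each group), a PG post-loss speed-up near 37 ms
with a severity correlation near 0.4 — together with a valence-specific
choice deficit large enough to be detectable at n = 45/33 (the `w_neg`
contrast is therefore deliberately strong). Severity couples only to
`delta_loss`, the one severity association in the emulated design;
coupling it to `w_neg` is possible via a custom `group_spec` but off by
default. Clinical covariates (urgency, depression, trait anxiety, chronic
stress) differ in mean between groups but are generated independently of
task behavior, so covariate regressions are true nulls by construction.

What the generator does *not* emulate: demographic structure,
questionnaire item-level data, within-session nonstationarity (fatigue,
learning-to-learn), RT sequential effects beyond the two modeled shifts,
and — notably — a between-group difference in reward rate. In this task's
bounded-walk design the harvesting advantage of MB control is tiny
(measured here at ≤ 0.3 percentage points even for pure MB vs pure MF
agents, and sign-unstable at realistic sample sizes), so the empirical
observation that controls earn noticeably more than gamblers cannot be
reproduced by the MB-weight mechanism alone. `reward_rate_comparison()` is
therefore validated against arithmetic oracles on fixtures, not against a
direction property of the default cohorts.

## Preprocessing conventions

Engagement filters (all three strict, matching their verbal definitions):
a subject is excluded iff the rewarded second-step repetition rate is
**below** 50% (repeating the choice made at the previous visit to the
*same* second-stage state, given that visit was rewarded — the only
reading that is well-defined when states alternate), **more than** 20
stages were missed (counting stages, since a trial can time out at either
stage), or some first- or second-stage (state, option) response was never
tried. Exactly 50% and exactly 20 misses are retained. A subject with no
completed trials is reported distinctly under the coverage rule.

The lagged stay table contains one row per pair of consecutive *fully
completed* trials; a missed stage on either side of a pair, or
non-adjacent trial indices, removes the pair. (The stricter both-complete
convention is used even when only the current trial's stage 2 is missing,
so the stay table and the RT-by-previous-outcome cells use the same
notion of a usable pair.) Factors are effect-coded ±1 — o: reward +1;
τ: common +1; g: CP +1 — so main effects are averages over the other
factors, MB behavior appears as a positive o×τ coefficient, and an
attenuated-PG MB signature appears as a *positive* g×o×τ coefficient
under this coding.

## Statistical procedures and numerical choices

**Stay regressions** are hierarchical logistic models fit by maximum
likelihood (`lme4::glmer`) with `nAGQ = 0`, the fast penalized-likelihood
approximation — appropriate here because the acceptance properties involve
dozens of cohort-sized fits and the approximation error is negligible
relative to seed-to-seed variability. The default random-effects structure
is a per-subject intercept plus uncorrelated slopes for the within-subject
terms (o, τ, o×τ); on error or non-convergence the fit falls back, with a
message and a flag, to intercept-only and then to fixed-effects `glm`.
Singular fits are tolerated (they are expected when a variance component
is truly near zero and do not bias the fixed effects). Inference is Wald:
z = β/SE, two-sided normal p; no multiple-testing correction is applied
anywhere in the pipeline. Standard errors above 10 on the logit scale
trigger a separation warning. Continuous covariates are z-scored across
subjects before entering the `c * o * τ` model; a zero-variance covariate
is an error, as is an empty valence stratum.

**Mixed ANOVAs** operate on per-subject cell means, not trial-level
models, which makes the error degrees of freedom (1, N−2) with N the
retained subjects. The implementation uses the sum/difference-score
decomposition with *unweighted* (Type III-style) means, matching how such
designs are conventionally reported; with balanced groups it coincides
exactly with the classical sums-of-squares decomposition, which is the
independent oracle in the tests. Partial eta squared is computed through
the identity η²p = F·df1/(F·df1 + df2). Post-hoc contrasts use the
pooled-variance two-sample t with Cohen's d_s on difference scores
(a Welch variant is available behind a flag) and paired t with
d_z = t/√n. Degenerate inputs are flagged rather than silently handled: a
zero-variance paired contrast reports an infinite t, a zero within-group
variance in the reward-rate ANOVA sets a `degenerate` flag, and a
zero-effect/zero-error cell pattern yields F = 0, not NaN. No RT outlier
trimming is applied — a documented choice, not an inference about how any
particular dataset was processed.

**Severity correlation**: Pearson r between the DSM-style count and the
per-subject (mean RT1 after reward − mean RT1 after non-reward), p from
t = r√((n−2)/(1−r²)).

## Problem sizes in the test suite

The suite checks stochastic properties at sizes chosen to make the
expected behavior unambiguous while keeping a full run on one CPU
comfortable: transition frequencies and walk-increment SDs at 100,000
draws; pure-strategy signatures on cohorts of 200 identical agents at
w ∈ {0, 0.25, 0.5, 0.75, 1}; and group-contrast recovery on 20 replicate
default cohorts (45/33 × 200 trials) plus 20 negative-control replicates
in which the PG `w_neg` distribution is set equal to CP's — the latter
verifying that the detected three-way effect is driven by the
valence-specific weight and nothing else. Rate thresholds (e.g. the
three-way stay term significant in ≥ 80% of replicates, the severity
correlation positive in ≥ 90%) refer to these replicate counts.

## Known limitations

- The agent layer reproduces choice/RT *signatures*; it is not evidence
  about which latent mechanism produces them in any clinical population.
- Passing the emulation suite shows the pipeline detects the encoded
  contrasts at study scale; it says nothing about effects the generator
  does not model (see the reward-rate note above).
- The ANOVA layer assumes two groups and two within-levels — exactly the
  designs it serves; it is not a general factorial ANOVA engine.
- `nAGQ = 0` trades a small amount of likelihood accuracy for speed; for a
  single final fit on real data one can refit with `nagq = 1`.
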