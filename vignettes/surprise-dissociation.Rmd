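---
title: "Dissociating prediction error, rare rewards, and visuospatial surprise: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating prediction error, rare rewards, and visuospatial surprise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardsurprise)
```

## The problem

A reward that deviates from expectation is surprising in the classical
prediction-error sense. But an outcome can also be surprising purely
because it is *rare*, even when it exactly matches the mean expectation.
Separating these two signals — and both from perceptual surprise — requires
an unusual reward environment: one in which the mean-level outcome almost
never actually occurs.

This package implements such an environment and everything needed to
analyse behaviour and region-of-interest (ROI) fMRI simulated within it.
Rewards are 1, 2 or 3 drops of juice. Under the *stable* schedule the
session mean is 2 drops, yet 2-drop outcomes occur on only 10% of trials
(the distribution is 45/10/45). Receiving 2 drops therefore carries
(nearly) zero scalar reward prediction error (sRPE) while being a large
rare-reward event (RRE). Visuospatial surprise (VS) is generated by a
separate mechanism — occasional stimuli on the side opposite the currently
established one — and is independent of the reward stream by construction.

## Schedule algebra

With outcomes in {1, 2, 3} drops, a target mean `m` and a fixed 2-drop
probability `p2`, the remaining probabilities are fully determined:

```
p3 = (m − 1 − p2) / 2,   p1 = 1 − p2 − p3.
```

`solve_outcome_probs(2.0, 0.1)` gives 45/10/45 (stable);
`solve_outcome_probs(2.5, 0.1)` and `(1.5, 0.1)` give the 20/10/70 and
70/10/20 halves of the *changing* schedules, whose mean moves from 1.5 to
2.5 drops (or back) at mid-session while 2 drops stay rare. The
*equiprobable* control uses `p2 = 1/3`, which removes the frequency-based
surprise entirely. Infeasible combinations (means not reachable at the
requested `p2`) are rejected with an explicit message.

### Count enforcement

The schedule statements are percentages of trials, so the default generator
enforces counts exactly rather than sampling i.i.d.: the session-level
2-drop count is fixed first (`p_rre * n`, exact whenever integral — 15 of
150), split across halves; within each half the 1- versus 3-drop counts are
the rounding of the solved probabilities that best matches the half mean.
Exact half-unit ties are rounded in opposite directions in the two halves
so the session mean stays exact. Order within a half is a seeded uniform
shuffle. This makes tests deterministic and the realised per-half mean
never deviates from its target by more than one count (`2/n` drops). An
i.i.d. mode (`method = "iid"`) is available for studying sampling
variability.

### Sides and timing

Stimulus sides come in runs whose lengths are uniform on 11–19 trials
(mean 15, matching the design's stated range and mean with the simplest
distribution); after a run the side reverses and a new length is drawn.
Within a run each trial is independently displaced to the opposite side
with probability `p_offside`. The displacement rate is not specified
anywhere in the task description beyond "occasional"; the default 0.1 is a
deliberate, configurable guess matching the rarity of the other surprise
events. Offside trials do not reset the run.

Trial timing follows the task: blank 2–4 s, stimulus onset (the *decision*
event), response, 200 ms delay, 1.5 s juice delivery (the *outcome* event),
2–4 s intertrial interval. Sessions generated without an agent use a 500 ms
nominal response time; when simulated behaviour is supplied, realised RTs
shift the outcome onsets.

## The generative agent

`agent_params()` defines a learner/actor with:

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.257 | — | learning rate of the Rescorla–Wagner value update |
| `v0` | 2 | drops | animals over-trained on a 2-drop mean carry that prior into every session |
| `lapse_coefs` | intercept `qlogis(0.11)`; vs 0.4; sre −0.3; rre 0; position 0; trialno 0.15 | logit per SD | ~11% baseline lapse rate, mid-range of typical per-animal rates (≈7–16%); VS and time-on-task increase lapses, high expectation protects; RRE has no behavioural effect |
| `rt_coefs` | intercept `log(500)`; vs 0.06 | log-ms per SD | ~500 ms baseline; VS slows responding |
| `rt_shape` | 20 | — | gamma RTs with ≈22% CV |
| `p_error` | 0.5 | — | a lapse becomes an error vs. an outlier RT (4000–6000 ms) with equal probability; the analysis pools both, so the split is free |

The value trace `V` updates only on rewarded (correct) outcomes; repeated
attempts inherit the pre-outcome value. Errors repeat the trial with the
stimulus unchanged, so repeats can carry no VS and no decision-time RRE —
the generative model implements the same zeroing rule the analysis applies
("no surprise on a repeat"). Lapse probabilities use session-z-scored
predictors so the generative scale matches the fitting side; because the
reward and side sequences are fixed before behaviour is simulated, the
z-scoring constants are known up front, and zeroed predictors on repeats
enter at the z-value of a raw zero.

What the generator does *not* emulate: within-trial motor kinematics,
licking or satiety drift, session-to-session non-stationarity in the lapse
mechanism, or any coupling between behaviour and the reward schedule.
Passing tests therefore demonstrate internal consistency of the estimation
machinery under the assumed model, not robustness to the many ways real
behaviour departs from it.

## Behavioural estimation

`build_behavior_design()` assembles the trial-level design: VS (side
change, zeroed after errors), RRE (previous rewarded trial delivered
2 drops, zeroed after errors), position, trial number, and either the
Rescorla–Wagner expectation `sre` (given a learning rate) or five
lagged-reward columns. Trials without five preceding rewarded trials are
dropped; all predictors are z-scored per session so position and trial
number are comparable across sessions. Zero-variance columns (e.g. VS in a
session that never reverses) are excluded with a warning.

Two decisions here were genuinely open:

* **RRE lag.** At decision time the current trial's outcome has not
  happened yet, so a lapse can only be predicted by the *previous* trial's
  rare reward; the design uses lag 1 and exposes lag 0 (`rre_lag = 0`) for
  outcome-locked analyses.
* **sRE timing.** The expectation entering trial *t* is the pre-outcome
  value `V_t` (which already incorporates trial *t−1*'s reward), so "high
  expectation after a good run" and "positive expectation on the previous
  trial" coincide; we use `V_t`.

`fit_lapse_model()` fits the hierarchical logistic model. The full mixed
model (random slopes per subject, random intercept per session, via lme4)
is available as `method = "glmer"`, but full random-slope binomial fits are
fragile and slow on small synthetic cohorts, so the default route fits one
maximum-likelihood logistic regression per subject and combines
coefficients by inverse-variance weighting; the route taken is recorded in
the result. The inferential targets here are population coefficient signs
and magnitudes, for which the aggregation is adequate and calibrated (the
test suite checks type-I behaviour). Degenerate per-subject fits
(separation) are down-weighted and flagged. `fit_rt_model()` applies the
same structure to RTs with a gamma family and log link, excluding outliers
(or additionally errors and repeats, selectable).

Outlier RTs are flagged by absolute thresholds first (< 50 ms or
> 4000 ms), then by the 2.5-SD rule computed on the remaining trials —
the ordering is not specified in the task description; applying the
relative rule after removing absolute outliers keeps a single extreme
trial from inflating the SD and hiding itself.

### Two-stage learning-rate estimation

The influence of the reward `k` trials back under a truncated
Rescorla–Wagner learner is `w_k = c · α (1 − α)^{k−1}`, with `c` a free
scale (the inverse-temperature analogue; its sign is free, which is what
lets negative lapse-model betas be inverted directly).
`fit_truncated_rw()` minimises the Euclidean norm between these model
weights and the five fitted lag coefficients: a 1001-point grid on `[0, 1]`
with `c` solved in closed form per grid point (a least-squares projection),
followed by golden-section refinement between the neighbouring grid points.
The grid keeps the search robust to the objective's flat regions near
`α = 0`; all-zero inputs are flagged rather than inverted.
`reward_history_slope_test()` complements this with the simpler question —
does the influence of past rewards decay at all? — by fitting a line
through each subject's five lag betas and t-testing the slopes against
zero.

Likelihood-ratio tests between nested fits use
`χ² = 2 (llₓ − llᵣ)` clipped at zero; the expectation term is tested with
2 df to account for the learning rate and scale estimated upstream.

## The fMRI model

### HRF

A single gamma kernel parameterised by mean lag 4.5 s and SD 2 s
(moment-matched: shape 5.06, scale 0.89), normalised to unit sum. Macaque
haemodynamics are faster than human, hence the early peak. One subtlety:
a gamma with *mean* 4.5 s and SD 2 s has its mode at
`(shape − 1)·scale = 3.61` s, slightly later than the conventionally
quoted ~3.5 s peak; the package implements distribution-mean semantics and
accepts the ≈0.1 s discrepancy as rounding. Kernels whose shape would not
exceed 1 (no interior mode) are rejected.

### Session design

Thirteen named regressors are built per session — decision-phase VS_left,
VS_right, RRE_decision, a decision constant and a hand-movement regressor
at the response; outcome-phase reward_current (amplitude = drops),
reward_lag1…5 (amplitudes of the five previous rewards, placed at the
*current* outcome onset, matching how a contrast subtracts them from the
current reward), RRE_outcome and an outcome constant. The design
description mentions sixteen regressors without naming three of them; the
package builds only the thirteen it can identify and provides an
`extra_nuisance` hook rather than inventing identities. Events are
impulses by default (durations are unstated; impulse + HRF is the
conservative choice), with a 1.5-s boxcar option for outcome events.
Everything is convolved on a 0.1-s grid (batched FFT), sampled at
TR = 2.28 s, and z-scored. All-zero columns (e.g. RRE in a session with no
2-drop outcome) are flagged.

Contrasts: `sRPE = reward_current − Σ w_k · reward_lagk` with
`w_k = α(1−α)^{k−1}`; a leave-most-recent-out variant re-anchors the decay
on lags 2–5 (a control for orofacial/gustatory correlates of the last
juice delivery); `VS = VS_left + VS_right`; `RRE = RRE_outcome`.
`shared_variance()` (100 r²) is the decorrelation diagnostic; over a
simulated full cohort the trial-level sRPE and RRE regressors share well
under half a percent of variance in every schedule class, and VS shares
essentially none with either.

### ROI simulation and inference

`simulate_roi_bold()` builds `y = Xβ + ε` with AR(1) Gaussian noise
(coefficient 0.3 by default — a mild, generic fMRI autocorrelation;
ROI-level prewhitening details are not specified for the real data, so the
session fit uses plain OLS). An optional Gaussian running-line high-pass
(100-s cutoff) mirrors the temporal filtering applied to real series.
`fit_session_glm()` computes contrast effects, variances from the design
covariance, and z-statistics via the normal approximation — session dfs are
hundreds of volumes, so the approximation is inconsequential (an exact-t
mode exists). Rank-deficient designs drop aliased columns with a warning.

`combine_levels()` implements a two-level summary-statistics scheme:
sessions pool within subject by precision-weighted fixed effects; subjects
combine by a one-sample random-effects t (df = subjects − 1). This is a
deliberate simplification of full Bayesian mixed-effects variance
modelling, declared in the result metadata; its type-I behaviour under a
between-subject null is verified in the tests. Degenerate zero-variance
inputs are flagged rather than reported as infinitely significant.

`extract_timecourse()` up-samples the series ×10 with spline
interpolation, cuts epochs at event onsets, baselines at onset, and
averages 0–10 s; `epoch_group_test()` tests subject-mean epoch averages
against baseline. A prediction-error ROI shows suppressed 1-drop and
elevated 3-drop epochs; a magnitude ROI shows monotonically ordered
positive responses.

### The dissociation experiment

`run_pipeline()` wires the stages together. The default ROI map injects an
sRPE-patterned effect into a midbrain/striatum-like ROI, an RRE effect into
a posterior-lateral-OFC-like ROI *in changing sessions only* (rare rewards
acquire significance only where the reward statistics can be learned), and
a VS effect into a lateral-prefrontal-like ROI, each at amplitude 0.2 BOLD
a.u. per regressor SD against unit-SD noise. Group effects are called
significant at `alpha_sig = 0.01` — a stringent threshold chosen in the
spirit of corrected neuroimaging inference rather than nominal 0.05, which
keeps the nine ROI × contrast cells of the dissociation table jointly
reliable. Injecting an *unsigned* prediction-error effect (|sRPE|) instead
produces a significantly negative fitted RRE weight: a region coding
surprise magnitude responds to 1- and 3-drop outcomes but not to the
2-drop events the signed RRE regressor marks.

## Reproducibility and problem sizes

All stochastic stages draw from labelled substreams derived from one
master seed (`derive_seed()`), so changing one stage's settings never
perturbs another's draws, and identical configurations are byte-identical.

The test suite exercises the pipeline at the study's own scale where that
matters and at reduced scale elsewhere, as the package's own choice of
problem sizes: schedule and design diagnostics pool full cohorts
(6 subjects × 12 sessions × 150 trials); learning-rate recovery runs 50
replicate cohorts at the full session complement (median
|α̂ − α| ≈ 0.04 there — the changing sessions contribute most of the
identifying variance); the end-to-end dissociation runs 50 replicate
cohorts; null calibrations use 250–400 simulations.

## Known limitations

* The per-subject-aggregation default is not a full mixed model; shrinkage
  across subjects and session-level random intercepts are only available
  through the `glmer` route.
* The two-level group combination treats session variances as known
  (fixed-effects pooling) and subjects as exchangeable; between-session
  random variance within subject is not modelled.
* ROI noise is stationary AR(1); real BOLD has drifts, motion artefacts
  and physiological structure the simulator does not attempt.
* Spatial analysis — smoothing, cluster inference, atlas masks,
  whole-brain maps — is out of scope; everything is ROI-level.
* The offside-stimulus rate and the identities of the three unnamed design
  regressors are unspecified upstream; the package's choices (0.1; a
  nuisance hook) are documented guesses.
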