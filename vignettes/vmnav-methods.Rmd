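---
title: "Methods: simulating and analysing virtual water-maze navigation in aMCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing virtual water-maze navigation in aMCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmnav)
```

## The task and the problem

The virtual Morris water navigation task (VMWNT) places a participant in a
first-person circular virtual arena (radius 20 virtual metres inside a
50 x 50 m room) and asks them to reach a platform of diameter 4.5 m as
quickly and directly as possible. The task has three stages of seven trials
each, every trial capped at 60 s and sampled at 15 Hz:

* **Stage 1** — visible platform, varying start positions. Performance here
  loads on executive and perceptual-motor function rather than spatial
  memory.
* **Stage 2** — hidden platform at a new location, fixed start. The platform
  must be found from distal cues and remembered across trials (egocentric +
  allocentric learning).
* **Stage 3** — hidden platform, novel location and cues, varying starts.
  This isolates allocentric processing and is hard for everyone.

From each trial's XY path six metrics are computed: path length, latency
(60 s if the platform is not reached, with a censor flag), path distance
ratio, quadrant crossings, time in target quadrant, and target crossing
(binary success). Healthy controls (HC) outperform people with amnestic
mild cognitive impairment (aMCI) on most of these, most clearly in Stage 2.

Because the underlying clinical trajectory data are not publicly deposited,
this package pairs the full analysis pipeline with an agent-based simulator
whose defaults are calibrated so that the derived metrics reproduce the
published group-level summaries of a 38-participant cohort (20 HC, 18
aMCI). Everything downstream of the trajectory table — metrics, tests,
composite, classification — is agnostic about whether the input is
simulated or real.

## Coordinate and quadrant conventions

Coordinates are arena-centred Cartesian metres. The four equal quadrants
are delimited by the two axis-aligned lines through the centre; boundary
points are resolved half-open (`x >= 0 & y >= 0` is Q1, and so on), so
`(0, 0)` belongs to Q1. The published task does not state the angular
placement of the quadrant boundaries relative to the cues, so the rotation
is exposed as `quadrant_rotation` in `arena_config()` rather than guessed;
all metrics are invariant to rotating the world by a multiple of 90 degrees.
Platform centres and start positions are likewise not printed in the source
material; the defaults were chosen so that the straight-line start-platform
distances are consistent with the published path-distance-ratio and
path-length tables (e.g. Stage 3 has short start-platform distances, which
is the only way a mean ratio of ~15 can coexist with ~145 m paths).

## The trajectory simulator

Each virtual participant is a goal-directed correlated random walker with a
*belief* about where the platform is:

* Per 1/15 s step the heading is pulled toward the believed platform
  location with gain `goal_weight` (in [0, 1]) and perturbed by von Mises
  noise with concentration `heading_noise_kappa`; the position advances by
  `speed / 15` where speed is drawn once per participant
  (mean `speed_mean`, SD `speed_sd`, truncated above 0.5 m/s).
* The believed location is the true platform centre plus an isotropic
  Gaussian error whose SD shrinks geometrically across trials within a
  stage (`learning_rate`), and is clipped into the arena so it is always
  reachable. If the walker reaches the believed spot and finds no platform
  there, it searches locally for `search_dwell_s` seconds (longer in
  Stage 3 by `dwell_mult3`, reflecting the uncertainty induced by novel
  cues) and then draws a fresh belief. This dwell-then-resample search is
  what produces the published Stage 3 signature — very high path-distance
  ratios and roughly 50% success despite substantial time spent in the
  correct quadrant.
* Positions that would leave the arena are clamped to the wall with the
  heading reflected about the tangent.
* Trials end at the first sample inside the platform disc or at 60 s
  (exactly 901 samples when censored).

A single latent, non-negative *impairment* scalar separates the groups
(truncated-normal per group); group membership is a shift in that
distribution, not a separate mechanism, so the groups overlap. It lowers the steering gain, widens and slows
the belief learning, and adds heading noise. Stage 1 (visible platform)
uses two dedicated channels: the belief error is proportional to impairment
(an unimpaired navigator has none when the target is visible, and a wrong
initial belief is replaced by the true location at the first
re-orientation), and with probability `lapse_rate * impairment` a trial is
an *attentional lapse* — the agent searches beliefs scattered about the
arena centre until attention recovers (exponential time, mean
`lapse_recover_s`). The lapse channel is what reconciles the published
Stage 1 aMCI profile: moderate mean path length but low time in target
quadrant and roughly one lost trial in seven. Without further heterogeneity a single impairment scalar makes the five
global metrics almost collinear across participants (a PC1 share near 80%
and an effect size far above the published one), so individual *style*
traits are modelled explicitly, each an independent per-participant
log-normal multiplier: overall traits on the steering gain, belief error,
heading precision and search dwell (`trait_sd`); per-stage skill
multipliers on the belief error (`stage_trait_sd` — executive, egocentric
and allocentric abilities dissociate partially across people); a radial
search bias pulling believed locations toward the centre or the wall
(`radial_bias_sd`, the centre-vs-periphery style seen as thigmotaxis
variation, which sets the quadrant-crossing rate per metre largely
independently of overall performance); and a wide per-participant speed
distribution (which decouples latency from path length, since a slow
accurate navigator and a fast sloppy one can share a latency). These
traits jointly reproduce the published within-group standard errors, the
overlap needed for a cross-validated AUC of about 0.78 rather than 1.0,
and a PC1 variance share near one half instead of a rank-one structure.
The log-normal multipliers are mean-one normalised, so widening the trait
spread changes the population spread without shifting the group-average
difficulty.

Cognitive and demographic scores (MoCA, MoCA-MIS, AD8, CDR, CDR-SOB, age,
sex, education) are drawn per group from truncated normals whose SDs are
recovered from the published standard errors (SE times the square root of
the group size), with the latent mean adjusted so the *truncated* mean
equals the published group mean; integer instruments are rounded. Within a
group, the memory instruments (MoCA and MoCA-MIS) are *weakly* coupled to
a navigation-deficit index — the standardised impairment combined with the
performance-relevant style traits — via `cognitive_coupling` (the latent
instrument mean shifts down per standardised deficit unit), while the
remaining scores are independent. Full independence was
considered and rejected: clinical cohorts show small but nonzero
within-group score-navigation correlations, and with a composite effect
size of 1.39 a fully independent construction caps the full-sample
Spearman correlation well below the published 0.6 (the correlation of two
group-separated, within-independent variables is the product of their
point-biserial correlations). The default coupling leaves within-group
correlations small enough to be nonsignificant at n = 18-20, matching the
published pattern of a strong full-sample correlation with nonsignificant
within-group and partial correlations.

Reproducibility: a master seed is split into one documented integer stream
per participant and per (participant, stage, trial) via `derive_seed()`
(a multiplicative-congruential recurrence modulo 2^31 - 1), so cohorts are
bit-identical under the same seed and partial regeneration is stable.

## Calibration

`calibrate()` runs a derivative-free coordinate search over a named subset
of scalar parameters, minimising the mean squared standardised discrepancy
between simulated and target group-by-stage summaries (means, plus a
0.25-weighted term matching the standard errors so that group spreads, and
hence effect sizes, are matched too). Optionally the composite-stage
statistics — PC1 variance share, Cohen's d, the full-sample Spearman
correlation with MoCA, the nested-CV AUC and the group Route Efficiency
means (`reference_derived_targets()`) — enter the objective as well; the
shipped calibration uses them, because the published summary of the study
includes these quantities and the metric-level table alone does not pin
down the between-metric correlation structure. Each objective evaluation
simulates a small number of full cohorts at the study sizes. The shipped
`params_calibrated.yaml` is the product of this search targeting the
published summaries (`reference_targets()` plus
`reference_derived_targets()`); it is a fixed input of the package, not
something analyses re-fit. One mechanistically
motivated deviation between cells remains visible in the shipped fit:
healthy-control Stage 1 quadrant crossings are somewhat below the published
value, because near-direct paths from the default start positions rarely
graze a quadrant boundary.

## The statistical pipeline

* **Group comparisons** are two-sided Mann-Whitney U tests on
  participant-level means, globally (over all 21 trials) and per stage,
  with exact p-values for small tie-free samples and the tie-corrected
  normal approximation otherwise. Means are reported with standard errors.
* **Mixed models** preserve the trial-level structure: for each outcome and
  stage, fixed effects of group, trial (categorical, reference trial 1) and
  their interaction with a participant random intercept. Path length, path
  distance ratio and time in target quadrant are log(x+1)-transformed
  (natural log) and fitted by REML; quadrant crossings use a Poisson and
  target crossings a logistic mixed model (Laplace ML). Latency is excluded
  because of censoring. Logistic fits are skipped, with a flag, when a
  group's success rate is within 0.025 of 0 or 1 (quasi-separation; with
  near-ceiling Stage 1 success this reproduces the published blank row).
  Outright fit failures are reported, never silently ignored. Time in
  target quadrant is modelled on the percent scale after log(x+1), as in
  the reference analysis, despite being bounded.
* **Latency** is analysed by Kaplan-Meier curves of cumulative success
  probability (1 minus the survival of "not yet found") with two-sample
  log-rank tests, pooling the trials of a stage as independent
  observations; no within-participant clustering correction is applied,
  and the output carries a note saying so.
* **Route Efficiency** is the first principal component of the
  correlation-matrix PCA of the five continuous global metrics on
  complete cases (listwise deletion; one aMCI participant's path-distance
  ratio is flagged missing, giving n = 37), oriented deterministically so
  the path-length loading is positive and then inverted, so higher scores
  mean better navigation. Associations use Spearman correlations (full
  sample and within groups), Pearson partial correlations controlling for
  a binary group indicator, and a linear model adjusting the group effect
  for sex, age and education. The effect size is pooled-SD Cohen's d; the
  post-hoc power method (not named in the reference analysis) is the
  noncentral-t power of a two-sided two-sample t test at the observed d
  and group sizes, and is labelled as such in the output.
* **Classification** is nested cross-validation: stratified 5-fold
  partitions repeated 10 times; within each fold the standardization,
  PCA, PC1 orientation and logistic model are all fitted on training rows
  only (standardization must be fold-internal too, or leakage occurs).
  The reported AUC is the literal mean of the fold-level AUCs, with the
  pooled-prediction variant available behind a flag. The 95% CI resamples
  participants with replacement (stratified) and reruns the whole nested
  CV per bootstrap sample with a reduced repetition count (default 2) for
  tractability; the cheaper pooled-score bootstrap is offered as an option
  and labelled in output. Which variant the reference analysis used is not
  stated; both are implemented. Quasi-separated logistic fits inside folds
  are used anyway — ranks, and hence AUC, remain defined. Empirical AUCs
  use the Mann-Whitney identity with midranks.

## Numerical choices and degenerate inputs

* Stratified folds guarantee both classes in every test fold at n = 37.
* The path-distance-ratio denominator is the distance from the start to the
  platform *edge* (centre distance minus 2.25 m), guarded by a small
  epsilon; an optimal path then has ratio exactly 1 and successful trials
  always have ratio >= 1.
* Metrics for successful trials use samples up to and including arrival;
  censored trials use all 901 samples. Whether the original software
  scored time in quadrant over the full 60 s for successful trials is
  unstated; up-to-arrival is used here and the alternative would be a
  one-line change in `compute_time_in_target_quadrant()`.
* Quadrant crossings use raw adjacent-sample transitions without a dead
  zone — the only rule the metric definitions support; the simulator's
  paths are smooth at 15 Hz so boundary jitter is negligible.
* Zero-variance PCA inputs fail loudly, naming the variable; PCA requires
  at least 6 complete cases.
* A constant classification variable yields an explicitly flagged
  undefined AUC.

## What the simulation does and does not establish

Passing the calibration-reproduction checks shows that the pipeline,
applied to trajectories whose metric structure matches the published
summaries, reproduces the published composite, correlation and
discrimination results. It does not validate the simulator as a cognitive
model: real navigation includes thigmotaxis, speed modulation, pauses,
strategy switches and learning-to-learn that the walker does not model, and
the latent impairment is a one-dimensional caricature of a heterogeneous
clinical state. Conclusions about real aMCI navigation require the real
trajectories.

## Problem sizes used in the checks

The bundled verification suite simulates cohorts at the study size
(20 + 18) across 20 seeds for the calibration-reproduction checks, and uses
reduced sizes elsewhere (8-16 participants; 200 replicates for the
type-I-error and mixed-model-recovery checks; 50 label permutations for the
chance-level check) — chosen to give stable Monte-Carlo estimates with a
suite that runs in minutes on one core.
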