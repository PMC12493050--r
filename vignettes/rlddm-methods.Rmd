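---
title: "Modelling reward and loss avoidance learning with RLDDMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward and loss avoidance learning with RLDDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the model

The package models a three-condition probabilistic instrumental learning
task: 60 reward trials ("win or nothing"), 60 neutral trials and 60 loss
trials ("lose or nothing"), 180 trials in total, pseudo-randomly interleaved
in a sequence that is fixed by a seed and shared by all subjects. Within the
reward and loss fractal pairs one option carries a 70% favourable
contingency and the other 30%. Subjects respond within 3 s; responses slower
than the window count as omissions.

A reinforcement learning drift diffusion model (RLDDM) couples two
components:

* **Value learning.** The chosen option's value follows the delta rule
  `Q <- Q + alpha * (R - Q)`, with learning rate `alpha` in (0, 1) and
  reinforcement `R` coded +1/0 on reward trials, -1/0 on loss trials and 0
  on neutral trials. The coding is symmetric so prediction errors
  (`R - Q`) span comparable ranges in both valence systems. The neutral
  pair's value difference is fixed at 0.4 (the difference between the
  contingencies) and never updated, which stabilizes estimation in a
  condition that carries no reinforcement.
* **Decision process.** Choices and reaction times arise from a Wiener
  diffusion between two absorbing boundaries separated by `a`, starting at
  the fixed midpoint `z = 0.5` (stimulus sides are randomized), with
  non-decision time `t_nd` and unit noise scale. The drift rate on each
  trial is the value difference between the options mapped to the upper and
  lower boundaries scaled by `nu`. The upper boundary corresponds to the
  objectively better option: the 70%-win option on reward trials and the
  30%-loss option on loss trials, so positive drift input always means
  evidence toward the better option (+0.4 on neutral trials).

Two extensions let the decision process evolve over the course of a
condition, with `t` the 1-based trial index *within* each trial type (so the
power terms anchor at 1 on the tenth trial of a condition):

* drift-rate power: drift = (value difference) x `(t/10)^p`
  (`RLDDM_drpow`); as printed this form replaces the scalar `nu`, and an
  `include_nu` toggle reinstates it multiplicatively for sensitivity
  analyses;
* boundary-separation power: `a(t) = bb * (t/10)^bp` (`RLDDM_bspow`);
  negative `bp` gives a collapsing boundary (faster, less cautious
  responding as learning progresses), positive `bp` a rising reaction-time
  asymptote.

`RLDDM_bspow` is flagged as the winning model and is the default everywhere
downstream. Within-trial variability parameters of the full DDM and other
collapsing-bound families are out of scope.

## Likelihood

The likelihood of a (choice, reaction time) pair is the Wiener first passage
time (WFPT) joint density. `wfpt_density()` evaluates the lower-boundary
density with the classic dual-series representation - a small-time
expansion over mirrored starting points and a large-time Fourier sine series
- switching automatically to whichever needs fewer terms, truncated for
absolute error below 1e-7; the upper-boundary density follows by reflection
(`z -> 1 - z`, drift sign flipped). Reaction times at or below `t_nd`
return zero density rather than an error, which makes likelihoods robust
under parameter proposals. `session_loglik()` replays a session
sequentially, maintaining values per condition pair, summing log densities
over non-omitted trials; omitted trials contribute nothing and leave the
values unchanged (the subject saw no outcome).

The density is validated against an independent brute-force oracle
(`diffusion_oracle()`): plain Euler-Maruyama paths with no crossing
correction, kept deliberately naive so the two routes share no code path.
The behavioural simulator itself uses an Euler scheme *with* within-step
Brownian-bridge crossing probabilities, which removes the leading
discretization bias, so a step of 1e-3 s suffices for simulation while the
oracle runs at 1e-4 s.

## Synthetic cohorts

Because the study's patient data are not deposited, a generator stands in
for them as a first-class, tested module. `group_spec()` describes a group
by parameter means (natural scale), spreads (on the sampling scales: logit
for `alpha`, log for `nu`, `bb`, `t_nd`, identity for the powers) and a
severity model. The defaults in `default_group_specs()` encode the study's
qualitative structure:

* controls: `alpha` 0.25, `nu` 3.5, `bb` 1.2, `bp` -0.25, `t_nd` 0.35 s -
  brisk evidence accumulation and a collapsing boundary;
* depression groups: lower drift scalar (2.0 unipolar / 2.4 bipolar),
  higher boundary power (-0.05 / -0.10) and longer non-decision time
  (0.45 / 0.42 s) - the psychomotor-slowing profile - with identical
  learning rates, since reward sensitivity rather than learning rate is the
  reported locus of abnormality.

The spread values (0.5 logit units for `alpha`, 0.25 log units for `nu`,
0.15 for `bb` and `t_nd`, 0.12 for `bp`) give realistic between-subject
overlap: group differences are detectable at n = 20/group but not trivially
so. Severity ratings follow a linear map from the slowing parameters,
`HAM-D = round(c0 - 2*nu + 10*bp + 30*t_nd + noise)` clipped at zero with
noise SD 2.5, then `HAM-A` as an affine function of HAM-D. The intercepts
(8 unipolar, 3 bipolar) put the simulated depression groups around means of
16 and 10 with a span of roughly 5-25, and controls (all slopes zero,
intercept 0.5) near zero - matching the reported clinical ranges. The
positive `t_nd` coefficient makes severity increase with non-decision time,
the coupling the correlation analyses probe. The severity map includes the
`t_nd` term precisely because non-decision time is a slowing parameter; a
map without it would make the package's severity analyses vacuous.

What the generator does *not* emulate: within-subject parameter drift,
lapses and fast guesses, missing data other than slow-response omission,
medication effects, and any neuroimaging signal. Passing tests on synthetic
cohorts therefore demonstrate that the estimation and analysis machinery is
correct and adequately powered under the model's own assumptions - not that
the model is true of real patients.

## Hierarchical estimation

`fit_hierarchical()` estimates a two-level model: subject parameters on
transformed scales are Normal around group means with group spreads; group
means carry weakly-informative Normal priors and spreads half-Normal
priors. The priors are a package choice (the source analysis delegated them
to an existing implementation without stating them): on the transformed
scales, Normal(-1, 1.5) for logit `alpha`, Normal(0.8, 1) for log `nu`,
Normal(0.3, 0.8) for log boundary parameters, Normal(-1.1, 0.8) for log
`t_nd`, Normal(0, 0.5) for the powers, with half-Normal spreads of scale
0.3-0.6. `t_nd` is sampled on the log scale; its hard upper bound (no
reaction time below `t_nd`) is enforced by the likelihood returning zero
density, so proposals beyond a subject's fastest response are simply
rejected.

Sampling is an adaptive Metropolis-within-Gibbs scheme written in C++:
conjugate Gibbs updates for group means, Metropolis on log spreads,
per-coordinate adaptive random-walk Metropolis for subject parameters
(Robbins-Monro adaptation toward 0.44 acceptance during warm-up only, so
the post-warm-up kernel is fixed), plus interweaved non-centered moves that
translate or rescale a whole parameter column jointly with its group mean
or spread. The interweaving is essential: with weakly-identified subject
parameters the centered Gibbs kernel mixes the group level an order of
magnitude more slowly. Any sampler meeting the convergence thresholds is
considered compliant; the defaults mirror the study design (4 chains, 1000
warm-up, 3000 sampling iterations). Raising `iter` with proportional
`thin` is the supported way to buy effective sample size at fixed memory.

Convergence is assessed per parameter with the rank-normalized split
Gelman-Rubin statistic (maximum of the bulk and folded versions) and the
tail effective sample size (minimum of the ESS of the 5% and 95% quantile
indicators, Geyer initial-monotone autocorrelation sums on split chains).
The acceptance rule - max split R-hat < 1.01 and min tail-ESS > 400 - is
enforced as a gate: downstream analyses refuse a flagged posterior unless
explicitly overridden, and a flagged fit always warns, never passes
silently. Degenerate inputs are defined rather than fatal: constant chains
report a tail-ESS of 0; subjects with no usable trials are excluded with a
warning.

## Model comparison, recovery, predictive checks

`kfold_elpd()` implements 5-fold cross-validated expected log predictive
density. Folds partition *trials within subject*, stratified by trial type,
so every fold's training set retains all subjects (subject-level parameters
are needed to predict any held-out trial); held-out trials are masked out of
the likelihood but their outcomes still drive the observed learning path,
since the subject did see them. A held-out trial's contribution is the log
of the posterior-mean trial likelihood; differences between variants are
computed per trial and summed, with `sqrt(n) * sd` standard errors
(`compare_models()`). Outputs are labelled `elpd` from k-fold
cross-validation; approximate leave-one-out estimators are deliberately out
of scope. The base RLDDM serves as the comparison baseline.

`parameter_recovery()` simulates subjects from a generating distribution
with generous spreads (so regressions span a usable range), refits, and
regresses recovered posterior means on the truth. `posterior_predictive()`
re-simulates each subject per posterior draw and compares observed
per-condition block means (18-trial blocks; with 60 trials per type the
fourth block is partial) of choice accuracy and mean reaction time against
the 95% highest density interval of the simulated means; the HDI is the
narrowest interval, not equal-tailed.

## Derived signals and statistics

`compute_traces()` replays a session with posterior-mean parameters
(point-estimate mode is the default; per-draw propagation is available by
calling it per draw), recording both options' values at decision time and
the prediction error at outcome time. The decision-time "value signal" is
the chosen option's value by default, with a chosen-minus-unchosen
difference mode behind a flag. Zero prediction errors join the positive
category (a measure-zero tie-break); neutral trials generate no prediction
error. `detrend_values()` subtracts the control group's per-trial mean -
removing the bias the shared trial sequence imposes - and is linear, so
constant offsets survive and cross-subject correlations are unchanged.
`section_means()` aggregates over the full task and within-type sections
1-20 / 21-40 / 41-60; empty cells propagate as `NA`, never zero.

Group statistics follow the reporting conventions of the field:
Cohen's d for a model parameter from group means and SDs over pooled
subject-level posterior samples, p-values from two-sample t-tests on
per-participant posterior means (pooled-variance Student by default - the
convention is ambiguous, so Welch sits behind a flag), with d > 0 meaning
group b exceeds group a; one-sample t-tests against zero for detrended
value means; Pearson correlations with Fisher-z intervals for severity.
No multiple-testing correction is applied by default, matching
overall-pattern reporting; `adjust_pvalues()` provides Benjamini-Hochberg
when wanted. Event tables for neuroimaging first-level designs are exported
with raw (uncentred) modulators; onsets are reconstructed from the response
times and the schedule's jittered 3-13.75 s inter-stimulus intervals plus
fixed 1 s feedback and 1.5 s inter-trial periods (the original
stimulus-optimized sequence is irrelevant to behaviour and not
reproducible).

## Numerical choices and problem sizes

Degenerate and edge inputs are handled explicitly: zero-spread generating
specs flag recovery regressions as degenerate; single-subject groups yield
an undefined p with d still computed; constant inputs flag correlations and
one-sample tests rather than erroring. All randomness flows through
explicit seeds - R-side draws through a locally-scoped RNG state and
C++-side simulation through a seeded xoshiro256+ generator with
Marsaglia-polar normals, so results are bit-reproducible across platforms
and never disturb the caller's RNG.

The test suite and the acceptance script run study-shaped but scaled-down
problems, chosen to exercise every claim at desk scale: density validation
against 3 x 10^5 brute-force paths per parameter setting at a 1e-4 s step;
parameter recovery with 30 subjects x 180 trials under reduced sampler
settings (4 chains, 600 warm-up + 1200 sampling); model selection on an
8-subject boundary-power cohort with 2 chains per fold; effect recovery
with 20 controls versus a combined 37-subject depression group; and a
5-subject reference fit at 4 chains x (1000 + 6000, thinned by 3) for the
convergence gate. These sizes are the package's own trade-off between
statistical resolution and a comfortable desk runtime; all of them can be
scaled up by the corresponding arguments.

## Known limitations

* The sampler is a random-walk scheme: robust and dependency-free, but far
  less draw-efficient than gradient-based samplers; budget iterations
  accordingly for large cohorts.
* Point-estimate traces understate uncertainty in derived signals; the
  per-draw mode exists but is not the default.
* The generator's omission model (censoring at the response window) is the
  only missingness mechanism; attentional lapses are not modelled.
* Neutral-trial values are fixed by construction, so neutral trials inform
  only the decision parameters, not learning.
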