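---
title: "Models and methods in qpupil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in qpupil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

qpupil analyses probabilistic reinforcement learning behaviour and
task-locked pupillometry in within-subject drug crossover designs, of the
kind used to study noradrenergic (e.g., atomoxetine) effects on learning.
This vignette explains the models, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The behavioural task and the Q-learning model

The emulated task presents two stimulus pairs: a *gain* pair (choosing
well wins £0.50 with 75% probability, otherwise nothing) and a *loss*
pair (choosing badly loses £0.50 with 75% probability). A session has 96
trials, 48 per condition, interleaved at random within blocks of 12
(balanced 6/6 per block by default). A *hit* is a choice of the
advantageous option.

Behaviour is modelled with the standard two-parameter Q-learning model.
The Rescorla–Wagner delta rule updates the expected value of the chosen
stimulus–action pair,

    Q[t+1](s, a) = Q[t](s, a) + alpha * (r[t] - Q[t](s, a)),

and the softmax choice rule maps values to choice probabilities,

    P(a | s) = exp(beta * Q(s, a)) / (exp(beta * Q(s, a)) + exp(beta * Q(s, a'))),

with learning rate `alpha` in [0, 1] and inverse temperature `beta` in
[0, 10]. Both are computed in logistic/log-sum-exp form for numerical
stability. Two open choices had to be fixed:

* **Initial Q-values.** Q0 = 0 for every pair and condition, so the first
  choice is uniform. This is the neutral choice consistent with chance
  behaviour before any feedback.
* **Outcome units.** Outcomes are coded in pounds (+0.5/0 gain, 0/−0.5
  loss). `beta` multiplies value differences on this scale, so its
  effective range interacts with the coding; the coding is the package
  default and is configurable only by supplying different schedules.

"Too late" (no-response) trials carry no observed choice and are simply
absent from a sequence; likelihood and hit-rate denominators shrink
accordingly.

## Hierarchical Bayesian estimation

The model is fit per task condition, with non-centred hierarchical
structure: unconstrained participant values are
`mu + sigma * nu` with `nu ~ N(0, 1)`, and bounds are enforced by the
probit transform, `alpha = pnorm(alpha')`, `beta = 10 * pnorm(beta')`.
In the crossover design, atomoxetine-session parameters shift the
placebo values on the unconstrained scale by participant-specific
offsets `Delta = mu_Delta + sigma_Delta * nu_Delta` before the
transform. Priors are standard normal on all `mu` and `nu` and
half-normal(0, 1) on all `sigma`.

**Sampler.** No Stan backend is available in the target environment, so
`sample_posterior()` implements Hamiltonian Monte Carlo directly: the
joint log density and its analytic gradient (including the exact
derivative of the choice log-likelihood with respect to `alpha` via the
recursion `dQ/dalpha`) are evaluated in C++; warmup adapts the step size
by dual averaging (target acceptance 0.8 by default) and estimates a
diagonal metric from the middle half of warmup; sampling uses a
randomised number of leapfrog steps to avoid resonance. `sigma`
parameters are sampled on the log scale with the Jacobian included, so
the support constraint can never be violated. The reference
configuration is 4 chains × 10,000 iterations (2,000 warmup); the
package's tested desk-scale configuration is 4 × 2,000 (1,000 warmup),
which reaches split-R̂ < 1.1 on 20-participant synthetic cohorts in
seconds. Chain initial values are drawn `N(0, 0.5)` in the unconstrained
space. Divergent trajectories (energy error beyond 1000) are counted and
reported, never silently dropped.

Convergence is summarised by split-R̂ (each chain halved, pooled versus
within-half variance); constant parameters report `NaN` with a flag
rather than failing. Goodness of fit is examined with graphical
posterior predictive checks on binned learning curves
(`posterior_predictive_check()`), which report the fraction of observed
bins inside the central 89% replicated interval. The discrete envelope
makes that coverage conservative (often 1.0 on self-consistent data), so
tests assert only its lower edge.

## Posterior summaries and the joint parameter space

Group-level natural-scale means are `pnorm(mu)` (times 10 for `beta`),
with the offset mean added first for the atomoxetine state; drug
contrasts are computed draw-wise (atomoxetine minus placebo), never on
summaries. Summaries follow the probability-of-direction / ROPE / 89%
HDI convention:

* `p_dir`: percent of draws strictly on the dominant side of zero (zeros
  count for neither side).
* ROPE: ±0.1 × a point estimate (posterior median) of the group SD of
  the parameter, with `< 2.5%` inside read as reject-null and `> 97.5%`
  as accept-null. The package's group SD point estimate is the posterior
  median of the across-participant SD of natural-scale values.
* HDI: narrowest contiguous sample window holding 89% of draws; among
  tied widths the window with the smallest lower bound is returned
  (deterministic). Note the location of this window has sampling noise
  of about ±0.02 on 10^5 normal draws, which matters when asserting its
  endpoints.

The "optimal strategy" analysis simulates mean hit rate over an
(`alpha`, `beta`) grid (defaults: step 0.02 × 0.25, 1,000 agents/cell,
configurable; the source analysis left resolution to supplementary
material, so these are engineering choices). In this stable 75/25
environment the optimal `beta` is the top of its range (10), and the
optimal `alpha` is lower for gain than for loss. Per MCMC draw, the
Euclidean distance between the group-mean (`alpha`, `beta`) point and
the optimal point is computed in raw natural units — `beta` therefore
dominates the distance, mirroring the joint-space axes; a normalised
option exists but is off by default. Negative drug contrasts of the
distance mean the drug moved the group towards the optimum.

## Pupil preprocessing and cluster inference

Traces are preprocessed per trial in a fixed order: (1) blink runs
shorter than 500 ms are linearly interpolated between the medians of
100 ms anchor windows (anchored at the window centres; boundary blinks
fall back to a one-sided constant fill and are logged), while any run of
500 ms or more discards the trial; (2) a second-order low-pass
Butterworth filter is applied forward–backward (zero phase, with
steady-state edge initialisation) — the cutoff is **not stated in the
source pipeline**, so the package default is 4 Hz, a common pupillometry
choice, and configurable; (3) the per-trial baseline is the median of
the final 500 ms of fixation; (4) trials with baselines outside
mean ± 2 SD within a participant–session are removed, with the SD
computed once before removal (no iterative re-exclusion) and a zero-SD
session excluding nothing; (5) the baseline median is subtracted from
all samples. The exclusion uses pre-correction baselines, matching the
stated order of operations. Analysis then takes the first-order temporal
derivative (per-sample difference, deliberately not divided by the
sampling interval) over the first 1000 ms of the outcome phase, and
z-scores it within participant × session.

Cluster inference compares per-participant condition averages with
paired t-statistics per timepoint; runs of |t| above the two-sided 0.05
t-quantile (df = n−1, configurable) form clusters per sign whose mass
(CMS) is the summed t. The null distribution is the maximum |CMS| per
sign-flip permutation, pooled over signs (family-wise control across
time and directions), with p = (1 + #{null ≥ |CMS|}) / (1 + N). This
paired sign-flip scheme replaces an LMM-based permutation backend; for a
balanced two-level within-subject factor the two target the same effect.
Zero-variance timepoints are treated as t = 0.

## Plausible-values correlation

To relate a covariate (e.g., the atomoxetine-induced change in baseline
pupil diameter) to latent participant-level parameter effects without
the bias of correlating point estimates, the Pearson correlation between
the covariate and the per-participant drug effect (atomoxetine minus
placebo natural-scale parameter, computed inside each draw) is evaluated
for every MCMC draw, giving a distribution of plausible sample
correlations. For population inference, each draw's r is turned into an
analytic posterior of the population correlation rho under a uniform
prior on (−1, 1):

    p(rho | r, n)  ∝  (1 − rho²)^((n−1)/2) (1 − rho r)^(−(n−3/2))
                      ₂F₁(1/2, 1/2; n − 1/2; (1 + rho r)/2),

evaluated on an equally spaced grid of 1,999 points on (−0.999, 0.999),
normalised per draw, then averaged. The hypergeometric factor is summed
as a series (fast for the n used here). Because this closed form is a
choice the package makes, the test suite validates the density against
a brute-force
Monte-Carlo posterior (simulated bivariate-normal likelihood of r given
rho, flat prior) at three (r, n) points. Draws with |r| = 1 are clipped
to 1 − 1e−9 and counted.

**A caveat the tests make explicit.** Plausible values propagate
estimation uncertainty — they do not remove it. With 48 trials per
condition, each draw's participant-level drug effect carries posterior
noise comparable to the true between-participant spread, so the
plausible-r distribution is attenuated towards zero relative to the
generative latent correlation (empirically by a factor of ~0.4–0.7 at
the task's data scale). The acceptance suite runs the recovery test at
the stated task scale and reports this honestly; a green antisymmetry
and density-validation suite alongside a red recovery band indicates
attenuation, not an implementation defect. Recovering a generative
correlation of 0.5 to within 0.2 would require participant-level
effects identified well beyond what 48 binary choices support.

## The synthetic-data generator

`generate_task_schedule()` draws per-trial outcome assignments i.i.d.
with p = 0.75 for the advantageous option (switchable to exact counts);
block composition is balanced 6 gain + 6 loss per block of 12, the
natural reading of randomisation within blocks. `generate_cohort_behaviour()`
draws probit-scale deviations per participant and condition, builds
placebo/atomoxetine parameters through the same transforms the model
assumes, and simulates both sessions on independent schedules. Default
hyperparameters place the placebo group near alpha ≈ 0.1 and beta ≈ 2.7
with a +3-unit group beta effect under drug — the moderate regime the
fitted estimates suggest. The pupil generator produces
fixation (3.5 s) / stimulus (uniform 0.5–2.5 s, response-terminated) /
outcome (2.5 s) phases at 500 Hz by default, as tonic baseline (per
drug state, optionally drifting as a random walk across trials) plus a
biphasic outcome-locked response (Gaussian dilation bump, default
120 units at 300 ms, then a constriction bump, 80 units at 650 ms) plus
white noise and lognormal-duration blinks (median 150 ms, 5% forced
beyond 500 ms to exercise the discard rule).

What the generator does **not** emulate: gaze-dependent pupil
foreshortening, luminance confounds (the source stimuli were
luminance-matched), saccade artefacts, and any dependence of the pupil
response on trial outcome value. A green pupil test therefore
establishes the preprocessing arithmetic and the inference's error
control, not robustness to real eye-tracker pathology.

## Numerical and testing choices

* Random leapfrog counts are capped at 64; energy errors beyond 1000
  are treated as divergences.
* The flat-task optimal-grid check uses absolute bounds rather than
  binomial SEs: exploitative agents produce autocorrelated choice runs,
  inflating per-cell Monte-Carlo noise well beyond the i.i.d. formula.
* Acceptance tests use the criteria's own reduced configurations
  (e.g., 4 × 2,000 iterations, 500 agents/cell, a 2-replicate smoke of
  the 10-replicate recovery suite) so the suite stays inside a desktop
  budget; the full-scale configurations remain available through the
  public interfaces.
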