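---
title: "Two adaptive designs for a two-arm binary-outcome trial: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two adaptive designs for a two-arm binary-outcome trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsim)
```

# The setting

`adaptsim` implements, side by side, the two designs that were specified for
the same confirmatory question in the SHINE trial (Stroke Hyperglycemia
Insulin Network Effort): a two-arm 1:1 randomized comparison of intensive
glucose control against standard care in acute ischemic stroke, with a
binary *favorable neurologic outcome* assessed 90 days after enrollment as
the primary endpoint and a preliminary assessment of the same construct at
6 weeks.  The design values are a 25% favorable rate on control, a
clinically meaningful improvement to 32% on treatment, a maximum of 1,400
patients, two-sided 5% type I error and 80% power.

The executed design was a frequentist group-sequential trial; the
alternative, fully prespecified at the same time, was a Bayesian
"Goldilocks" sample-size-selection design.  The package provides both
engines, a patient-level trial generator with the statistical structure the
designs assume, and Monte-Carlo operating-characteristic estimation, so the
two approaches can be compared under controlled truths or virtually
executed over a stored patient-level dataset.

# The Bayesian Goldilocks design

## Decision structure

Interim analyses occur when 500 patients have been randomized and after
every additional 100, up to the 1,400 maximum (`interim_schedule()`).  At
each interim two predictive probabilities of *trial success* are computed
by Monte Carlo over posterior-predictive completions of the current data
(`predictive_probabilities()`):

* **PPn** — the probability that the trial succeeds at the final analysis
  if accrual stops now and every randomized patient completes follow-up;
* **PPmax** — the probability of success if the trial instead enrolls to
  the 1,400 maximum under 1:1 allocation.

Accrual stops early for predicted success when PPn exceeds 99%; the trial
stops for futility — bindingly — when PPmax falls below 5%.  Success at the
final analysis means the posterior probability that the treatment arm's
favorable rate exceeds the control arm's is at least 97.9%.  That critical
value compensates for the repeated interim looks: it was chosen so the
design's overall one-sided type I error stays below 2.5%, and
`calibrate_final_threshold()` reproduces the choice by simulation (on a
0.002 grid with 1,000 simulated null trials it selects 0.979; the package's
simulated type-I curve crosses 2.5% between 0.977 and 0.979).

All priors are the noninformative uniform `Beta(1, 1)`.  The posterior
probability of superiority is computed by deterministic quadrature, not
simulation, so the final analysis is exactly reproducible (see *Numerical
choices*).

## The longitudinal model

Interims are timed by the number randomized, so some patients lack the
90-day outcome.  Patients with a 6-week outcome contribute through a
longitudinal transition model (`fit_transition_model()`): for each arm and
each 6-week state $j \in \{0, 1\}$, a conjugate beta posterior for
$P(y_{90} = 1 \mid y_6 = j)$ is fitted from the patients with both outcomes
observed.  A completion draws the three rates (two conditionals plus the
marginal, used for patients with no outcome at all) from their posteriors
and then draws the missing outcomes as Bernoulli — the rate re-draw on
every completion is what propagates the *uncertainty* in the 6-week/90-day
association rather than plugging in a point estimate.  Patients with
neither outcome carry no information: their completions come from the
arm's marginal posterior predictive, which is exactly the no-information
contribution.

Two parameterization questions were genuinely open:

* **Arm-specific or pooled conditionals.**  The transition model is fitted
  per arm by default, so no treatment effect is borrowed across arms
  through the early endpoint; `pooled_transition = TRUE` covers the other
  reading.  The marginal rate posteriors are always arm-specific — they
  *are* the treatment comparison.
* **Disabling the model.**  `use_longitudinal = FALSE` imputes the
  6-week-observed patients from the marginal posterior instead.  On
  snapshots matched to the margins of the motivating trial's final interim,
  the futility decision is the same with and without the longitudinal
  model, mirroring the sensitivity analysis reported for the original
  virtual execution (this is asserted in the test suite).

## Seeding

One master seed drives a virtual execution; each interim draws from a
substream keyed by `seed + milestone`.  A decision at one interim therefore
never perturbs the draws of a later one, and decision logs are reproducible
bit for bit.

# The group-sequential comparator

Interim analyses occur when 500, 700, 900 and 1,100 consecutively
randomized patients have completed 90-day follow-up (information fractions
$t_k = n_k/1400$), with a final analysis at 1,400.  Two-sided efficacy and
inner futility z boundaries come from Gamma-family (Hwang–Shih–DeCani)
error spending,

$$\alpha(t) = \alpha \frac{1 - e^{-\gamma t}}{1 - e^{-\gamma}},$$

with efficacy spending computed under the null and futility (beta)
spending under the design alternative's drift ($\delta \approx 2.91$ at
full information for 25% vs 32%).  Per-look bounds are solved by the
standard recursive numerical integration over the canonical joint law of
sequential z statistics (correlation $\sqrt{t_j/t_k}$).

The published design did not print its spending shape parameters, so the
package's defaults ($\gamma_{\text{eff}} = -3.995$,
$\gamma_{\text{fut}} = -4.202$) are least-squares calibrations of the
recursion to the published per-look bounds — `calibrate_gamma_spending()`
reproduces them, with fitted bounds within about 0.01 of the printed
values (2.97, 2.86, 2.65, 2.42 for efficacy; 0.06, 0.13, 0.45, 1.05 for
futility).  `shine_boundaries()` ships the printed table itself, and
passing it as `boundary_table` bypasses spending entirely — operating
characteristics quoted against the published design use this path, so they
do not depend on an unprinted parameter.  The final-look bound is then
completed so the total two-sided efficacy crossing probability under the
null, ignoring the (nonbinding) futility bound, equals 5%; for the printed
table this gives $z_5 = 2.022$.

The executed trial's futility bound was nonbinding (a crossing could be
overruled); `run_gs()` reports `futility_signal` and continues unless
`stop_on_futility = TRUE`.  Operating-characteristic simulation treats
futility as binding, because the published design-stage numbers came from
binding-rule simulation and a monitoring committee's discretion is not
simulable.

The interim test statistic is the unpooled two-proportion z on complete
cases.  The executed trial's covariate-adjusted, multiply-imputed statistic
is deliberately out of scope: its adjustment model is not specified here,
and the z-path law under the null — which drives the operating
characteristics — is the same.

# The synthetic-data generator

`generate_trial()` draws what both designs assume:

* **Accrual** — a homogeneous Poisson process, default 0.55 patients/day.
  The motivating trial never published its accrual assumption; this value
  is calibrated so that at the 500-randomized interim roughly 85–90% of
  patients have completed 90-day follow-up, the information pattern of the
  published first-interim log (432 of 498).
* **Randomization** — 1:1 permuted blocks of 4 (the Bayesian alternative
  did not use response-adaptive randomization).
* **Outcomes** — the 90-day outcome is Bernoulli with the arm's marginal
  rate; the 6-week outcome is then drawn conditionally on it, with defaults
  $P(y_6 = 1 \mid y_{90} = 1) = 0.85$ and
  $P(y_6 = 1 \mid y_{90} = 0) = 0.15$.  The original publications state
  only that the 6-week outcome predicts the 90-day outcome; conditionals
  given the final outcome make that predictive value directly tunable and
  imply $P(y_{90} = 1 \mid y_6 = 1) \approx 0.65$ under the null rate.
* **Missingness** — none by default (the executed trial's
  multiple-imputation handling of missing outcomes is out of scope); a
  `missing_prob` flag produces missing-completely-at-random outcomes for
  robustness exercises.

What the generator deliberately does *not* emulate: site effects, drift in
accrual or outcome rates over calendar time, a dropout *process* (as
opposed to marginal missingness), the clinical sliding-dichotomy
construction of the favorable-outcome flag from stroke-severity-specific
modified-Rankin cutoffs (the flag is consumed already dichotomized), and
response-adaptive randomization.  Passing operating-characteristic checks
under this generator therefore validates the decision machinery under the
design's stated statistical model, not the designs' behaviour under those
real-world complications.

# Numerical choices

* **Posterior probability of superiority.**  $P(p_T > p_C)$ for
  independent beta posteriors is computed by Gauss–Legendre quadrature
  after a probability-integral transform: the integral runs on the
  probability scale of the *narrower* posterior, where the companion cdf is
  a smooth monotone function.  This absorbs the beta density entirely —
  robust to shape parameters below 1, whose densities are unbounded at the
  support edge — and achieves absolute accuracy well inside $10^{-6}$ with
  128 nodes (verified against adaptive quadrature and $10^6$-draw Monte
  Carlo in the tests).  Interim predictive draws reuse the same routine
  with 64 nodes (accuracy about $10^{-5}$), since the Monte-Carlo error of
  the predictive draws is orders of magnitude larger; repeated
  count-pairs within a draw set are memoized.
* **Boundary recursion.**  Sub-densities of the still-running z process are
  propagated on a grid of step 0.01 with Simpson weights; first-look
  quantities use the exact normal cdf, so the single-look case reproduces
  the fixed-sample critical value 1.959964 to $10^{-6}$.  Transition
  kernels depend only on the information fractions and drift and are
  cached, which makes the least-squares gamma calibration cheap.  Grid
  accuracy for multi-look crossing probabilities is about $10^{-4}$,
  ample against the 0.05 reproduction tolerance for printed bounds and
  checked against forward Monte Carlo of the correlated z paths.
* **Predictive probabilities.**  Count-level vectorization: a completion
  draws per-arm rates, then binomial counts for each observation stratum
  (6-week favorable, 6-week unfavorable, no outcome, future patients), so
  cost is independent of patient numbers.  PPn and PPmax are by
  construction invariant to patient ordering and monotone in the final
  success threshold under a common seed.
* **Threshold calibration.**  The interim predictive draws do not depend on
  the candidate final threshold, so one execution per simulated trial
  yields the per-draw superiority values, which are then thresholded across
  the whole candidate grid (common random numbers).  Calibration over a
  ten-point grid costs the same as a single operating-characteristic run.
* **Ties and boundary values.**  Success stopping requires PPn strictly
  above 99%, futility strictly below 5%, final success at-or-above the
  posterior threshold; milestone interims count randomized patients
  exactly.  Degenerate inputs (empty strata, zero denominators, priors with
  no data) fall back to the prior or raise informative errors; the
  two-proportion z is defined as 0 when the observed proportions are equal.

# Problem sizes for simulation summaries

Reported operating characteristics in the test suite and the
reproduction script use 2,000 simulated trials with 2,000 posterior
predictive completions per interim for the Goldilocks design (Monte-Carlo
standard errors about 0.6 percentage points on a 91% futility probability
and about 6 patients on the expected sample size), 2,000 patient-level
trials for group-sequential power, and $10^5$ canonical z paths for
boundary-crossing probabilities.  Threshold calibration uses 1,000 trials
per grid point via the common-random-numbers scheme above.

# Known limitations

* The virtual-execution comparison of the original publication used the
  actual patient-level trial data, which are not redistributable; the
  package demonstrates the same interim *decisions* on synthetic snapshots
  matched to the printed interim margins, and its generator-based operating
  characteristics agree with the published design-stage numbers within
  their Monte-Carlo bands.  The published exact per-interim predictive
  probabilities (21.1%, 39.7%, 15.6%, 2.0%) cannot be reproduced without
  those data.
* Expected enrolled sample size for the group-sequential design depends on
  the accrual overrun model (patients enrolled while the milestone-th
  completer finishes follow-up); with the default accrual the simulated
  value is near 1,090 against the published design-stage 1,039, inside the
  10% band but sensitive to the unpublished accrual assumption.
* Two arms, binary endpoint, uniform priors only.  No hierarchical
  borrowing, no response-adaptive randomization, no sample-size
  re-estimation (the executed trial's blinded re-estimation did not change
  its sample size and its rule is unpublished).
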