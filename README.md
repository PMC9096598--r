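# adaptsim

Bayesian "Goldilocks" and frequentist group-sequential adaptive designs for
two-arm randomized trials with a binary primary outcome, with a
patient-level trial simulator and Monte-Carlo operating-characteristic
estimation.

## The problem

Confirmatory trials waste patients when they run to a fixed sample size
that hindsight shows was too large (the question was already answered) or
pointless (the treatment was never going to win). Two adaptive answers to
this right-sizing problem were fully prespecified for the same clinical
question — intensive glucose control versus standard care in acute
ischemic stroke, with a binary *favorable neurologic outcome* at 90 days
(design rates 25% control vs 32% treatment, maximum n = 1400, two-sided 5%
type I error, 80% power), and an earlier assessment of the same outcome at
6 weeks:

* **A frequentist group-sequential design** (the executed SHINE trial):
  interim z-tests when 500, 700, 900 and 1100 consecutively randomized
  patients have completed 90-day follow-up, with two-sided efficacy and
  nonbinding inner futility boundaries from Gamma-family
  (Hwang–Shih–DeCani) error spending,

  α(t) = α (1 − e^(−γt)) / (1 − e^(−γ)),

  closely resembling an O'Brien–Fleming boundary.

* **A Bayesian Goldilocks design** (the prespecified alternative): interims
  after 500 randomized patients and every 100 thereafter. At each interim,
  two predictive probabilities of trial success are computed over
  posterior-predictive completions of the data — **PPn** (success if
  accrual stops now and follow-up completes) and **PPmax** (success if the
  trial enrolls to the maximum). Accrual stops for predicted success when
  PPn > 99%; the trial stops, bindingly, for futility when PPmax < 5%.
  Incomplete 90-day outcomes of patients with a 6-week assessment are
  imputed through a longitudinal beta-binomial transition model
  P(y90 | y6), with the association's uncertainty propagated by re-drawing
  its rates on every completion. The final analysis declares success when
  P(p_T > p_C | data) ≥ 97.9%, a critical value calibrated by simulation to
  keep the one-sided type I error below 2.5% despite the repeated looks.
  All priors are uniform Beta(1, 1).

The package implements both engines over a common patient-level data
model, a seeded generator of such data (Poisson accrual, permuted-block
1:1 randomization, conditionally linked 6-week/90-day outcomes, correct
snapshot censoring), posterior-superiority computation by deterministic
quadrature, group-sequential boundary derivation by the canonical
recursion, and operating-characteristic simulation for either design.

## Worked example

Virtually execute both designs on one simulated null trial (no treatment
effect, both arms 25% favorable):

```r
library(adaptsim)

params <- generator_params(p90_treatment = 0.25, p90_control = 0.25, seed = 7)
trial  <- generate_trial(params)

run_goldilocks(trial, goldilocks_config(n_draws = 2000, seed = 7))
#> Goldilocks execution: stopped for futility at n = 500; no final analysis (binding futility)
#> Interim decision log:
#>  milestone n_enrolled n_complete90 prop_treatment prop_control pp_current
#>        500        500          450         0.2277       0.2743          0
#>  pp_max        action
#>  0.0025 stop_futility

run_gs(trial, gs_config(boundary_table = shine_boundaries()),
       stop_on_futility = TRUE)
#> Group-sequential execution: futility at n = 944 (z = -0.230); success = FALSE
#>  look n_complete n_enrolled x_t n_t x_c n_c       z        action
#>     1        500        549  61 250  68 250 -0.7159      continue
#>     2        700        749  86 350  95 350 -0.7772      continue
#>     3        900        944 112 450 115 450 -0.2303 stop_futility
```

Reading the Goldilocks log: at the first interim (500 randomized, 450 with
a 90-day outcome) the treatment arm trails 22.8% to 27.4%; the predictive
probability of success with the current patients is 0 and even at the full
1400 it is 0.25% — below the 5% futility bound, so this trial stops after
500 patients. The group-sequential execution of the *same* dataset waits
for completer milestones and crosses its inner futility bound
(|z| = 0.23 ≤ 0.45) at the third look, by which time 944 patients are
enrolled. That enrolled-versus-analyzed gap (944 vs 900) is the accrual
overrun: patients randomized while the 900th completer finished follow-up.

Journal-style effect reporting reproduces printed unadjusted risk
differences exactly:

```r
risk_difference(two_by_two(102, 483, 102, 453))
#> Risk difference, % (95% CI): -1.4 (-6.7 to 3.9)
```

Operating characteristics under a named scenario:

```r
simulate_ocs("goldilocks", "null", n_sims = 2000, seed = 1,
             config = goldilocks_config(n_draws = 2000))
# expected enrolled N, P(early futility), P(success), stop distribution, MC SEs
```

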