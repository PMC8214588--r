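# markovboot

Markov cohort cost-utility analysis of add-on nabiximols (Sativex®)
oromucosal spray versus standard care for multiple sclerosis spasticity,
with the probabilistic sensitivity analysis (PSA) performed by **stratified
bootstrapping of the source data** instead of the conventional parametric
Monte Carlo simulation.

## Who this is for

Health economists and biostatisticians who build Markov cohort models from
patient-level trial data and want uncertainty estimates that (a) avoid
parametric distributional assumptions and (b) preserve the correlations
between model parameters — here, between transition probabilities and state
utilities estimated from the same patients — that an independent-parameter
Monte Carlo PSA discards.

## The model

Seven Markov states: {mild, moderate, severe} spasticity on add-on
treatment, the same three on standard care alone (reached by treatment
discontinuation, with no re-initiation), and absorbing death. Severity is
graded on the 0–10 spasticity NRS: mild < 3.3 ≤ moderate ≤ 6.6 < severe.
The cohort runs 65 cycles of 28 days (5 years, 13 cycles/year), with

* per-cycle 3×3 severity transition matrices estimated from patient-level
  trial data (relative transition frequencies, conditional on remaining on
  treatment and alive; missing observations excluded, never imputed),
* treatment discontinuation 0 / 3.8% (cycles 2–4) / 3.5% (cycle 5+) and
  background mortality ramping 0.020% → 0.035% per cycle,
* state utilities = pooled means of utility observations classified by
  concurrent NRS (published values 0.594 / 0.509 / 0.499),
* drug costs from the dosing schedule (6.9 → 7.7 → linear 7.3→6.2 → 6.2
  sprays/day) at €466.40 per 3×90-spray pack, and standard-of-care costs
  from a Delphi panel (8 experts) priced at unit-cost tariffs,
* discounting at 3.0%/year (costs) and 1.5%/year (QALYs).

Outcomes are discounted incremental costs ΔC, incremental QALYs ΔQ, the
ICER ΔC/ΔQ, and dominance (ΔC < 0 and ΔQ > 0) at horizons of 1–5 years.

The PSA follows the stratified bootstrap algorithm: each replicate redraws,
with replacement and at original size, the three trial strata (53 + 53
randomised patients, 84 single-blind-only) and the 8 panel experts, then
re-estimates *all* parameters jointly and reruns the model. An
independent-parameter Monte Carlo engine (Dirichlet transition rows, normal
utilities, gamma costs) is included as the comparator.

No patient-level data from the source trial are deposited publicly, so the
package ships a synthetic-data generator (`generate_trial()`,
`generate_delphi_panel()`) that emulates the trial design — 190 enrolled,
responder-gated wash-out, 53/53 double-blind randomisation — with known
ground truth, including a tunable coupling between patients' severity
trajectories and utility levels. External inputs the original analysis took
from non-redistributable sources (standard-care transition matrices, unit
costs) ship as clearly-labelled synthetic stand-ins under `inst/extdata/`.

## Worked example

```r
library(markovboot)

cfg    <- generator_config()                  # trial-design defaults
trial  <- generate_trial(cfg, 1)
dp     <- generate_delphi_panel(cfg, 2)
inputs <- list(trial = trial, panel = dp$panel, tariffs = dp$tariffs)

run_scenario("base", inputs, mode = "point")
#> <cua_evaluation> scenario: base
#>  horizon delta_costs delta_qalys  icer dominant
#>        1        2964      0.0351 84448    FALSE
#>        2        4287      0.0693 61857    FALSE
#>        3        5090      0.0906 56197    FALSE
#>        4        5579      0.1037 53783    FALSE
#>        5        5876      0.1118 52535    FALSE

psa <- run_scenario("base", inputs, mode = "bootstrap",
                    n_replicates = 1000, seed = 3)
psa$summary$table[5, c("delta_qalys", "delta_qalys_lo", "delta_qalys_hi",
                       "dominance_probability", "prob_qaly_gain")]
#>   delta_qalys delta_qalys_lo delta_qalys_hi dominance_probability prob_qaly_gain
#> 5   0.1097475     0.04899317      0.1719065                     0          0.999
```

Reading: on this synthetic dataset the add-on arm gains 0.11 QALYs per
patient over 5 years (95% bootstrap interval 0.049–0.172, probability of
any QALY gain 99.9%) at an extra cost of €5,876, i.e. an ICER of €52,535
per QALY — not dominant under the synthetic stand-in cost inputs. The
`"s1"` and `"s2"` scenarios rerun the same pipeline with the standard-care
matrices taken from the placebo stratum, or with the treatment effect
stopped after the trial window while drug costs continue.

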