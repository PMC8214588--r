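---
title: "Model, estimators, and bootstrap PSA: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimators, and bootstrap PSA: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovboot)
```

This vignette is the package's own account of its science: the cohort
model and its conventions, the estimators, the two PSA engines, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The cohort model

Spasticity severity on the 0–10 numerical rating scale (NRS) is collapsed
into three ordered states. The verbal definitions — mild below 3.3, severe
above 6.6, moderate "between" — leave the boundary assignment open; we read
the middle interval as closed, so mild = [0, 3.3), moderate = [3.3, 6.6],
severe = (6.6, 10]. This matches the verbal cut-offs exactly, partitions
[0, 10] with no gaps or overlaps, and is frozen in `classify_nrs()`.

The model has seven states: the three severity states on add-on treatment
(`sat_*`), the same three on standard care alone (`soc_*`), and absorbing
death. A patient discontinuing treatment moves to the standard-care state
of *identical severity* and thereafter follows standard-care transitions
with no drug cost; the seven-state structure admits no other destination,
and this matches the model lineage this implementation follows.
Standard-care states place no mass on treatment states (no re-initiation).
`compose_full_matrix()` layers, in order, death (probability `d_death`),
then discontinuation (`(1 - d_death) * d_disc` to the same-severity
standard-care state), then the 3×3 severity matrix over the remainder.

Structural constants (all overridable in `model_config()`): 65 cycles of
28 days; 13 cycles per model year, so horizon *h* years = cycles 1..13*h*;
discontinuation 0 in cycle 1, 3.8% per cycle in cycles 2–4 and 3.5%
thereafter; background mortality a linear per-cycle ramp from 0.020% (age
51) to 0.035% (age 56). The initial severity distribution is not published;
the default 0 / 0.5 / 0.5 over mild / moderate / severe is a documented
placeholder consistent with the trial's moderate-to-severe entry criterion,
and any substantive analysis should set it explicitly.

### Accrual and discounting conventions

Costs and QALYs accrue on **start-of-cycle occupancy**: the transition
happens at cycle end, so a cohort annihilated in cycle 1 still accrues one
cycle. No half-cycle correction is applied — the model lineage does not use
one — and the convention is fixed and testable rather than silently mixed.
QALYs for cycle *c* are `sum(occupancy * utility) * 28 / 365.25 *
discount_factor(c)`.

Discounting uses the exact elapsed-time exponent `(1 + r)^-(t)` with
`t = (c - 1) * 28 / 365.25` years, so cycle 1 is undiscounted and factors
decrease smoothly and order-consistently. Because the source analysis does
not state its timing convention, the alternative per-completed-year step
(`t = floor(elapsed years)`) is available via
`model_config(discount_method = "annual")`; the difference is bounded by
one year of discounting (about 1.5–3%) and is the tolerance we attach to
any comparison against externally printed totals.

### Published transition matrices

The published per-cycle matrices for the add-on arm are printed with
discontinuation already removed: each printed row sums to `1 - d` for that
cycle's discontinuation `d` (the printed cycle-4 mild row sums to 0.962 =
1 − 0.038 exactly, which is the evidence for this reading).
`load_published_matrix()` divides the printed rows by `1 - d` and
renormalises each row to sum to exactly 1, recovering the severity matrix
conditional on remaining on treatment; `compose_full_matrix()` then puts
`d` back. The round-trip reproduces the printed entries within ±0.002
(print rounding), which the acceptance suite verifies. Base-case
extrapolation carries the cycle-5 matrix forward to cycles 6–65, exactly as
the printed "cycle 6+" block states; mortality continues its ramp.

## Estimators

`estimate_transition_matrix()` counts observed severity transitions between
consecutive observation cycles and divides by the per-row at-risk count.
Patients missing either endpoint are excluded from that row only; missing
data are never imputed, because imputation would distort exactly the
uncertainty the bootstrap is meant to measure. A row with zero at-risk
patients is returned as the identity row and flagged (warning class
`markovboot_empty_row`) rather than failing: small bootstrap replicates
must always yield a usable schedule, and the flag keeps the substitution
auditable. A cycle with no observations at all raises an error, which is a
different condition from a sparse row.

Each patient contributes one NRS value per cycle — the data format carries
cycle-level summaries, pre-aggregated from diaries upstream, because the
source design maps visits and diaries onto 28-day cycles without stating
the aggregation rule. `estimate_utilities()` attributes every utility
observation to the severity state of its concurrent NRS and pools the
arithmetic mean over all patients, cycles and strata: the analysis uses a
single set of three state utilities shared by both arms, which is how the
published values (0.594 / 0.509 / 0.499) are reported.

For the on-treatment arm, cycles 1–2 are estimated from all strata (every
patient receives add-on treatment in the single-blind phase, and only
wash-out completers are observed at the cycle-3 endpoint), and cycles 3–5
from the randomised active stratum. The estimator itself is agnostic about
cycle semantics: it consumes whatever cycle labels the data carry.

## Costing

Drug cost per cycle is `sprays/day × 28 × price_per_spray` with
`price_per_spray = 466.40 / 270`. Fractional sprays are priced
continuously: the source states no wastage rule, and a whole-pack rounding
mode (`rounding = "pack"`) is provided for sensitivity exploration rather
than as a default assumption. Drug costs attach only to `sat_*` states.

Care costs per severity state are the Delphi panel's expert-mean resource
quantities priced at unit-cost tariffs, identical in both arms. Experts are
aggregated by the arithmetic mean — the conventional Delphi point estimate,
and the quantity the bootstrap perturbs by resampling experts. Tariffs are
point values deliberately excluded from resampling: tariff uncertainty is
minimal compared with the spread in expert resource-use estimates. Panel
quantities are per 28-day cycle by definition of the file format.

## The stratified bootstrap PSA

Each replicate draws, with replacement and at original size, (1) the 53
randomised active-arm patients, (2) the 53 randomised placebo patients,
(3) the remaining single-blind-only patients, and (4) the 8 panel experts;
then re-estimates transition matrices and utilities from the combined
resampled trial data, recomputes state costs from the resampled panel,
rebuilds both arms' schedules, and reruns the cohort model. Stratification
preserves the trial's phase structure exactly on every replicate. Because
all trial-derived parameters are recomputed *jointly* from the same
resampled patients, correlations among them — e.g. between favourable
transitions and higher utilities when the same patients drive both — carry
through to the outcome distribution. Under scenario `"s1"` the
standard-care matrices are re-estimated from the resampled placebo stratum
inside each replicate; the base case and `"s2"` keep the external
standard-care matrices fixed, mirroring the fact that uncertainty in an
external literature source cannot be bootstrapped from patient-level data.

One root seed spawns an independent substream per replicate, so results
are bit-reproducible and invariant to evaluation order. An identity-resample
hook (`identity_resample = TRUE`) turns the PSA into copies of the
point-estimate run, which pins the whole pipeline to the deterministic
path in tests.

Summaries are empirical: dominance probability = fraction of replicates in
the south-east quadrant of the cost-effectiveness plane (ΔC < 0, ΔQ > 0);
95% intervals are 2.5th/97.5th percentiles with linear interpolation
(plain percentile method, no BCa — matching the B = 1,000 presentation).
ICER intervals are percentiles of the per-replicate ratio, which is how
the results are presented, but ratio percentiles are ill-behaved when the
cloud spans plane quadrants, so quadrant counts are always reported
alongside and should be read first.

## The Monte Carlo comparator

`run_monte_carlo_psa()` is the conventional engine the bootstrap replaces:
per replicate it samples every parameter independently — each transition
row from a Dirichlet with concentration *row at-risk count × estimated
probabilities* (the per-row multinomial count, which the estimator records;
note structural zeros stay zero), each state utility from a normal with the
estimated mean and naive standard error, each state cost from a
moment-matched gamma — and reruns the model. Two known properties of this
comparator are worth stating because the test suite demonstrates them:

* **Parameter correlations are discarded.** In bootstrap replicates the
  re-estimated utility level and the re-estimated improvement probabilities
  co-move when the generator couples patients' trajectories and utilities;
  the Monte Carlo draws are independent by construction. The suite measures
  this at the parameter level, where the contrast is clean.
* **Outcome-level correlation is *not* a clean discriminator.** Within any
  faithful MC replicate the sampled transition matrices are used
  model-wide, and transitions drive both ΔQ and (through severity occupancy
  times the care-cost gradient) ΔC. Both engines therefore show strong
  corr(ΔQ, −ΔC); `scripts/acceptance.R` reports both correlations so the
  comparison is explicit. A near-zero MC outcome correlation would require
  a negligible care-cost gradient across severity states, which would
  contradict the Delphi costing design.
* **Naive dispersion understates utility uncertainty.** The MC utility
  standard errors use `sd/sqrt(n_obs)`, ignoring that observations cluster
  within patients (the generator's patient-level random effect gives an
  intraclass correlation near 0.85 at the defaults). The bootstrap
  resamples whole patients and therefore captures the clustering; the MC
  comparator's ΔQ variance is accordingly smaller — roughly half at the
  default settings. This is deliberately left uncorrected: it is the
  textbook failure mode of the comparator, not a defect to patch.

## The synthetic-data generator

`generate_trial()` emulates the source trial's structure: 190 patients with
moderate-to-severe baseline NRS enter a single-blind add-on cycle; early
responders (NRS improvement ≥ 20% versus baseline) enter a wash-out cycle;
re-qualifying patients are randomised 53/53 into active versus placebo
add-on for three further cycles. Severity evolves under per-phase latent
3×3 chains (defaults: the published base-case matrices, back-converted to
conditional form, for the active path; a distinctly less favourable chain
for placebo); NRS values are drawn uniformly within the state's band;
utilities are state means plus a patient random effect (SD 0.12) plus
observation noise (SD 0.05), clipped to [−1, 1]; post-baseline
observations are lost with probability 0.05 (responder gating uses the
clinic-known pre-loss values).

Two generator choices deserve justification:

* **Exact design counts.** Responders are the `round(134/190 × n)` patients
  with the largest realised relative improvement, and a random subset of
  `round(106/134 × k)` of them passes wash-out. Independent Bernoulli gates
  at the same rates would leave fewer than 106 qualifiers in roughly half
  of all runs and make the 53/53 randomisation infeasible; conditioning on
  the design counts reproduces the 53/53/84 stratum structure every time,
  which is also how the single realised trial looks to the analyst. The
  wash-out pass is a fixed-count random subset rather than a simulation of
  NRS rebound dynamics: the published stopping rule for wash-out is
  ambiguous and none of the estimators consume wash-out dynamics.
* **The coupling knob.** A latent propensity `z ~ N(0,1)` per patient tilts
  their transition rows toward improvement with strength
  `|rho| × tilt_scale × z` (exponential tilting, destinations scored
  +1/0/−1 for mild/moderate/severe), while the utility random effect is
  `sigma_p (rho z + sqrt(1 − rho²) eps)`. The sign of `rho` thus lives
  entirely on the utility side, so the correlation between a patient's
  utility effect and their realised improvement carries the sign of `rho`,
  and at `rho = 0` transitions and utilities are exactly independent and
  the latent chains are realised without distortion — which is what the
  parameter-recovery tests exploit.

What the generator does **not** emulate: SF-36 item responses or the
utility mapping chain (utilities arrive as precomputed values, as in the
analysis), dropout for specific reasons, NRS autocorrelation within a
state band, or dose titration heterogeneity. Passing tests therefore show
that the pipeline recovers the truth of *this* data-generating process,
not that the published trial numbers are reproduced — the patient-level
source data are not publicly deposited, and the packaged standard-care
matrices and tariffs are synthetic stand-ins (files suffixed
`_synthetic`), so absolute cost results in examples should not be read as
estimates for the real setting.

## Scenarios

* `"base"`: on-treatment matrices from trial estimates (cycles 1–5, then
  carry-forward); standard-care matrices external.
* `"s1"`: standard-care matrices from the placebo stratum. The source does
  not detail the cycle mapping; we use the placebo estimates for the cycles
  matching the double-blind phase, carried *back* over the two
  pre-randomisation cycles and *forward* past the trial window, mirroring
  the base case's carry-forward. Setting the external matrices equal to
  the placebo estimates makes `"s1"` and `"base"` coincide exactly, which
  the tests assert.
* `"s2"`: conservative; from cycle 6 the on-treatment states follow the
  external standard-care matrices while drug costs continue to accrue.

## Numerical choices and test scales

Row-stochasticity is enforced at 1e−8 on inputs and holds to 1e−12 on
estimates; traces conserve probability to 1e−9 over 65 cycles. Quantiles
use R's default type 7 (linear interpolation). Degenerate inputs are
first-class: identity rows for empty transition rows, collapsed intervals
for zero-variance replicates, `NA` ICER when ΔQ = 0 (and ΔQ = 0 is never
flagged dominant).

Test problem sizes are the package's own trade-off between statistical
resolution and a suite that runs in minutes: estimator consistency uses
5,000 patients with five pooled transition cycles of a homogeneous chain;
end-to-end recovery uses a 50,000-patient cohort so the ±0.02 entrywise
tolerance sits at ≥3 binomial standard errors for every estimable row;
the bootstrap-SE calibration averages five source trials (400 replicates
each) against 200 regenerated trials, because a single 190-patient trial's
bootstrap SE is itself variable by ±25%; the interval-coverage check runs
40 experiments of 150 replicates against the generator-implied truth.

## Known limitations

Uncertainty in the external standard-care matrices is not (and cannot be)
bootstrapped — only scenario `"s1"` makes it data-driven. The ICER
percentile intervals inherit the usual ratio pathologies across quadrants.
Utilities are pooled over arms and phases; no age-dependent utility
decrements or per-arm utility sets are modelled. The model is a cohort
expectation, not a microsimulation: patient-level heterogeneity enters
only through the estimators and the PSA, not the trace.
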