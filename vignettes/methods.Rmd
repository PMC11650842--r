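---
title: "Methods: within-trial cost-effectiveness analysis in trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-effectiveness analysis in trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The evaluation model

`trialcea` implements the standard within-trial economic evaluation of a
1:1 cluster-randomised trial over a sub-year horizon, from the perspective of
a resource-constrained healthcare system that also wishes to see
productivity losses. The estimand is the pair (ΔC, ΔE): the between-arm
difference in mean per-patient costs (USD) and in mean per-patient QALYs,
and the decision quantities derived from them — the incremental
cost-effectiveness ratio ICER = ΔC/ΔE, and the net monetary benefit
NMB(λ) = ΔE·λ − ΔC at a willingness-to-pay threshold λ.

Assumptions inherited from this design:

- **No discounting.** The horizon is 0.5 years; `analysis_config()` carries a
  `discount_rate` field that must be 0, making the assumption explicit
  rather than implicit.
- **Intention to treat.** Every randomised participant enters the analysis;
  loss to follow-up is a missing-data problem, not an exclusion rule.
- **Cluster randomisation, individual-level analysis.** The default
  bootstrap resamples participants within arm, reproducing the common
  analytic practice for trials whose published intervals show no design
  effect adjustment; a cluster bootstrap (`resampling_unit = "cluster"`)
  resamples whole clusters and is the more defensible option when
  within-cluster correlation is non-negligible.

## Costing

Costs accrue in four blocks per patient over the trial: direct medical
(consultations, screening tests, medication spend, inpatient nights), direct
non-medical (transport, recommended food servings), indirect (productivity
loss), and intervention delivery (phone calls/SMS, peer supporters,
intensive training sessions). Quantities are priced in Nepali rupees against
a `price_schedule()` and converted at a fixed exchange rate (125.20 NRs per
USD, the 2022 average); all arithmetic is unrounded internally, and currency
is rounded to 2 decimals only in reports. The shipped unit prices are
synthetic placeholders with realistic magnitudes — they stand in for a
hospital price list that is not redistributable — so absolute cost levels in
examples are illustrative while the pipeline's behaviour is not.

Indirect costs follow the human capital approach: an inpatient day is a full
8-hour workday and an outpatient visit a 4-hour half-day, valued at the
daily minimum unskilled wage, with no friction-period adjustment.
Cluster-shared intervention costs (two peer supporters per cluster, trainer
session rates, materials) are divided equally over the heads of the cluster;
participants with no delivery at all (the control arm) carry an intervention
cost of exactly 0.

## Utilities and QALYs

EQ-5D-3L profiles are valued by an additive tariff: utility = 1 − the sum of
dimension-level decrements, minus an optional constant once any dimension is
at level 3. The tariff is configuration data, not code: the package ships a
toy tariff (0.1 per level step, for documentation and tests) and a
*synthetic* TTO tariff with the typical structure of published South-Asian
value sets (floor −0.594); a study would inject its own country tariff as a
CSV. Utilities below 0 (worse-than-dead states) are legitimate values and
QALYs are never floored at 0.

QALYs accrue by trapezoidal area under the utility curve,
`0.5 × (u0 + u1)/2` for the two-timepoint half-year case. This is the
standard within-trial convention; with baseline utilities near 0.90 it
reproduces arm QALY magnitudes near 0.43 over six months. QALYs are
reported to 4 decimals, money to 2, ICERs to 2.

## Estimation

Incremental costs and QALYs come from identity-link GLMs with a treatment
dummy; β₁ is the adjusted increment. Costs adjust for age and sex under a
gamma family; QALYs adjust for baseline utility under a Gaussian family. The
modified Park test (log squared residuals on log fitted values of a
provisional Gaussian fit) estimates the mean–variance power; its slope is
mapped to a family by nearest integer with exact x.5 ties resolved toward
the lower-variance family, and observations with non-positive fitted values
are excluded with a count reported.

Numerical choices:

- GLMs are solved by iteratively reweighted least squares
  (`stats::glm.fit`) with OLS starting values and a 100-iteration cap;
  non-convergence is an error carrying the deviance, never a silent result.
- Gamma-type families exclude zero outcomes, so when zeros are present every
  outcome is lifted by the smallest observed positive value × 10⁻³; under
  the identity link this uniform shift leaves the treatment contrast
  unchanged and is recorded in the fit object.
- In the unadjusted two-group model, the identity-link score equations make
  β₁ the raw difference in arm means for *every* family; the bootstrap uses
  this closed form when no covariates are requested, which is what makes
  500-replicate-by-500-trial coverage simulations cheap. The equivalence
  itself is a tested invariant, not an assumption.

Uncertainty is nonparametric bootstrap: replicates resample participants
with replacement within arm (preserving arm sizes), refit both models, and
store the (ΔC, ΔE) pairs. Point estimates are full-sample fits; intervals
are percentile intervals using the (B+1) order-statistic convention of
Davison & Hinkley, so bounds are always elements of the draw set. Replicates
with degenerate designs are redrawn, and more than 1% redraws raises a
warning. ICER percentile intervals are flagged unstable when effect draws
straddle ΔE = 0 — the ratio changes sign there, which is how a
"negative lower ICER limit" arises in published tables; the plane
probabilities are the reliable summary in that regime.

Loss to follow-up blanks the follow-up EQ-5D and VAS; because resource use
is also collected at follow-up, the pipeline treats the cost and QALY
outcomes of lost participants as missing too. Missing outcomes are multiply
imputed (m = 5 by default) by normal-model regression with posterior
parameter draws, conditioning on arm, age, sex, residency and baseline
utility; imputed costs are clamped at 0, their support boundary. The
imputation-bootstrap nesting runs the bootstrap *within* each completed
dataset (B/m replicates each): per-imputation point estimates are pooled by
Rubin's rules (total variance W + (1 + 1/m)·B, t reference with Rubin
degrees of freedom), and the stacked draws across imputations feed the
percentile intervals, plane and CEAC. The alternative nesting
(bootstrap-then-impute) is costlier and was not required.

## Decision quantities

The threshold is λ = GDP per capita × 3 (US$4,140 at US$1,380), the
WHO-CHOICE convention. A draw counts as cost-effective when its NMB is
strictly positive, and as cost-saving when ΔC < 0; draws with NMB exactly 0
count as *not* cost-effective, matching the "NMB > 0" decision framing. In
the north-east quadrant, ICER < λ, NMB > 0 and "cost-effective" are the same
statement, and this identity is asserted in tests. The CEAC evaluates the
NMB rule over a λ grid (default 0 to 3λ in 101 points) and equals the plane
probability exactly wherever the grids meet.

## Scenario analyses and the printed-rounding convention

Scenario transforms operate on arm-level summary means, as published
scenario tables do: residency sub-groups re-run the pipeline within the
stratum; component exclusions subtract one intervention component's
per-patient mean from the intervention arm; ±10% scenarios scale arm mean
costs and QALYs.

Published scenario tables are assembled from increments rounded to reporting
precision (2 decimals for money, 4 for QALYs) *before* the ICER division —
under unrounded arithmetic, scaling costs and effects by the same factor
would leave the ICER exactly invariant, yet published tables show it
drifting by a few USD. `rounding_mode = "printed"` reproduces this
convention (with half-up commercial rounding, since R's default half-even
rule disagrees on exact halves such as 0.00825); `"unrounded"` gives the
analytically clean variant, and the two differ by under 1% at the magnitudes
involved. This reverse-engineered convention is the key interoperability
detail of the scenario module.

One scenario family scales only selected cost categories (screening and
intensive training) in both arms by ±10%; it is implemented from each arm's
own category means. Published versions of this row are not always internally
reconstructible (the control-arm shift implied by the printed numbers does
not match the printed category means), so it is exercised for behaviour, not
for agreement with any printed ICER.

## The synthetic trial generator

The generator emulates the study conditions end to end: 30 clusters (15 per
arm), 238 intervention and 243 control participants spread round-robin over
their arm's clusters; age from a truncated normal (54.4 ± 9.4 years, window
30–70); 52.8% male; 64.2% semi-urban; 7.9% loss to follow-up, completely at
random. Its defaults are the published arm-level moments and are not tuning
knobs.

- **Costs.** Each of the ten cost categories is drawn independently per arm
  from a gamma distribution moment-matched to the published per-category
  mean and SD (shape = mean²/SD², scale = SD²/mean); categories with mean 0
  in an arm (intervention components in the control arm) are exactly 0. Only
  marginal moments are published, so no cross-category correlation is
  modelled — summed totals therefore have a somewhat smaller SD than the
  printed total-cost SD, a documented limitation. Non-intervention
  categories are emitted as resource *quantities* (continuous six-month
  aggregates) chosen to round-trip exactly through `price_resource_use()`,
  so the costing stage is genuinely exercised by pipeline runs;
  intervention components are emitted as per-participant USD costs, since
  only their cost footprint — not delivery counts — is modelled.
- **Utilities.** Baseline utility is a scaled Beta on [floor, 1] matched to
  mean 0.90, SD 0.13 — bounded, right-skewed toward the ceiling, as EQ-5D
  data are. Follow-up utility is the mixture u₁ = w·u₀ + (1−w)·v with
  tracking weight w = 0.4 and v a scaled Beta whose mean is solved so that
  E[u₁] hits its target: 0.7908 in the control arm plus a +0.03
  intervention effect, making the trapezoidal QALY difference exactly
  0.0075. A convex combination of variables on [floor, 1] stays on
  [floor, 1], so no truncation is needed and every arm-level expectation is
  available in closed form — this is why the mixing form was preferred over
  additive normal noise with truncation, whose truncation bias would have
  broken the closed-form calibration that `truth_summary()` provides to
  parameter-recovery tests.
- **What is not emulated.** Profile-level EQ-5D bimodality (an optional
  nearest-profile projection emits discrete profiles, slightly perturbing
  moments); cross-category cost correlation; informative missingness (the
  rate is the only published fact, so dropout is MCAR); within-cluster
  correlation (no ICC is published — an optional additive cluster effect on
  follow-up utility exists with default 0, and nothing in the defaults
  induces a design effect). Consequently the published between-person QALY
  SDs (~0.107) are not reproduced — they are not jointly consistent with
  the published baseline utility SDs under any plausible baseline–follow-up
  correlation on the bounded utility scale — and passing tests say nothing
  about cluster-robust inference on real data.

A single master seed drives everything; per-stage substreams (demographics,
utilities, costs, missingness, imputation, each bootstrap) are derived from
it deterministically, so a fixed configuration reproduces its dataset and
report bundle bit for bit.

## Problem sizes in the test suite

Structure tests run on reduced trials (6–8 clusters, 60–90 per arm).
Distributional checks use 6,000 draws per arm with tolerances set at five
analytic Monte-Carlo standard errors. The coverage experiment simulates 500
trials at full size (481 participants) with 500 bootstrap replicates each,
using the closed-form unadjusted bootstrap; parameter recovery uses one
20×-size trial (9,620 participants). The acceptance script runs the full
pipeline at B = 10,000 with m = 5 imputations, the replicate count used in
practice for published CEACs.

## Known limitations

- Scenario transforms on summary means cannot propagate sampling
  uncertainty; re-running the pipeline per scenario on participant-level
  data is available for sub-groups but not bootstrapped by default.
- The probability of cost-effectiveness is a function of the bootstrap
  draw cloud; PSA approaches that place parametric distributions on inputs
  instead (common in spreadsheet implementations) can report very different
  probabilities from the same point estimates, and no attempt is made to
  reconcile the two.
- The gamma-offset policy for zero costs is a pragmatic device; with many
  zeros a two-part model would be the right tool and is out of scope.
- Whether the cost outcome should include the intervention delivery cost
  itself is left as a switch (`include_intervention_cost`), defaulting to
  inclusion; published adjusted/unadjusted increment pairs do not
  disambiguate the choice.
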