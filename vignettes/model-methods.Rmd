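---
title: "Methods: budget impact and cost-utility modelling of the coronary sinus reducer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: budget impact and cost-utility modelling of the coronary sinus reducer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reducerHTA)
```

## The problem

Refractory angina leaves patients with debilitating symptoms, reversible
ischemia, and no revascularization option; they accumulate hospitalizations,
emergency admissions, coronary angiographies, repeat PCIs and outpatient
visits. The coronary sinus reducer is a one-off implant that relieves
symptoms in most — but not all — of these patients. Two economic questions
follow for a national payer: *affordability* (what does wider uptake do to
the budget over five years?) and *efficiency* (what does a QALY gained
through the device cost?). The package answers the first with a two-scenario
budget impact model and the second with a success/failure decision tree.

## Budget impact model

The eligible population comes from a multiplicative funnel
(`build_funnel()`): a base population and ordered stage proportions, with
counts rounded **half up** to whole patients at every stage. Half-up rather
than banker's rounding is deliberate: it is what reproduces the published
stage counts 245,771 → 29,493 → 17,696, and it is the convention used in
published funnel tables generally.

Two market mixes share this pool. Device shares evolve linearly
(`share(y) = share(1) + (y−1)·increment`) and are kept at full precision;
the comparator share is the exact complement. The eligible pool is constant
by default (`annual_incident_eligible = 0`, `annual_mortality = 0`): the
published analysis describes incident inflow and mortality but never prints
their values, so the package treats them as first-class, documented
parameters defaulting to a prevalent-pool world rather than hiding guessed
constants. Consequently the published absolute totals (€649M scale) are
declared out of scope; the engine reproduces the *shape* of that analysis
from any complete parameter set.

Costs per patient-year (`per_patient_annual_cost()`) are
`Σ rate_d × unit_cost_d + weighted drug cost`, plus the implant in the first
year in the implant arm. Patients newly captured by a rising device share
are new implants that year and pay the implant once; in later years they pay
only recurring costs. One modelling choice needs flagging: the recurring
costs and event counts of implanted patients are the **responder mixture**
`p_success·(reducer profile) + (1 − p_success)·(SoC profile)`. A pure-arm
reading (implanted patients always get the reducer's low event rates) would
make the responder fraction irrelevant to the budget impact, yet the
one-way sensitivity analysis of this model class identifies it as the
single largest driver; the mixture is the only reading consistent with
that. Non-responders keep full drug therapy; responders get the (default 0)
`drug_reduction_on_reducer`.

The budget impact is **undiscounted by default**, as is standard for
affordability analyses (the published discounting statement concerns the
cost-utility model only); `differential_budget_impact(..., discounted =
TRUE)` exposes discounting for exploration. Reported quantities: yearly and
cumulative differential (revised − current), avoided events per driver
(current − revised), per-scenario totals and average annual impact
(total/horizon, exactly).

## Cost-utility model

A cohort (default 10,000 per arm) enters a decision tree: implant succeeds
with probability `p_success`, giving utility `utility_success`; failure
reverts to `utility_soc`. Standard of care is the pre-implant management
period, utility `utility_soc`. Annual cycles carry an alive/dead state: the
alive fraction is the cumulative product of the per-arm survival schedule
times `(1 − annual_mortality)`; the dead accrue zero cost and zero utility.
Effectiveness is constant over the horizon — the package deliberately does
*not* model the 30%/year effect decay assumed by the earlier registry-based
analysis, because longer-term device studies report sustained benefit.

Costs: implant-arm year 1 uses the implant-inclusive €15,702; later years
mix €2,550 (responders) with the SoC €6,988 (non-responders); the SoC arm
pays €6,988 every year. These per-patient values are taken from the
published registry figures rather than re-derived from the unit-cost ×
rate tables, because the published cohort totals are close to the former
and not to the latter; both routes remain configurable
(`parameters_from_estimates()` rebuilds tree costs from rates when that is
wanted).

Two defaults are **inferences, not published values**, and are documented
as such: `p_success = 0.9451` back-solves the published year-1 implant-arm
QALY total (5,864.285 per 10,000 = `p·0.594 + (1−p)·0.456`), and
`annual_cost_reducer_later = 2550` back-solves the published year-1→2
cumulative cost increment after undoing one year of discounting. With them
the base case crosses into dominance at year 4 (the published table shows
year 3); the published table's later horizons are not exactly recoverable
from its printed inputs (its own two-year ICER differs between table and
narrative), so only its internal arithmetic — increments, ICER ratios,
dominance verdicts — is reproduced, via `reference_results()`.

Discounting: 3.5%/year on both costs and QALYs, first model year
undiscounted (`1/(1+r)^(y−1)`), the convention under which the published
year-1 row equals the undiscounted per-patient products. A
`first_year_discounted` flag switches conventions. No half-cycle correction
is applied — the model class uses plain yearly accounting; the flag-free
simplicity is preferred over a correction the source never describes.

Verdicts: dominant iff ΔC ≤ 0 and ΔQ > 0, dominated iff ΔC > 0 and ΔQ ≤ 0,
equivalent at (0,0); the measure-zero edge ΔC < 0, ΔQ = 0 is labelled
dominant (weak dominance) so division by zero can never occur. A
cheaper-but-less-effective (southwest) result is reported as a ratio, not
dominance.

## Sensitivity analyses

**Tornado (`one_way_dsa()`).** Each registered parameter — responder
fraction, the five SoC event rates, annual mortality, drug-therapy
reduction — is set to base×(1∓0.15) with everything else at base, and the
target (cumulative budget differential, or the 5-year cost/QALY ratio) is
recomputed by the full model; entries are ranked by absolute swing.
Probabilities are clamped to [0, 1] after perturbation (0.9451 × 1.15 would
exceed 1). Parameters with a zero base (mortality, drug reduction in the
base case) have zero swing by construction — a ±15% *relative* perturbation
cannot move them — so their published qualitative ranking is only testable
under assumed non-zero bases.

**Probabilistic (`run_psa()`).** Probabilities and utilities get beta
distributions by the method of moments (`k = m(1−m)/v − 1`, `v = (0.15·m)²`;
infeasible moments are an error, a zero SD a point mass); frequencies and
costs get normals truncated at zero via the inverse-CDF method (the
truncation's mean shift is negligible at the default 15% SD, ~6σ from
zero). Parameters are drawn independently — no correlation structure is
specified by the source — in registry order, vectorised across draws, from
one generator seeded once: fixed seed ⇒ bit-identical reruns within this
implementation. Each of the default 1,000 draws reruns the full 5-year
tree; the (ΔC, ΔQ) cloud is summarised by quadrant (SE = dominant), and the
CEAC reports `P(λ·ΔQ − ΔC ≥ 0)` on a €0–100,000/QALY grid (step €1,000,
spanning the €30,000–€40,000 Italian reference band); draws with ΔQ = 0
never enter a division.

## Synthetic cohorts

`generate_cohort()` emulates the *unpublished* patient-level data behind
the registry rates: per patient, uniform administrative follow-up over the
horizon (the real censoring pattern is unknown; uniform is the declared
default), geometric yearly death at `annual_mortality`, Poisson event
counts at rate × observed exposure, Bernoulli responder status, and beta
utilities at the patient's mixture mean with 15% relative SD. Poisson is
the minimal model consistent with "events per patient-year"; overdispersion
is deliberately out of scope, so recovery tests validate the pipeline, not
real-data dispersion. `estimate_parameters()` inverts it (events/exposure,
mean utility, deaths per person-year — the geometric MLE), `km_survival()`
wraps the product-limit estimator on the yearly grid, and
`parameters_from_estimates()` maps estimates back to a full parameter set
(carrying the implant arm's mixture utility with `p_success = 1`, an
expectation-preserving reparameterisation, and rebuilding tree costs from
the estimated rates). What passing recovery tests shows: the generator,
estimators and engines are mutually consistent at the stated n; what it
does not show: that real refractory-angina data follow these families.

## Numerical and testing choices

* Percentages live as fractions internally; formatting happens at the
  reporting edge only.
* YAML round trips are bit-exact (doubles written at 22 significant
  digits); partial configs overlay the packaged base case, but a config
  loaded without a base must be complete, and unknown keys or dotted
  override paths are hard errors.
* Headcounts in the budget model stay fractional (expected values); only
  funnel stages are rounded, since published funnels print integers.
* Problem sizes in the test suite — 50,000-patient recovery cohorts, 100
  replicates of 20,000 patients for verdict recovery, 4,000 Monte Carlo
  draws for the consistency check — were chosen to make 3-standard-error
  bands decisive while keeping the full suite under a minute.

## Limitations

* No Markov morbidity states, CCS-class transitions, placebo-effect
  modelling or effect decay; the tree is intentionally the published
  two-branch structure.
* The published headline totals that depend on unprinted inputs (absolute
  €649M scenario totals, avoided-event counts, per-driver savings) are not
  reproduced and are not acceptance-tested; the engines produce the same
  report shapes from any complete parameter set.
* Costs are Italian tariffs at face value: no currency conversion,
  inflation indexing or tariff-database lookups.
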