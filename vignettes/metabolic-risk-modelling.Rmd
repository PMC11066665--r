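---
title: "Modelling antipsychotic exposure and metabolic syndrome risk in schizophrenia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antipsychotic exposure and metabolic syndrome risk in schizophrenia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmets)
```

## The scientific problem

People with schizophrenia (SCZ) develop metabolic syndrome (MetS) — the
cluster of dyslipidaemia, abdominal obesity, hypertension and hyperglycaemia
— far more often than the general population, and both antipsychotic
medication and genetic predisposition are implicated. Disentangling the two
requires longitudinal registry data: drug-dispensing histories to quantify
treatment, diagnosis streams to date metabolic endpoints, repeated BMI
measurements to track weight, and polygenic risk scores (PRS) to quantify
inherited liability.

`apmets` implements that analysis as a reusable pipeline:

1. **Data model** — typed, validated longitudinal tables (persons,
   dispensing records, diagnoses, measurements, a 15-trait PRS table) read
   from CSV/TSV with a configurable column mapping and a total rejection
   report: every input row is either accepted or listed with a reason code.
2. **Exposure derivation** — per-person supply timelines and all derived
   treatment variables (below).
3. **Cohort construction** — case identification by first qualifying event
   and greedy nearest-neighbour matching of four controls per case on birth
   year with exact sex matching.
4. **Association** — covariate-adjusted marginal scans and forward-stepwise
   multivariate selection over the PRS panel.
5. **Survival** — endpoint-specific Cox proportional-hazards models with
   prevalent-case exclusion.
6. **Trajectories** — a ladder of linear mixed models for BMI over age, with
   scenario predictions and 83% confidence bands.
7. **Synthetic cohort** — a generator with known ground truth standing in
   for the access-restricted registry data, making every stage testable.

## Exposure derivation

All coverage arithmetic uses half-open day intervals `[start, end)` and
integer day counts; a year is 365.25 days throughout. Each purchase
contributes its `days_supplied`; with **stockpiling** (default, standard
proportion-of-days-covered practice) an early refill starts when the
previous supply runs out, rather than discarding the overlap. Four adherence
windows are computed:

* `pdc_1year` — the 365 days from first purchase (truncated at end of
  observation),
* `pdc_lastyear` — the 365 days ending at the *supply end* (the last covered
  day), so the final supply tail is included,
* `pdc_purchase` — first purchase to supply end,
* `pdc_followup` — first purchase to end of follow-up (or death).

Because the follow-up window contains the purchase span,
`pdc_followup <= pdc_purchase` holds for every person. Treatment length is
reported two ways: `ty_purchase` (first purchase to supply end) and
`ty_supply` (days actually covered); their divergence measures treatment
gaps. **Discontinuation** means the supply ended more than a year before the
end of follow-up or death.

The **median chlorpromazine-equivalent dose** converts each agent's daily
dose to chlorpromazine milligram equivalents through a shipped, editable
table of published consensus equivalents (`cpz_table()`), sums concurrently
active purchases per covered day, and takes the median over covered days.
Purchases are grouped into batches separated by supply gaps longer than
`batch_gap_days` (default 90, about a calendar quarter); because the median
is taken over *covered* days only — gap days are excluded entirely rather
than entered as zero dose — long treatment breaks cannot drag the summary
dose toward zero, and the batch partition itself is reported as a
diagnostic (`n_batches`). The dose summary is invariant to splitting one
purchase into two consecutive purchases of the same drug and dose.

Windowed exposure ties treatment intensity to each BMI measurement: the
look-back window `[anchor - 2 years, anchor)` intersected with the treatment
history gives `pdc_window` and a windowed median dose, and
`ty_supply_to_anchor` accumulates supplied years up to the measurement.

Every one of these quantities is tested for *exact* equality against an
independent day-grid oracle that re-simulates coverage one calendar day at a
time with a FIFO stock of dispensed supplies, on a thousand random purchase
histories — the bedrock correctness check of the package.

## Cohort construction

A case's onset is the earlier of the first antipsychotic purchase (ATC
N05A*, excluding lithium) and the first schizophrenia-spectrum diagnosis
(ICD-10 F20–F29), accepted when it falls at ages 15–40 and after a two-year
buffer from the start of electronic records (onset year > 2006, both
configurable). Controls must carry no F* diagnosis and no antipsychotic
dispensing anywhere in their record.

Matching is greedy nearest-neighbour without replacement on absolute
birth-year difference within exact sex strata. Cases are processed scarcest
first (fewest exact-year candidates), with candidate ties broken by a seeded
shuffle fixed at pool construction, making the procedure deterministic.
Greedy assignment is not globally optimal; the test suite compares it with
an exhaustive minimal-assignment oracle on small pools and verifies that it
never beats the optimum and that deviations remain the exception (on
deliberately sparse 8-candidates-for-5-cases pools it finds the exact
optimum about 70% of the time; with a 4-to-1 registry pool exact birth-year
matches are essentially always available). Controls inherit their case's
onset date as the **index date** — the time origin for survival analysis —
since a control has no onset of its own; this is a documented artifact
convention.

## Association and survival models

The marginal scan fits one regression per candidate PRS (logistic for case
status, linear for continuous outcomes such as the median dose), adjusted
for sex, birth year and ten genotype principal components, reporting Wald
estimates and odds ratios with 95% CIs. Forward-stepwise selection then
repeatedly admits the lowest-p candidate below the entry threshold and
rescans the remainder against the enlarged model. The default entry
threshold is the Bonferroni fraction for the 15-trait family (0.05/15 ≈
0.0033); nominal flags are reported alongside. Birth year enters as a
continuous covariate — matching already balances it, and continuous
adjustment is the conservative reading.

Survival records are built per endpoint (type 2 diabetes = E11;
hypercholesterolemia = E78.0; essential hypertension = I10; coronary heart
disease = I20–I25; cerebrovascular disease = I60–I69 plus I21; "any
metabolic disorder" = the union) with time measured in years from the index
date to the first qualifying diagnosis, death or administrative end of
follow-up. Persons with a qualifying code on or before the index date are
excluded (prevalence rule) and the bookkeeping is total: eligible +
prevalent + no-follow-up = cohort size. Cox models use Efron tie handling
(registry dates tie at day resolution); the cohort is pooled with
covariates rather than stratified by matched set, the default the package
documents. The PRS stepwise inside Cox reuses the forward procedure with
the endpoint-family Bonferroni threshold (0.05/6 ≈ 0.0083). The adherence
analysis restricts to treated cases and models first-year adherence
(per SD) against endpoint incidence.

## BMI trajectories

The trajectory ladder contains nested linear mixed models with a
per-subject random intercept and random age slope, all fitted by **maximum
likelihood** (not REML) because the rungs differ in fixed effects and are
compared by likelihood-ratio tests:

* *baseline*: sex, smoking (ever/never), BMI PRS, 10 PCs, age, case status;
* *interaction*: adds case-by-age (different slope for cases);
* *treatment*: adds a quartic polynomial of accumulated treatment-supply
  years.

Smoking is kept as a default-on, flag-controlled fixed effect: it is part
of the scenario definitions even though the minimal covariate listing omits
it, and including it reconciles the two. Age is centred at 27 (the typical
onset age) and the treatment polynomial uses an orthogonalised basis — raw
quartics in years are numerically ill-conditioned — with the basis stored in
the fit so scenario predictions evaluate it consistently. A singular
random-effects covariance triggers a diagonal-structure refit with a
warning. The untreated-case level of the trajectory is carried by an
explicit disease main effect (cases start lower), not by the treatment
polynomial at zero; both parameterisations were possible and the explicit
main effect keeps the untreated trajectory interpretable.

Scenario prediction is population-level (random effects at zero): treatment
years accumulate piecewise-linearly at `treatment_days_per_year / 365.25`
per year from the start age. The confidence band comes from the
fixed-effect covariance through the linear predictor at the normal quantile
of `(1 + level)/2`. The default 83% level is chosen so that *non-overlap*
of two independent equal-variance bands corresponds to a test of equal
means at approximately alpha = 0.05: each band has half-width z ≈ 1.372
standard errors, so non-overlap requires the means to differ by 2 × 1.372
× s, which is 2 × 1.372 / √2 ≈ 1.94 standard errors of the difference —
a two-sided p of about 0.052. The suite verifies the implied rejection
rate by Monte Carlo. The decade gain is the predicted BMI at the
end of a ten-year horizon minus the start value, and is invariant to
shifting the age origin when the model is linear in age.

## The synthetic cohort and what it does (not) show

The generator emulates the registry extract the analysis expects, with
every latent quantity recorded in a truth table:

* 677 cases, 4 matched-eligible controls per case (candidate pool inflated
  1.3-fold so nearest-neighbour matching has slack), 54% female; onset ages
  truncated-normal around 27 (SD 6.9) within 15–40, onset dates 2007–2019,
  follow-up to a 2023-03-31 freeze.
* Case status shifts the PRS mean vector along the schizophrenia column of
  the trait correlation matrix by log(1.75), so the implied logistic model
  has exactly that coefficient on the schizophrenia score and zero on the
  others (the multivariate-normal discriminant identity).
* Dispensing: 88% of cases ever treated; 30/60/90-day supplies; refill gaps
  equal to supplied days inflated by a per-person Beta(3.5, 2.2) adherence
  propensity with lognormal jitter and occasional long breaks; drug
  switching within a per-person drug set weighted toward olanzapine,
  quetiapine and clozapine; 42% of histories stop for good after a
  lognormal duration with median about 2.1 years. These defaults were
  chosen once to reproduce the published cohort's marginal summaries
  (median about 20 purchases, three distinct drugs, median supply years
  about 2.5 against purchase-span years about 6, about 41% discontinuation,
  median chlorpromazine-equivalent dose near 186 mg).
* Metabolic endpoints follow exponential proportional hazards from the
  index date with the published hazard-ratio magnitudes and control rates;
  pre-index prevalence uses one shared uniform per person, so the
  endpoint-specific exclusions overlap heavily as they do in registry data.
* BMI measurements (median 3 per person, mean spacing 330 days, windows
  scattered anywhere in follow-up since measurement timing is
  noninformative) come from the trajectory model itself, with treatment
  years accumulated from the person's own generated dispensing history.
  The trajectory coefficients give decade gains of 1.5 (control), 1.8
  (untreated case) and 4.6 BMI points (case treated 180 days/year): the
  treatment-years slope is `2.8 / (10 * 180/365.25)` per supplied year.
  Random intercept SD 3.5, age-slope SD 0.1 (correlation 0.2), residual SD
  1.2 — reproducing an overall BMI SD near 4.5.

A single root seed expands into named substreams (persons, scores,
dispensing, outcomes, measurements) so adding a stage never perturbs
earlier draws; identical (config, seed) gives byte-identical output.

What passing on synthetic data shows: the estimators recover known
parameters at study scale, calibrations hold, and the plumbing is exact.
What it cannot show: robustness to the messiness of real registries —
informative measurement timing, miscoded diagnoses, in-hospital medication
invisible to pharmacy claims, non-proportional hazards, or selection into a
volunteer biobank. The generator deliberately omits these (measurement
timing is independent of outcome, codes are clean, hazards are exactly
proportional), so real-data use still requires the usual epidemiological
diagnostics.

## Numerical choices and problem sizes

* Day arithmetic is exact integer arithmetic; no floating-point dates.
* The weighted day-median equals the ordinary median of the expanded
  per-day dose vector, including the even-count halfway convention.
* Cox fits use Efron ties; mixed models use `lme4` with derivative checks
  disabled for speed, ML throughout.
* Recovery experiments run at the emulated study size (677 cases / 2,708
  controls): 50 replicates for the Cox and mixed-model surfaces, 100 for
  the logistic surface, 10,000 Monte-Carlo draws for the 83% rule, 1,000
  random histories for the day-grid oracle. These sizes give Monte-Carlo
  error comfortably below the acceptance bands while keeping a full run in
  the minutes range on one CPU.

## A short worked example

```{r example, eval = FALSE}
library(apmets)

sim <- simulate_cohort(generator_config(n_cases = 100, seed = 1))
res <- run_pipeline(run_config(tables = sim, seed = 1, out = "run"))

res$survival_table          # per-endpoint eligible N, events, HR for SCZ
res$trajectory$comparison   # model ladder with likelihood-ratio tests
fit <- res$trajectory$fits$treatment
decade_gain(predict_trajectory(fit, trajectory_scenario("treated_case")))
```

## Known limitations

* Depot versus oral routes are not distinguished; in-hospital medication is
  out of scope (invisible to dispensing data).
* Matching is greedy without replacement; no calipers or propensity scores.
* Cox models are pooled with covariates; matched-set stratification and
  competing-risks formulations are not implemented.
* The PRS stepwise explores single-addition paths only, not best subsets.
* Endpoint ICD-10 maps are configurable defaults, not a clinical standard.
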