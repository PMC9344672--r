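---
title: "Relapse in polymyalgia rheumatica: criteria, agreement and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relapse in polymyalgia rheumatica: criteria, agreement and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrelapse)
```

## The problem

Polymyalgia rheumatica (PMR) is an inflammatory rheumatic disease of older
adults, treated with oral glucocorticoids (typically prednisolone starting
around 15 mg/day) that are tapered stepwise after remission. During the
taper a large fraction of patients — roughly a third within the first year
— relapse, and the field has no uniform definition of what counts as a
relapse in routine-care records. Two operational criteria are in common
use:

* **RJ (rheumatologist judgement)**: the treating rheumatologist judges
  the patient not in remission at a visit, or the rheumatologist and/or
  patient report a relapse since the previous visit;
* **TI (treatment intensification)**: the prednisolone dose was increased
  between visits (or an increase advised), a DMARD was started or
  increased for inefficacy, or a local/intramuscular glucocorticoid
  injection was added.

Both are combined with a *debounce*: no relapse at the previous visit, so
one continuous episode is not counted at consecutive visits.

`pmrelapse` implements the complete analysis a cohort study of these
criteria needs — visit-eligibility rules, rule-based adjudication under
both criteria, agreement statistics (percent agreement, Cohen's kappa),
incidence summaries, univariable association screening, and a
multivariable prediction model for TI relapse within the first treatment
year developed under multiple imputation with bootstrap-corrected
discrimination — together with a synthetic cohort generator, because
routine-care PMR datasets of this kind are not publicly available.

## Eligibility: which visits can carry a relapse

A visit is a *potential relapse visit* iff

* it falls strictly more than 30 days after the baseline visit at which
  prednisolone started (an initial-response period during which relapse is
  not defined),
* the prescribed oral prednisolone dose is strictly above 2.5 mg/day
  (relapses at very low dose have few treatment implications and are
  easily confounded by mimicking conditions),
* it is no more than 90 days after oral treatment ended (recurrences after
  glucocorticoid-free remission are a different phenomenon), and
* it is not after the patient's follow-up end date.

Both dose thresholds are strict inequalities and the 90-day bound is
inclusive at exactly 90, following the wording of the rules ("more than
30 days", "more than 2.5 mg", "more than 90 days ... excluded").
"Treatment ended" is operationalised as the first zero-dose visit with no
later positive dose; a later positive dose reopens treatment and moves the
treatment end. A visit can violate several rules at once; the single
reported reason uses the fixed precedence `after_followup_end` >
`post_treatment_window` > `too_early` > `dose_at_or_below_2_5`. The
eligibility decision is a pure function of the patient's visit sequence,
so it is idempotent and stable under removal of ineligible visits except
where removing a zero-dose visit changes the computed treatment end.

## Adjudication and the debounce

Within the eligible visits of a patient, ordered by date, the raw clauses
are

```
rj_raw = rj_not_in_remission | rj_interval_relapse
ti_raw = dose_increased_since_prev | dmard_intensified_for_inefficacy |
         gc_injection_added
```

and the relapse flag at a visit is the raw clause AND no raw clause at the
*previous eligible* visit (the first eligible visit has no previous visit,
so its debounce passes). Two design points were genuinely open and are
settable by the user:

* **Previous visit** means previous *eligible* visit (default), not
  previous calendar visit: ineligible visits are outside the relapse
  universe. Because adjudication is restricted to eligible visits this is
  the only coherent reading, but the calendar alternative can be emulated
  by adjudicating unfiltered sequences.
* **Debounce against raw or debounced state** (`debounce = "raw"` or
  `"flag"`): comparing against the raw clause (default) means a long
  uninterrupted episode is counted once and cannot re-trigger at alternate
  visits; comparing against the debounced flag would count a sustained
  episode at visits 1, 3, 5, ... Both variants are implemented and tested;
  they differ only on episodes lasting three or more consecutive eligible
  visits.

Between-visit reports (RJ clause b) and between-visit dose increases (TI
clause a) are attributed to the later visit, where a retrospective chart
records them. A consequence of debouncing worth knowing: per patient, the
number of adjudicated events can never exceed half the eligible visits,
rounded up.

## Agreement statistics

Visit-level agreement cross-classifies the debounced RJ and TI flags over
all eligible visits. For two binary raters, expected chance agreement
depends only on the marginals,

$$p_e = \frac{a_+ b_+ + a_- b_-}{N^2}, \qquad
  \kappa = \frac{p_o - p_e}{1 - p_e},$$

and `kappa_from_marginals()` exposes exactly this identity so that
published agreement figures can be desk-checked from their printed
marginal counts; it also reports the double-negative cell's contribution
to $p_e$, which is what makes $\kappa$ much lower than percent agreement
when most visits are relapse-free. Patient-level agreement classifies each
patient as positive under a criterion iff at least one adjudicated event
falls within the horizon (1 or 2 years; a year is 365.25 days throughout).

The package does not pick intervals ad hoc: percent agreement gets a
Wilson score interval and $\kappa$ the Fleiss–Cohen–Everitt large-sample
standard error with a normal-approximation interval. Neither method is
dictated by the underlying study designs in this field; both reproduce
typical published intervals to about two decimals, which the test suite
checks as a soft property on printed marginals.

## Incidence

The incidence rate is total adjudicated events over total person-years.
Person-time per patient runs from baseline to the end of the
potential-relapse-visit window — follow-up end capped at treatment end +
90 days — because that is the window in which an event could have been
observed. This rule is switchable (`person_years(rule =)`): `on_treatment`
censors at treatment end (the window in which the synthetic hazard is
active) and `last_visit` at the last recorded visit, since published
totals rarely state which rule produced them.

Cumulative incidence at a horizon uses *all* patients in the denominator,
whether or not each has complete follow-up to the horizon; with early
censoring this underestimates the true cumulative risk, and an
at-risk-denominator variant is provided. The default matches how such
proportions are usually reported in retrospective cohorts.

## The synthetic cohort generator

`generate_cohort()` emulates a routine-care PMR cohort of 417 patients so
that every downstream stage is testable against known truth. Baseline
covariates follow the marginals of a typical newly diagnosed cohort: age
66.4 (SD 8.8) years; 55.9% female; cardiovascular history 14.1%;
malignancy history 12.2%; smoking never/stopped/current 47/21/13%;
symptom duration gamma with mean 14 and SD 13.7 weeks; CRP log-normal with
median 29 and IQR 15–52.5 mg/L and ESR log-normal with median 37 and IQR
26–51 mm/h (both moment-matched on the log scale from median and IQR);
haemoglobin normal, 8.2 (IQR 7.6–8.6) mmol/L; a 0–8 severity sum score
obtained by convolving the four girdle pain/restriction component
distributions; 79% meeting the EULAR/ACR core classification criteria.
Missingness is injected per covariate (smoking 19%, symptom duration 1%,
CRP 13%, ESR 5%, Hb 24%), MCAR by default, with an age-dependent MAR
option for imputation stress tests.

Several longitudinal design choices were open and are worth stating
explicitly, since the reference cohort description does not fix them:

* **Visit schedule.** Visits every 75 days (± 7 days uniform jitter). This
  matches a cohort that accumulates roughly ten visits per patient over
  about 2.2 patient-years of follow-up — i.e. one review per ~2.5 months
  during a taper — and yields a per-eligible-visit relapse prevalence near
  13%, the value implied by published visit counts.
* **Taper.** Ten steps, 15 → 12.5 → 10 → 8.75 → 7.5 → 6.25 → 5 → 3.75 →
  2.5 → 0 mg/day, one step per relapse-free visit. Follow-up ends at 1095
  days or 90 days after the dose reaches zero, whichever is earlier.
* **Event process.** A per-patient piecewise-constant hazard, per
  patient-year,
  $\lambda_i(t) = \exp\{\beta_0 + \sum_j \beta_j (x_{ij} - \bar x_j) + u_i\}
  \cdot d^{\,[t > 365]}$, active while the oral dose is positive. The
  covariate effects default to modest published univariable rate ratios
  (e.g. +9% per 10 mm/h ESR) applied to centred covariates; $u_i$ is a
  mean-one log-normal frailty (SD 1.1 on the log scale) capturing the
  strong clustering of repeat relapses in a subset of patients; the decay
  factor $d = 0.40$ after the first year reflects that most PMR relapses
  occur early. The intercept $\exp(\beta_0) = 0.70$ was fixed once, at
  design time, so that the *adjudicated* statistics of the default cohort
  sit near the reference set (TI incidence rate ≈ 0.32/patient-year,
  cumulative incidence ≈ 34%/44% at 1/2 years) after the attenuation
  discussed below. A constant hazard cannot reproduce this pattern: it
  either overshoots the second-year cumulative incidence or undershoots
  the rate.
* **Recording a relapse.** Each true event is recorded at the next visit
  as a treatment intensification: 80% a dose step-up to the previous taper
  step (after which the taper resumes), 10% a DMARD start/increase and 10%
  a glucocorticoid injection (during which the oral taper continues — the
  point of glucocorticoid-sparing action). The mixture exercises all three
  TI clauses.
* **RJ noise.** RJ is the treatment signal observed with noise. At a visit
  with a TI action an RJ clause is recorded with probability 0.70. RJ
  clauses *without* treatment intensification are patient-correlated:
  19% of patients are "over-callers" who record an RJ clause at 47% of
  their non-TI eligible visits, giving a marginal visit-level rate of
  0.09. The decomposition matters: visit-*independent* noise at the rate
  needed for visit-level disagreement would make ~60% of non-relapsing
  patients RJ-positive over ten visits, which is far more patient-level
  disagreement than cohorts report (~18%). Both rates follow in closed
  form from published visit-level marginals (implied
  $P(\mathrm{RJ}\mid\mathrm{TI}) = 202.6/321 \approx 0.63$,
  $P(\mathrm{RJ}\mid\neg\mathrm{TI}) = 196.4/2101 \approx 0.09$); the
  conditional probability at TI visits is set slightly above the implied
  value to balance visit- and patient-level agreement.

What the generator deliberately does **not** emulate: giant cell
arteritis co-occurrence, glucocorticoid adverse events, comorbidity
flares, informative loss to follow-up, measurement drift in laboratory
assays, or the exact distribution of visit counts. Passing tests on this
synthetic cohort therefore demonstrate that the *pipeline* is correct and
calibrated under a known data-generating process, not that any particular
clinical conclusion transfers to real charts.

### Attenuation of the observed incidence rate

The adjudicated event count is an attenuated observation of the
underlying process, for three structural reasons: two events in one
inter-visit gap collapse into one relapse visit; an event whose recording
visit is ineligible (the 2.5 mg/day step, the post-treatment window) is
never counted; and the debounce suppresses an event recorded at the visit
immediately after another. Under a constant hazard $\lambda$ and a dose
path independent of the events, the exact expectation of the adjudicated
count given the realised schedule is

$$E = \sum_{k \in \text{eligible}} p_k (1 - p_{j(k)}), \qquad
  p_k = 1 - e^{-\lambda \Delta^{\text{on}}_k},$$

with $\Delta^{\text{on}}_k$ the on-treatment length of the interval ending
at visit $k$ and $j(k)$ the previous eligible visit. The test suite uses
this closed form as an independent oracle: across 100 replicate cohorts of
2000 patients at $\lambda = 0.35$, the observed count falls within the
95% Poisson band of $E$ in at least 93 replicates and is unbiased for $E$
pooled across replicates to better than 1%. At the default design the
total attenuation is roughly 30% — which is why an estimator that divides
observed events by person-time should be read as a rate of *identified*
relapses, not of underlying disease activity; the same caveat applies to
any chart-review study using these criteria.

## Univariable screening

Twelve baseline candidate predictors are screened against three outcomes:
TI relapse within 1 year and within 2 years (logistic regression, odds
ratios) and the per-patient event count with a log person-years offset
(Poisson regression, incidence rate ratios). CRP and ESR enter divided by
10 so coefficients are per 10 mg/L and 10 mm/h; symptom duration enters in
months by default (weeks/4.345) with a per-week option, since published
tables are inconsistent about this unit and the package does not resolve
that inconsistency for the user. Screening is complete-case per predictor
(published per-predictor n footnotes imply the same), fits are
maximum-likelihood with Wald intervals and p-values, significance is
flagged at p < 0.05, and (quasi-)separation raises an explicit error
rather than returning an absurd estimate. The full table reports 13
contrasts (smoking contributes two) × 3 outcomes, with per-cell failure
markers instead of aborting.

Calibration is tested rather than assumed: under the null the type-I error
is 5% ± 2% over 500 replicates, and Wald intervals cover a known OR of 2
and IRR of 1.5 in at least 93 of 100 replicates at n = 5000.

## The prediction model

`relapse_model()` develops and internally validates a multivariable
logistic model for TI relapse within the first treatment year:

1. **Multiple imputation.** Chained equations over the incomplete
   covariates (smoking, symptom duration, CRP, ESR, Hb), m = 20 by
   default, five sweeps. Continuous covariates use predictive mean
   matching on a Bayesian linear-regression draw (posterior draw of
   residual variance and coefficients, five nearest donors by predicted
   value), so imputed values are always observed values and skewed
   distributions keep their support; the three-level smoking variable uses
   a multinomial model fitted to a bootstrap resample of the observed rows
   (the resample standing in for the parameter draw). All twelve
   candidate predictors *and the outcome* enter every imputation model.
   With complete data, all m sets are identical and every later stage
   collapses to the single-dataset analysis — an identity the tests
   assert.
2. **Selection.** Within each imputed dataset, backward elimination from
   the full candidate set removes the variable with the largest Wald
   chi-square p-value (multi-degree-of-freedom for smoking, so the factor
   moves as one unit) until all remaining satisfy p < 0.157, the
   AIC-equivalent retention threshold. The final model keeps the variables
   retained in strictly more than 50% of the sets; a variable retained in
   40% of sets is therefore dropped. Inclusion fractions are always
   reported — model "stability" should be checkable, not asserted.
3. **Pooling.** The selected model is refitted on every set and pooled by
   Rubin's rules: mean coefficients; total variance = within + (1 + 1/m) ×
   between; normal-approximation intervals.
4. **Validation.** Harrell's bootstrap with patient-level resampling: the
   *entire* development procedure (elimination, inclusion-fraction
   selection, refit, pooling) is repeated in each bootstrap sample, and
   optimism = mean(bootstrap AUC − original-data AUC of the bootstrap
   model) is subtracted from the apparent AUC. Resampling reuses the
   existing imputed datasets (the same patient indices across all m sets)
   rather than re-imputing inside the bootstrap, which follows the
   standard recipe and keeps the computation proportionate; re-imputation
   noise is second-order here because imputation uncertainty is already
   propagated through the m sets. Bootstrap samples with a constant
   outcome are redrawn (capped retries). The default is 200 resamples
   (minimum 100); the AUC is the average of per-set c-statistics of the
   pooled linear predictor and is reported with its across-set range.

The c-statistic itself is the rank-based (Wilcoxon) estimator, checked in
the tests against an independent ROC implementation to 12 decimals. The
pipeline's honesty is tested where it can be known: on outcome-independent
covariates (n = 1000, 200 resamples) the corrected AUC lies in
[0.47, 0.53], and for a single standardized predictor with a group mean
difference of 0.5 the apparent AUC approaches the binormal closed form
$\Phi(0.5/\sqrt2) \approx 0.638$ at n = 40000.

An events-per-variable check (the "10 events per variable" heuristic)
warns — deliberately does not fail — when the candidate count exceeds
events/10. `sensitivity_subset()` restricts the cohort to patients
fulfilling the EULAR/ACR core classification criteria so the identical
pipeline can be rerun as a sensitivity analysis.

## Numerical and degenerate-input choices

* Dates are calendar dates; all analysis is on days since baseline
  (day 0); a year is 365.25 days.
* Delimited text I/O enforces its dialect: ISO-8601 dates, period decimal
  separator (a comma decimal is a parse error naming the line), 0/1
  booleans, empty field = missing. Duplicate `(patient_id, visit_date)`
  rows and visits without a matching patient are integrity errors.
* Degenerate inputs raise classed conditions (`pmr_degenerate_error`,
  `pmr_empty_error`, `pmr_separation_error`, ...) rather than silently
  returning extreme estimates: kappa with $p_e = 1$, incidence with zero
  person-time, logistic fits with a constant outcome or separation,
  imputation with a fully missing covariate, prediction with a missing
  selected covariate.
* The PMM ridge (1e-8 on the cross-product diagonal) guards against
  collinear imputation designs; elimination treats an inestimable
  (aliased) coefficient as removable (p = 1).
* All randomness — generation, imputation, bootstrap — is governed by
  explicit integer seeds; a fixed configuration and seed reproduce the
  tables bit-identically.

## Problem sizes used in the shipped checks

The test suite exercises the marginal-recovery checks at n = 2000, the
incidence-recovery oracle at 100 replicates × 2000 patients, regression
calibration at 500 null replicates (n = 400) and 100 coverage replicates
(n = 5000), and the null-discrimination check at n = 1000 with 200
bootstrap resamples; the acceptance script runs the full pipeline on the
default 417-patient cohort with m = 10 and 150 resamples. These sizes were
chosen so each Monte-Carlo band is decisively narrower than the property
it checks while the whole suite stays comfortably reproducible on a single
CPU.

## Known limitations

* The generator's hazard, frailty and RJ-noise structure is a model *of*
  the reference cohort's summary statistics, not of any patient-level
  data; only closed-form identities (kappa from marginals, incidence
  ratios) reproduce published values exactly, and simulated statistics sit
  near, not on, them.
* The selection and validation recipe (backward elimination at p < 0.157,
  >50% inclusion, Harrell bootstrap) is a standard reconstruction; the
  original modelling appendix it would correspond to is not public, so
  coefficient-level comparisons are out of reach by design.
* MAR support is limited to the age-dependent mechanism; MNAR is not
  modelled.
* No time-to-event analysis (Kaplan–Meier, Cox, recurrent-event models):
  the package mirrors a fixed-horizon / rate-based analysis.
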