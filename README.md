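# pmrelapse

Relapse adjudication, inter-criteria agreement and prediction modelling
for polymyalgia rheumatica (PMR) cohorts.

PMR is treated with oral prednisolone tapered stepwise after remission,
and a third to a half of patients relapse during the taper. Routine-care
studies identify those relapses with rule-based criteria applied to visit
records, most commonly **rheumatologist judgement** (RJ: the clinician
judges non-remission at a visit, or clinician/patient report a relapse
between visits) and **treatment intensification** (TI: a prednisolone
dose increase or advice to increase, a DMARD started/increased for
inefficacy, or an added local/intramuscular glucocorticoid injection),
each combined with "no relapse at the previous visit" so a continuous
episode counts once. `pmrelapse` is for epidemiologists and
rheumatology researchers who need this whole analysis as tested,
reusable code:

* **eligibility** — potential-relapse visits only: > 30 days after
  treatment start, > 2.5 mg/day oral prednisolone, at most 90 days after
  oral treatment ended (`filter_eligible_visits()`);
* **adjudication** — both criteria with the debounce, in two documented
  variants (`adjudicate()`, `relapse_events()`);
* **agreement** — percent agreement with Wilson intervals and Cohen's
  κ = (p₀ − pₑ)/(1 − pₑ) with an asymptotic standard error, at visit and
  patient level, plus `kappa_from_marginals()` for desk-checking published
  values from marginal counts alone;
* **incidence** — events per patient-year and cumulative incidence at
  fixed horizons, with switchable person-time rules
  (`incidence_summary()`);
* **screening** — univariable logistic (OR) and Poisson-with-offset (IRR)
  associations for the twelve baseline candidate predictors
  (`association_table()`);
* **prediction** — `relapse_model()`: chained-equations multiple
  imputation (predictive mean matching), backward elimination within each
  imputed dataset at p < 0.157, across-imputation selection (> 50%
  inclusion), Rubin pooling, and Harrell bootstrap optimism-corrected
  AUC, with `predict()`/`summary()`/`coef()` methods and an EULAR/ACR
  core-criteria sensitivity subset (`sensitivity_subset()`);
* **synthetic cohorts** — `generate_cohort()` simulates baseline
  covariates, taper trajectories, covariate-dependent relapse hazards and
  both relapse signals with known ground truth, so every stage is
  testable without patient data (none are publicly available for this
  design). Tables round-trip through plain CSV (`read_cohort()`,
  `write_cohort()`).

The methods vignette (`vignettes/pmrelapse-methods.Rmd`) documents the
model assumptions, every tunable parameter and the design decisions.

## Worked example

```r
library(pmrelapse)

coh <- generate_cohort(cohort_config(n_patients = 417, seed = 2026))
coh
#> Synthetic PMR cohort
#>   417 patients, 5037 visits, 510 true relapse events
#>   follow-up: 968 patient-years (2.32 per patient)
#>   true event rate: 0.527 / patient-year

adj <- adjudicate(coh)
visit_level_agreement(adj)
#> Agreement between RJ and TI (n = 3437)
#>      TI
#> RJ    pos  neg
#>   pos 204  154
#>   neg 112 2967
#>   observed agreement: 92% (95% CI 0.91-0.93)
#>   chance agreement:   0.823 (double-negative cell 81%)
#>   Cohen's kappa:      0.563 (95% CI 0.52-0.61)

ev_ti <- relapse_events(adj, "TI")
incidence_summary(ev_ti, coh$patients, c(1, 2), "TI", coh$visits)
#> Relapse incidence (TI criterion, 417 patients)
#>   cumulative incidence 1y : 145 / 417 (35%)
#>   cumulative incidence 2y : 190 / 417 (46%)
#>   events: 316 over 968 patient-years -> IR 0.33 / patient-year

fit <- relapse_model(coh$patients, ev_ti, m = 5, n_bootstrap = 100, seed = 3)
fit
#> Relapse prediction model (TI relapse within 1 year)
#>   n = 417 patients, 145 events; 5 imputed datasets
#>   selected: smoking, severity_score, crp10, esr10
#>   apparent AUC: 0.612 (per-set range 0.596-0.639)
#>   optimism: 0.051 (100 bootstrap resamples) -> corrected AUC: 0.561
```

Reading the output: of 5037 simulated encounters, 3437 are potential
relapse visits; the two criteria agree at 92% of them, but because 81% of
that agreement is the chance-expected double-negative cell, the
chance-corrected κ is only 0.56 — the same dissociation between percent
agreement and κ that motivates studying these criteria at all. About a
third of patients have a treatment-intensification relapse within the
first year. The prediction model's apparent discrimination (AUC 0.61)
shrinks to 0.56 after bootstrap optimism correction: baseline covariates
carry only modest prognostic signal under this data-generating process,
mirroring the modest performance reported for such models on real
cohorts.

Published agreement figures can be desk-checked directly from printed
marginal counts, e.g. 2422 visits with 399 RJ-positive, 321 TI-positive
and 87% observed agreement:

```r
kappa_from_marginals(2422, 399, 321, 0.87)
#> $pe
#> [1] 0.7463927
#> $pe_negative_cell
#> [1] 0.7245588
#> $kappa
#> [1] 0.4873966
```

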