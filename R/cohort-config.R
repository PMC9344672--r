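#' Default severity-score distribution
#'
#' The 0-8 clinical severity sum score counts pain/stiffness and movement
#' restriction at the shoulder and hip girdles, each scored 0 (absent),
#' 1 (unilateral) or 2 (bilateral). The default distribution is the
#' convolution of four independent three-level components with marginals
#' typical of a newly diagnosed PMR cohort (bilateral shoulder pain in the
#' large majority, hip movement restriction in a minority).
#'
#' @return numeric vector of length 9, probabilities for scores 0..8.
#' @export
default_severity_probs <- function() {
  comps <- list(
    shoulder_pain        = c(0.026, 0.038, 0.935),
    hip_pain             = c(0.094, 0.024, 0.882),
    shoulder_restriction = c(0.532, 0.062, 0.405),
    hip_restriction      = c(0.779, 0.062, 0.158)
  )
  out <- 1
  for (p in comps) {
    p <- p / sum(p)
    new <- numeric(length(out) + 2L)
    for (i in seq_along(p)) {
      idx <- seq_along(out) + (i - 1L)
      new[idx] <- new[idx] + out * p[i]
    }
    out <- new
  }
  names(out) <- as.character(0:8)
  out
}

#' Default covariate effects of the relapse hazard
#'
#' Log rate ratios applied multiplicatively to the baseline relapse hazard
#' of the synthetic generator. The defaults emulate the direction and
#' magnitude of univariable rate ratios reported for PMR relapse: weak
#' positive effects of the acute phase reactants (per 10 units), a positive
#' effect of cardiovascular history, and a small negative effect of
#' pre-treatment symptom duration. Set to `NULL` in [cohort_config()] for a
#' covariate-independent (constant) hazard.
#'
#' Recognised names: `age` (per year), `female`, `cvd_history`,
#' `malignancy_history`, `smoking_stopped`, `smoking_current`,
#' `symptom_duration` (per week), `severity_score` (per point),
#' `arthritis`, `systemic_symptoms`, `crp10` (per 10 mg/L), `esr10`
#' (per 10 mm/h), `hb` (per mmol/L). Covariates are centred at their
#' configured population means, so the hazard intercept remains the rate
#' for an average patient.
#'
#' @return named numeric vector of log rate ratios.
#' @export
default_hazard_betas <- function() {
  c(
    age                = 0,
    female             = 0,
    cvd_history        = log(1.20),
    malignancy_history = log(0.91),
    smoking_stopped    = log(1.29),
    smoking_current    = log(0.97),
    symptom_duration   = log(0.96) / WEEKS_PER_MONTH,
    severity_score     = log(0.94),
    arthritis          = log(0.79),
    systemic_symptoms  = 0,
    crp10              = log(1.04),
    esr10              = log(1.09),
    hb                 = log(1.03)
  )
}

HAZARD_BETA_NAMES <- c(
  "age", "female", "cvd_history", "malignancy_history", "smoking_stopped",
  "smoking_current", "symptom_duration", "severity_score", "arthritis",
  "systemic_symptoms", "crp10", "esr10", "hb"
)

MISSING_RATE_FIELDS <- c("smoking", "symptom_duration", "crp", "esr", "hb")

#' Configuration of the synthetic PMR cohort generator
#'
#' Builds and validates the parameter set that [generate_cohort()] consumes.
#' Defaults describe a cohort of 417 patients starting oral prednisolone
#' 15 mg/day with a stepwise taper reviewed roughly every two and a half
#' months:
#' age 66.4 (SD 8.8) years, 55.9% female, CRP median 29 mg/L
#' (IQR 15-52.5, log-normal by moment matching), ESR median 37 mm/h
#' (IQR 26-51), haemoglobin 8.2 mmol/L (IQR 7.6-8.6, normal), and
#' missingness rates of 19% (smoking), 1% (symptom duration), 13% (CRP),
#' 5% (ESR) and 24% (Hb).
#'
#' Relapse events arise from a piecewise-constant per-patient hazard
#' `exp(intercept + sum(beta * (x - centre)))` per patient-year (scaled by
#' `relapse_hazard_decay` after `relapse_hazard_decay_day`), active while
#' the patient is on a positive prednisolone dose. Each event is
#' recorded at the next visit as a treatment intensification: a dose
#' step-up to the previous taper step, a DMARD start/increase, or a local
#' or intramuscular glucocorticoid injection, with probabilities
#' `ti_action_probs`. The rheumatologist-judgement fields are the
#' treatment signal observed with noise: at a visit with (without) a
#' treatment intensification, a rheumatologist-judgement relapse is
#' recorded with probability `p_rj_given_ti` (`p_rj_given_no_ti`).
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed; a fixed seed makes the generated tables
#'   bit-identical across runs.
#' @param age_mean,age_sd age distribution in years.
#' @param prop_female,prop_cvd_history,prop_malignancy_history,prop_arthritis,prop_systemic,prop_meets_eular_acr
#'   baseline prevalence of the binary covariates.
#' @param smoking_probs probabilities of never/stopped/current smoking;
#'   non-negative, summing to at most 1 (any remainder is the share that
#'   will typically be missing; true values are drawn from the renormalised
#'   vector and missingness is injected separately via `missing_rates`).
#' @param symptom_duration_mean,symptom_duration_sd pre-treatment symptom
#'   duration in weeks (gamma-distributed; the SD close to the mean gives
#'   the right skew).
#' @param crp_log_mean,crp_log_sd,esr_log_mean,esr_log_sd log-scale
#'   parameters of the log-normal CRP (mg/L) and ESR (mm/h) distributions.
#' @param hb_mean,hb_sd haemoglobin in mmol/L (normal).
#' @param severity_score_probs distribution over the 0-8 severity score;
#'   default [default_severity_probs()].
#' @param missing_rates named vector of per-covariate missingness
#'   probabilities; allowed names: smoking, symptom_duration, crp, esr, hb.
#' @param missing_mechanism `"MCAR"` (default) or `"MAR_age"`, under which
#'   the missingness log-odds increase by 0.08 per year of age above the
#'   configured mean (for imputation stress tests).
#' @param visit_interval_mean mean days between visits.
#' @param visit_jitter half-width (days) of the uniform jitter around the
#'   visit schedule.
#' @param start_dose starting oral prednisolone dose, mg/day (> 2.5; must
#'   equal the first taper step).
#' @param taper_schedule strictly decreasing dose steps in mg/day, ending
#'   at 0; one step is taken per relapse-free visit.
#' @param followup_max administrative end of follow-up, days after
#'   baseline.
#' @param relapse_log_hazard_intercept log relapse rate per patient-year
#'   for a patient at the covariate centres; `-Inf` switches relapses off.
#' @param relapse_log_hazard_betas named log rate ratios (see
#'   [default_hazard_betas()]), or `NULL` for a constant hazard.
#' @param relapse_hazard_decay multiplicative factor applied to the hazard
#'   from `relapse_hazard_decay_day` onwards (piecewise-constant time
#'   profile; 1 = constant hazard). The default < 1 reflects that most PMR
#'   relapses occur during the first treatment year.
#' @param relapse_hazard_decay_day day after baseline at which the decay
#'   factor kicks in.
#' @param relapse_frailty_sd standard deviation (log scale) of a
#'   mean-one log-normal patient frailty multiplying the hazard;
#'   captures unmeasured between-patient heterogeneity, which makes
#'   relapses cluster in a subset of patients (repeat relapses). 0
#'   disables the frailty.
#' @param ti_action_probs probabilities of the three treatment
#'   intensification actions (step_up, dmard, injection) recorded for a
#'   true relapse; must sum to 1.
#' @param p_rj_given_ti probability that a visit with a treatment
#'   intensification also carries a rheumatologist-judgement relapse
#'   clause.
#' @param p_rj_given_no_ti marginal probability of a
#'   rheumatologist-judgement clause at a visit without treatment
#'   intensification. This noise is patient-correlated: only a fraction
#'   `rj_overcall_prop` of patients ("over-callers": clinicians/patients
#'   who report activity without intensifying treatment) produce such
#'   clauses, at per-visit rate `p_rj_given_no_ti / rj_overcall_prop`, so
#'   criteria disagree more at the visit level than at the patient level.
#' @param rj_overcall_prop fraction of patients susceptible to
#'   rheumatologist-judgement relapse without treatment intensification;
#'   must be at least `p_rj_given_no_ti`; 1 gives visit-independent noise.
#'
#' @return an object of class `"pmr_cohort_config"` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 417L,
                          seed = 1L,
                          age_mean = 66.4, age_sd = 8.8,
                          prop_female = 0.559,
                          prop_cvd_history = 0.141,
                          prop_malignancy_history = 0.122,
                          smoking_probs = c(never = 0.472, stopped = 0.209, current = 0.125),
                          symptom_duration_mean = 14, symptom_duration_sd = 13.7,
                          crp_log_mean = log(29),
                          crp_log_sd = (log(52.5) - log(15)) / (2 * stats::qnorm(0.75)),
                          esr_log_mean = log(37),
                          esr_log_sd = (log(51) - log(26)) / (2 * stats::qnorm(0.75)),
                          hb_mean = 8.2,
                          hb_sd = (8.6 - 7.6) / (2 * stats::qnorm(0.75)),
                          severity_score_probs = default_severity_probs(),
                          prop_arthritis = 0.153,
                          prop_systemic = 0.436,
                          prop_meets_eular_acr = 0.79,
                          missing_rates = c(smoking = 0.19, symptom_duration = 0.01,
                                            crp = 0.13, esr = 0.05, hb = 0.24),
                          missing_mechanism = c("MCAR", "MAR_age"),
                          visit_interval_mean = 75,
                          visit_jitter = 7,
                          start_dose = 15,
                          taper_schedule = c(15, 12.5, 10, 8.75, 7.5, 6.25, 5, 3.75, 2.5, 0),
                          followup_max = 1095,
                          relapse_log_hazard_intercept = log(0.70),
                          relapse_log_hazard_betas = default_hazard_betas(),
                          relapse_hazard_decay = 0.40,
                          relapse_hazard_decay_day = 365,
                          relapse_frailty_sd = 1.1,
                          ti_action_probs = c(step_up = 0.8, dmard = 0.1, injection = 0.1),
                          p_rj_given_ti = 0.70,
                          p_rj_given_no_ti = 0.09,
                          rj_overcall_prop = 0.19) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, prop_female = prop_female,
    prop_cvd_history = prop_cvd_history,
    prop_malignancy_history = prop_malignancy_history,
    smoking_probs = smoking_probs,
    symptom_duration_mean = symptom_duration_mean,
    symptom_duration_sd = symptom_duration_sd,
    crp_log_mean = crp_log_mean, crp_log_sd = crp_log_sd,
    esr_log_mean = esr_log_mean, esr_log_sd = esr_log_sd,
    hb_mean = hb_mean, hb_sd = hb_sd,
    severity_score_probs = severity_score_probs,
    prop_arthritis = prop_arthritis, prop_systemic = prop_systemic,
    prop_meets_eular_acr = prop_meets_eular_acr,
    missing_rates = missing_rates, missing_mechanism = missing_mechanism,
    visit_interval_mean = visit_interval_mean, visit_jitter = visit_jitter,
    start_dose = start_dose, taper_schedule = taper_schedule,
    followup_max = followup_max,
    relapse_log_hazard_intercept = relapse_log_hazard_intercept,
    relapse_log_hazard_betas = relapse_log_hazard_betas,
    relapse_hazard_decay = relapse_hazard_decay,
    relapse_hazard_decay_day = relapse_hazard_decay_day,
    relapse_frailty_sd = relapse_frailty_sd,
    ti_action_probs = ti_action_probs,
    p_rj_given_ti = p_rj_given_ti, p_rj_given_no_ti = p_rj_given_no_ti,
    rj_overcall_prop = rj_overcall_prop
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "pmr_cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    pmr_stop("pmr_config_error", sprintf("invalid cohort configuration: field '%s' %s", field, why))
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      is.na(cfg$n_patients) || cfg$n_patients < 1) {
    bad("n_patients", "must be a single integer >= 1")
  }
  for (f in c("prop_female", "prop_cvd_history", "prop_malignancy_history",
              "prop_arthritis", "prop_systemic", "prop_meets_eular_acr",
              "p_rj_given_ti", "p_rj_given_no_ti")) {
    if (!is_probability(cfg[[f]])) bad(f, "must be a probability in [0, 1]")
  }
  for (f in c("age_sd", "symptom_duration_sd", "crp_log_sd", "esr_log_sd", "hb_sd",
              "visit_interval_mean", "followup_max")) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] <= 0) bad(f, "must be a positive number")
  }
  if (!is_scalar_number(cfg$visit_jitter) || cfg$visit_jitter < 0 ||
      cfg$visit_jitter >= cfg$visit_interval_mean) {
    bad("visit_jitter", "must be non-negative and smaller than visit_interval_mean")
  }
  sp <- cfg$smoking_probs
  if (!is.numeric(sp) || length(sp) != 3L || any(sp < 0) || sum(sp) > 1 + 1e-8 || sum(sp) <= 0) {
    bad("smoking_probs", "must be 3 non-negative probabilities summing to at most 1")
  }
  sev <- cfg$severity_score_probs
  if (!is.numeric(sev) || length(sev) != 9L || any(sev < 0) ||
      abs(sum(sev) - 1) > 1e-6) {
    bad("severity_score_probs", "must be 9 non-negative probabilities (scores 0-8) summing to 1")
  }
  mr <- cfg$missing_rates
  if (length(mr)) {
    if (is.null(names(mr)) || !all(names(mr) %in% MISSING_RATE_FIELDS)) {
      bad("missing_rates", sprintf("names must be among {%s}", paste(MISSING_RATE_FIELDS, collapse = ", ")))
    }
    if (!is.numeric(mr) || any(is.na(mr)) || any(mr < 0 | mr > 1)) {
      bad("missing_rates", "rates must lie in [0, 1]")
    }
  }
  ts <- cfg$taper_schedule
  if (!is.numeric(ts) || length(ts) < 2L || any(diff(ts) >= 0) || any(ts < 0)) {
    bad("taper_schedule", "must be strictly decreasing non-negative doses")
  }
  if (!is_scalar_number(cfg$start_dose) || cfg$start_dose <= 2.5) {
    bad("start_dose", "must exceed 2.5 mg/day")
  }
  if (abs(cfg$start_dose - ts[1]) > 1e-9) {
    bad("start_dose", "must equal the first taper step")
  }
  if (!is.numeric(cfg$relapse_log_hazard_intercept) ||
      length(cfg$relapse_log_hazard_intercept) != 1L ||
      is.na(cfg$relapse_log_hazard_intercept)) {
    bad("relapse_log_hazard_intercept", "must be a single number (possibly -Inf)")
  }
  bet <- cfg$relapse_log_hazard_betas
  if (!is.null(bet)) {
    if (!is.numeric(bet) || is.null(names(bet)) || !all(names(bet) %in% HAZARD_BETA_NAMES)) {
      bad("relapse_log_hazard_betas",
          sprintf("must be a named numeric vector with names among {%s}",
                  paste(HAZARD_BETA_NAMES, collapse = ", ")))
    }
  }
  ap <- cfg$ti_action_probs
  if (!is.numeric(ap) || length(ap) != 3L || any(ap < 0) || abs(sum(ap) - 1) > 1e-8) {
    bad("ti_action_probs", "must be 3 non-negative probabilities summing to 1")
  }
  if (!is_scalar_number(cfg$relapse_hazard_decay) || cfg$relapse_hazard_decay < 0) {
    bad("relapse_hazard_decay", "must be a non-negative number")
  }
  if (!is_scalar_number(cfg$relapse_hazard_decay_day) || cfg$relapse_hazard_decay_day <= 0) {
    bad("relapse_hazard_decay_day", "must be a positive number of days")
  }
  if (!is_scalar_number(cfg$relapse_frailty_sd) || cfg$relapse_frailty_sd < 0) {
    bad("relapse_frailty_sd", "must be a non-negative number")
  }
  if (!is_probability(cfg$rj_overcall_prop)) {
    bad("rj_overcall_prop", "must be a probability in [0, 1]")
  }
  if (cfg$rj_overcall_prop > 0 && cfg$p_rj_given_no_ti > cfg$rj_overcall_prop + 1e-9) {
    bad("rj_overcall_prop", "must be at least p_rj_given_no_ti (per-visit rate would exceed 1)")
  }
  if (cfg$rj_overcall_prop == 0 && cfg$p_rj_given_no_ti > 0) {
    bad("rj_overcall_prop", "cannot be 0 while p_rj_given_no_ti is positive")
  }
  invisible(cfg)
}

#' @export
print.pmr_cohort_config <- function(x, ...) {
  cat("Synthetic PMR cohort configuration\n")
  cat(sprintf("  patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  taper: %s mg/day, visits every ~%g d (+/- %g d)\n",
              paste(x$taper_schedule, collapse = " > "),
              x$visit_interval_mean, x$visit_jitter))
  cat(sprintf("  relapse hazard: exp(%.3f) = %.3f /patient-year at covariate centres, %s\n",
              x$relapse_log_hazard_intercept, exp(x$relapse_log_hazard_intercept),
              if (is.null(x$relapse_log_hazard_betas) || all(x$relapse_log_hazard_betas == 0))
                "constant" else "covariate-dependent"))
  invisible(x)
}
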