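`%||%` <- function(a, b) if (is.null(a)) b else a

# builders for small constructed patients/visits used across the suite

BASE <- as.Date("2010-01-01")

mk_patient <- function(id = "P1", baseline = BASE, fup_days = 1500,
                       age = 66, sex = "female", cvd = FALSE, malig = FALSE,
                       smoking = "never", sympt = 14, severity = 4L,
                       arthritis = FALSE, systemic = FALSE,
                       crp = 29, esr = 37, hb = 8.2, eular = TRUE) {
  data.frame(patient_id = id, baseline_date = baseline,
             age = age, sex = sex, cvd_history = cvd, malignancy_history = malig,
             smoking = smoking, symptom_duration_weeks = sympt,
             severity_score = severity, arthritis = arthritis,
             systemic_symptoms = systemic, crp = crp, esr = esr, hb = hb,
             meets_eular_acr_core = eular,
             followup_end_date = baseline + fup_days,
             stringsAsFactors = FALSE)
}

mk_visits <- function(days, doses, id = "P1", baseline = BASE,
                      rj_rem = FALSE, rj_int = FALSE,
                      up = FALSE, dmard = FALSE, inj = FALSE) {
  n <- length(days)
  rec <- function(x) rep_len(x, n)
  data.frame(patient_id = rep_len(id, n), visit_date = baseline + days,
             pred_dose = rec(doses),
             rj_not_in_remission = rec(rj_rem),
             rj_interval_relapse = rec(rj_int),
             dose_increased_since_prev = rec(up),
             dmard_intensified_for_inefficacy = rec(dmard),
             gc_injection_added = rec(inj),
             stringsAsFactors = FALSE)
}

# events table helper
mk_events <- function(ids, days) {
  data.frame(patient_id = ids, event_day = days, stringsAsFactors = FALSE)
}

# a quiet constant-hazard test configuration (no covariate effects, no
# frailty, no time decay, no RJ noise off treatment)
test_config <- function(n_patients, seed, lambda = 0.35, missing_rates = c(), ...) {
  cohort_config(n_patients = n_patients, seed = seed,
                relapse_log_hazard_intercept = if (lambda > 0) log(lambda) else -Inf,
                relapse_log_hazard_betas = NULL,
                relapse_hazard_decay = 1, relapse_frailty_sd = 0,
                missing_rates = missing_rates,
                ...)
}
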