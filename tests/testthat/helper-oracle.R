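# Independent oracle for the incidence-recovery check: under a constant
# per-patient hazard lambda and a visit/dose path that does not depend on
# the events (no dose step-ups in the action mixture), raw TI clauses at
# distinct visits are independent Bernoullis with p_k = 1 - exp(-lambda *
# on-treatment length of the interval ending at visit k). The exact
# expectation of the debounced, eligibility-filtered event count is
#   sum over eligible visits k of p_k * (1 - p_j),
# j being the previous eligible visit (none -> factor 1).
expected_adjudicated_ti <- function(cohort, lambda) {
  visits <- cohort$visits
  patients <- cohort$patients
  by_pid <- split(seq_len(nrow(visits)), visits$patient_id)
  vday_all <- as.numeric(visits$visit_date)
  base <- stats::setNames(as.numeric(patients$baseline_date), patients$patient_id)
  fup <- stats::setNames(as.numeric(patients$followup_end_date), patients$patient_id)
  total <- 0
  for (pid in names(by_pid)) {
    idx <- by_pid[[pid]]
    if (length(idx) < 2L) next
    day <- vday_all[idx] - base[[pid]]
    dose <- visits$pred_dose[idx]
    on_len <- c(0, diff(day) * (dose[-length(dose)] > 0))
    p_raw <- 1 - exp(-lambda * on_len / 365.25)
    elig <- pmrelapse:::eligibility_reasons(day, dose, fup[[pid]] - base[[pid]]) == "ok"
    k <- which(elig)
    if (!length(k)) next
    prev_p <- c(0, p_raw[k[-length(k)]])
    total <- total + sum(p_raw[k] * (1 - prev_p))
  }
  total
}
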