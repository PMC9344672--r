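# Relapse incidence: cumulative incidence at fixed horizons and the
# incidence rate per patient-year.

#' Person-years of observation
#'
#' By default (`rule = "window"`) a patient contributes time from baseline
#' to the end of the potential-relapse-visit window: the follow-up end
#' date, capped at 90 days after oral prednisolone treatment ended when
#' `visits` are supplied (treatment end = first zero-dose visit with no
#' later positive dose). `rule = "on_treatment"` counts only time from
#' baseline to treatment end (requires `visits`), the window during which
#' the simulated relapse hazard is active; `rule = "last_visit"` censors at
#' the last recorded visit.
#'
#' @param patients patient table.
#' @param visits optional visit table.
#' @param rule person-time rule, see above.
#' @return numeric vector of per-patient years (365.25-day years).
#' @export
person_years <- function(patients, visits = NULL,
                         rule = c("window", "on_treatment", "last_visit")) {
  rule <- match.arg(rule)
  end_day <- as.numeric(patients$followup_end_date - patients$baseline_date)
  if (rule != "window" && is.null(visits)) {
    pmr_stop("pmr_contract_error",
             sprintf("person_years: rule '%s' requires the visit table", rule))
  }
  if (!is.null(visits)) {
    by_pid <- split(seq_len(nrow(visits)), visits$patient_id)
    vday_all <- as.numeric(visits$visit_date)
    dose_all <- visits$pred_dose
    for (i in seq_len(nrow(patients))) {
      idx <- by_pid[[patients$patient_id[i]]]
      if (is.null(idx)) {
        if (rule != "window") end_day[i] <- 0
        next
      }
      day <- vday_all[idx] - as.numeric(patients$baseline_date[i])
      o <- order(day)
      day <- day[o]
      te <- treatment_end_day(day, dose_all[idx][o])
      end_day[i] <- switch(rule,
        window = if (is.na(te)) end_day[i] else min(end_day[i], te + 90),
        on_treatment = if (is.na(te)) end_day[i] else min(end_day[i], te),
        last_visit = min(end_day[i], max(day))
      )
    }
  }
  end_day / DAYS_PER_YEAR
}

#' Relapse incidence summary
#'
#' Cumulative incidence (the proportion of patients with at least one
#' adjudicated relapse within each horizon, denominator all patients in the
#' analysis set) and the incidence rate: total adjudicated events divided
#' by total person-years.
#'
#' Every patient counts in each horizon's denominator whether or not their
#' follow-up spans the full horizon; with substantial early censoring this
#' underestimates the true cumulative risk. Set `at_risk_denominator =
#' TRUE` to restrict each horizon's denominator to patients whose
#' follow-up reaches it.
#'
#' @param events event stream from [relapse_events()].
#' @param patients patient table.
#' @param horizons horizons in years for cumulative incidence.
#' @param criterion label carried into the result (`"TI"`/`"RJ"`).
#' @param visits,person_time_rule passed to [person_years()].
#' @param at_risk_denominator see above.
#' @return object of class `"pmr_incidence"`: `criterion`, `n_patients`,
#'   `cum_inc_counts`, `cum_inc_denoms`, `cum_inc_props`, `total_events`,
#'   `person_years`, `ir` (events per patient-year).
#' @export
incidence_summary <- function(events, patients, horizons = c(1, 2),
                              criterion = "TI", visits = NULL,
                              person_time_rule = "window",
                              at_risk_denominator = FALSE) {
  if (nrow(patients) == 0L) {
    pmr_stop("pmr_empty_error", "incidence_summary: empty cohort")
  }
  if (nrow(events) && !all(events$patient_id %in% patients$patient_id)) {
    pmr_stop("pmr_integrity_error", "incidence_summary: event for unknown patient")
  }
  py <- person_years(patients, visits, rule = person_time_rule)
  total_py <- sum(py)
  if (total_py <= 0) {
    pmr_stop("pmr_degenerate_error", "incidence_summary: zero person-time")
  }
  fup_years <- as.numeric(patients$followup_end_date - patients$baseline_date) / DAYS_PER_YEAR
  counts <- denoms <- props <- stats::setNames(numeric(length(horizons)),
                                               paste0(horizons, "y"))
  for (h in seq_along(horizons)) {
    cut <- horizons[h] * DAYS_PER_YEAR
    pos <- unique(events$patient_id[events$event_day <= cut])
    denom <- if (at_risk_denominator) sum(fup_years >= horizons[h]) else nrow(patients)
    counts[h] <- length(pos)
    denoms[h] <- denom
    props[h] <- if (denom > 0) length(pos) / denom else NA_real_
  }
  structure(list(
    criterion = criterion, n_patients = nrow(patients),
    cum_inc_counts = counts, cum_inc_denoms = denoms, cum_inc_props = props,
    total_events = nrow(events), person_years = total_py,
    ir = nrow(events) / total_py,
    person_time_rule = person_time_rule
  ), class = "pmr_incidence")
}

#' @export
print.pmr_incidence <- function(x, ...) {
  cat(sprintf("Relapse incidence (%s criterion, %d patients)\n",
              x$criterion, x$n_patients))
  for (h in names(x$cum_inc_props)) {
    cat(sprintf("  cumulative incidence %-3s: %d / %d (%.0f%%)\n",
                h, x$cum_inc_counts[[h]], x$cum_inc_denoms[[h]],
                100 * x$cum_inc_props[[h]]))
  }
  cat(sprintf("  events: %d over %.0f patient-years -> IR %.2f / patient-year\n",
              x$total_events, x$person_years, x$ir))
  invisible(x)
}
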