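# Rule-based relapse adjudication.
#
# Two criteria, both applied to the eligible visits of one patient in date
# order, both with a debounce clause ("no relapse at the previous visit")
# so one continuous episode is not counted at consecutive visits:
#
#   RJ (rheumatologist judgement): the rheumatologist judges the patient
#   not in remission at the visit, OR the rheumatologist and/or the patient
#   report a relapse since the previous visit.
#   TI (treatment intensification): prednisolone dose increased between
#   visits (or advice to increase), OR a DMARD was started/increased for
#   inefficacy, OR a local/intramuscular glucocorticoid injection added.

debounce_flags <- function(raw, variant = c("raw", "flag")) {
  variant <- match.arg(variant)
  if (!length(raw)) return(logical(0))
  if (variant == "raw") {
    raw & !c(FALSE, raw[-length(raw)])
  } else {
    out <- logical(length(raw))
    prev <- FALSE
    for (i in seq_along(raw)) {
      out[i] <- raw[i] && !prev
      prev <- out[i]
    }
    out
  }
}

#' Adjudicate rheumatologist-judgement (RJ) relapse for one patient
#'
#' For each eligible visit, the raw RJ clause is
#' `rj_not_in_remission | rj_interval_relapse`; the relapse flag is the raw
#' clause combined with no RJ at the previous eligible visit. The first
#' eligible visit has no previous visit, so its debounce always passes.
#'
#' Two debounce variants are provided. The default, `"raw"`, compares
#' against the raw clause at the previous eligible visit, so a long
#' uninterrupted episode is counted once and cannot re-trigger at alternate
#' visits. `"flag"` compares against the previous debounced flag instead.
#'
#' @param visits eligible visits of one patient, sorted by date.
#' @param debounce `"raw"` (default) or `"flag"`.
#' @return data frame with `patient_id`, `visit_date`, `rj_raw`,
#'   `rj_relapse`.
#' @export
adjudicate_rj <- function(visits, debounce = c("raw", "flag")) {
  debounce <- match.arg(debounce)
  if (nrow(visits) && is.unsorted(visits$visit_date, strictly = TRUE)) {
    pmr_stop("pmr_contract_error", "adjudicate_rj: visits must be strictly sorted by date")
  }
  raw <- visits$rj_not_in_remission | visits$rj_interval_relapse
  data.frame(patient_id = visits$patient_id, visit_date = visits$visit_date,
             rj_raw = raw, rj_relapse = debounce_flags(raw, debounce),
             stringsAsFactors = FALSE)
}

#' Adjudicate treatment-intensification (TI) relapse for one patient
#'
#' For each eligible visit, the raw TI clause is
#' `dose_increased_since_prev | dmard_intensified_for_inefficacy |
#' gc_injection_added`; the relapse flag combines the raw clause with no TI
#' at the previous eligible visit (see [adjudicate_rj()] for the debounce
#' variants). Between-visit actions are attributed to the later visit,
#' where a retrospective chart records them.
#'
#' @inheritParams adjudicate_rj
#' @return data frame with `patient_id`, `visit_date`, `ti_raw`,
#'   `ti_relapse`.
#' @export
adjudicate_ti <- function(visits, debounce = c("raw", "flag")) {
  debounce <- match.arg(debounce)
  if (nrow(visits) && is.unsorted(visits$visit_date, strictly = TRUE)) {
    pmr_stop("pmr_contract_error", "adjudicate_ti: visits must be strictly sorted by date")
  }
  raw <- visits$dose_increased_since_prev | visits$dmard_intensified_for_inefficacy |
    visits$gc_injection_added
  data.frame(patient_id = visits$patient_id, visit_date = visits$visit_date,
             ti_raw = raw, ti_relapse = debounce_flags(raw, debounce),
             stringsAsFactors = FALSE)
}

#' Adjudicate relapse across a whole cohort
#'
#' Applies the eligibility rules ([filter_eligible_visits()]) and both
#' relapse criteria to every patient, returning one row per visit. Flags
#' are `NA` for ineligible visits, which do not take part in adjudication
#' (the "previous visit" of the debounce is the previous *eligible* visit).
#'
#' @param patients,visits cohort tables (see [read_cohort()]), or pass a
#'   `"pmr_cohort"` object as `patients`.
#' @param debounce debounce variant, see [adjudicate_rj()].
#' @return data frame of class `"pmr_adjudicated"`: `patient_id`,
#'   `visit_date`, `day`, `eligible`, `reason`, `rj_raw`, `ti_raw`,
#'   `rj_relapse`, `ti_relapse`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 30, seed = 2))
#' adj <- adjudicate(coh)
#' table(adj$rj_relapse, adj$ti_relapse)
#' @export
adjudicate <- function(patients, visits = NULL, debounce = c("raw", "flag")) {
  debounce <- match.arg(debounce)
  if (inherits(patients, "pmr_cohort")) {
    visits <- patients$visits
    patients <- patients$patients
  }
  # hot path: everything on plain vectors, one data frame at the end
  by_pid <- split(seq_len(nrow(visits)), visits$patient_id)
  vday_all <- as.numeric(visits$visit_date)
  rj_raw_all <- visits$rj_not_in_remission | visits$rj_interval_relapse
  ti_raw_all <- visits$dose_increased_since_prev |
    visits$dmard_intensified_for_inefficacy | visits$gc_injection_added
  ord <- integer(0)
  day_out <- numeric(0); reason_out <- character(0)
  rj_raw <- ti_raw <- rj_rel <- ti_rel <- logical(0)
  for (i in seq_len(nrow(patients))) {
    idx <- by_pid[[patients$patient_id[i]]]
    if (is.null(idx)) next
    base_day <- as.numeric(patients$baseline_date[i])
    day <- vday_all[idx] - base_day
    if (is.unsorted(day, strictly = TRUE)) {
      pmr_stop("pmr_contract_error", "adjudicate: visits must be strictly sorted by date")
    }
    if (any(day < 0)) {
      pmr_stop("pmr_integrity_error", "visit before the patient's baseline date")
    }
    reason <- eligibility_reasons(day, visits$pred_dose[idx],
                                  as.numeric(patients$followup_end_date[i]) - base_day)
    el <- reason == "ok"
    rjr <- rep(NA, length(idx)); tir <- rjr; rjf <- rjr; tif <- rjr
    if (any(el)) {
      rjr[el] <- rj_raw_all[idx][el]
      tir[el] <- ti_raw_all[idx][el]
      rjf[el] <- debounce_flags(rj_raw_all[idx][el], debounce)
      tif[el] <- debounce_flags(ti_raw_all[idx][el], debounce)
    }
    ord <- c(ord, idx)
    day_out <- c(day_out, day); reason_out <- c(reason_out, reason)
    rj_raw <- c(rj_raw, rjr); ti_raw <- c(ti_raw, tir)
    rj_rel <- c(rj_rel, rjf); ti_rel <- c(ti_rel, tif)
  }
  res <- data.frame(
    patient_id = visits$patient_id[ord],
    visit_date = visits$visit_date[ord],
    day = day_out, eligible = reason_out == "ok", reason = reason_out,
    rj_raw = rj_raw, ti_raw = ti_raw,
    rj_relapse = rj_rel, ti_relapse = ti_rel,
    stringsAsFactors = FALSE
  )
  class(res) <- c("pmr_adjudicated", "data.frame")
  res
}

#' Extract the relapse event stream
#'
#' One event per flagged eligible visit, with the event day expressed in
#' days since the patient's baseline (day 0), ordered within patient.
#'
#' @param adjudicated output of [adjudicate()].
#' @param criterion `"TI"` (default, treatment intensification) or `"RJ"`.
#' @return data frame with `patient_id` and `event_day`.
#' @export
relapse_events <- function(adjudicated, criterion = c("TI", "RJ")) {
  criterion <- match.arg(criterion)
  col <- if (criterion == "TI") "ti_relapse" else "rj_relapse"
  hit <- !is.na(adjudicated[[col]]) & adjudicated[[col]]
  out <- adjudicated[hit, c("patient_id", "day")]
  names(out) <- c("patient_id", "event_day")
  out <- out[order(out$patient_id, out$event_day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
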