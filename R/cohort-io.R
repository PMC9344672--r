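# Reading/writing the cohort tables and the visit-eligibility rules.
#
# Schema (delimited text, header row, ISO-8601 dates, empty field = missing,
# booleans as 0/1, period decimal separator):
#   patients.csv: patient_id, baseline_date, age, sex, cvd_history,
#     malignancy_history, smoking, symptom_duration_weeks, severity_score,
#     arthritis, systemic_symptoms, crp, esr, hb, meets_eular_acr_core,
#     followup_end_date
#   visits.csv: patient_id, visit_date, pred_dose, rj_not_in_remission,
#     rj_interval_relapse, dose_increased_since_prev,
#     dmard_intensified_for_inefficacy, gc_injection_added

PATIENT_COLS <- c("patient_id", "baseline_date", "age", "sex", "cvd_history",
                  "malignancy_history", "smoking", "symptom_duration_weeks",
                  "severity_score", "arthritis", "systemic_symptoms",
                  "crp", "esr", "hb", "meets_eular_acr_core", "followup_end_date")
VISIT_COLS <- c("patient_id", "visit_date", "pred_dose", "rj_not_in_remission",
                "rj_interval_relapse", "dose_increased_since_prev",
                "dmard_intensified_for_inefficacy", "gc_injection_added")

parse_numeric_col <- function(x, col, file, allow_missing = TRUE) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & x != "")
  if (length(bad)) {
    pmr_stop("pmr_parse_error",
             sprintf("%s: cannot parse '%s' as number in column '%s', line %d (period decimal separator required)",
                     basename(file), x[bad[1]], col, bad[1] + 1L))
  }
  if (!allow_missing && any(x == "")) {
    pmr_stop("pmr_parse_error",
             sprintf("%s: missing value not allowed in column '%s', line %d",
                     basename(file), col, which(x == "")[1] + 1L))
  }
  out
}

parse_logical_col <- function(x, col, file, allow_missing = FALSE) {
  x <- trimws(x)
  ok <- x %in% c("0", "1") | (allow_missing & x == "")
  if (!all(ok)) {
    pmr_stop("pmr_parse_error",
             sprintf("%s: expected 0/1 in column '%s', line %d",
                     basename(file), col, which(!ok)[1] + 1L))
  }
  out <- x == "1"
  out[x == ""] <- NA
  out
}

parse_date_col <- function(x, col, file, allow_missing = FALSE) {
  x <- trimws(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- x != ""
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonblank)[which(is.na(parsed))[1]]
    pmr_stop("pmr_parse_error",
             sprintf("%s: cannot parse '%s' as ISO-8601 date in column '%s', line %d",
                     basename(file), x[bad], col, bad + 1L))
  }
  out[nonblank] <- parsed
  if (!allow_missing && any(!nonblank)) {
    pmr_stop("pmr_parse_error",
             sprintf("%s: missing date in column '%s', line %d",
                     basename(file), col, which(!nonblank)[1] + 1L))
  }
  out
}

read_raw_table <- function(path, cols) {
  if (!file.exists(path)) {
    pmr_stop("pmr_parse_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    pmr_stop("pmr_parse_error",
             sprintf("%s: missing required column(s): %s",
                     basename(path), paste(missing_cols, collapse = ", ")))
  }
  raw
}

#' Read a cohort from delimited text tables
#'
#' Parses the patient and visit tables (schema in the package README and
#' above), converting empty fields to missing values, validating dialect
#' (ISO dates, period decimals, 0/1 booleans), rejecting duplicate
#' `(patient_id, visit_date)` rows and visits without a matching patient,
#' and sorting each patient's visits by date.
#'
#' @param patients_path,visits_path paths to the two CSV files.
#' @return list with elements `patients` and `visits` (data frames).
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(patients_path, visits_path) {
  praw <- read_raw_table(patients_path, PATIENT_COLS)
  patients <- data.frame(
    patient_id = trimws(praw$patient_id),
    baseline_date = parse_date_col(praw$baseline_date, "baseline_date", patients_path),
    age = parse_numeric_col(praw$age, "age", patients_path, allow_missing = FALSE),
    sex = trimws(praw$sex),
    cvd_history = parse_logical_col(praw$cvd_history, "cvd_history", patients_path),
    malignancy_history = parse_logical_col(praw$malignancy_history, "malignancy_history", patients_path),
    smoking = ifelse(trimws(praw$smoking) == "", NA_character_, trimws(praw$smoking)),
    symptom_duration_weeks = parse_numeric_col(praw$symptom_duration_weeks, "symptom_duration_weeks", patients_path),
    severity_score = as.integer(parse_numeric_col(praw$severity_score, "severity_score", patients_path, allow_missing = FALSE)),
    arthritis = parse_logical_col(praw$arthritis, "arthritis", patients_path),
    systemic_symptoms = parse_logical_col(praw$systemic_symptoms, "systemic_symptoms", patients_path),
    crp = parse_numeric_col(praw$crp, "crp", patients_path),
    esr = parse_numeric_col(praw$esr, "esr", patients_path),
    hb = parse_numeric_col(praw$hb, "hb", patients_path),
    meets_eular_acr_core = parse_logical_col(praw$meets_eular_acr_core, "meets_eular_acr_core", patients_path),
    followup_end_date = parse_date_col(praw$followup_end_date, "followup_end_date", patients_path),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(patients$patient_id)) {
    pmr_stop("pmr_integrity_error",
             sprintf("duplicate patient_id: %s",
                     patients$patient_id[duplicated(patients$patient_id)][1]))
  }
  if (!all(patients$sex %in% c("male", "female"))) {
    pmr_stop("pmr_parse_error", "patients: sex must be 'male' or 'female'")
  }
  if (!all(is.na(patients$smoking) | patients$smoking %in% c("never", "stopped", "current"))) {
    pmr_stop("pmr_parse_error", "patients: smoking must be never/stopped/current or empty")
  }
  if (any(patients$severity_score < 0 | patients$severity_score > 8)) {
    pmr_stop("pmr_integrity_error", "patients: severity_score outside 0-8")
  }
  with(patients, {
    if (any(crp < 0, na.rm = TRUE) || any(esr < 0, na.rm = TRUE) || any(hb <= 0, na.rm = TRUE)) {
      pmr_stop("pmr_integrity_error", "patients: acute phase reactants must be >= 0 and hb > 0")
    }
    if (any(followup_end_date < baseline_date)) {
      pmr_stop("pmr_integrity_error", "patients: followup_end_date before baseline_date")
    }
  })

  vraw <- read_raw_table(visits_path, VISIT_COLS)
  visits <- data.frame(
    patient_id = trimws(vraw$patient_id),
    visit_date = parse_date_col(vraw$visit_date, "visit_date", visits_path),
    pred_dose = parse_numeric_col(vraw$pred_dose, "pred_dose", visits_path, allow_missing = FALSE),
    rj_not_in_remission = parse_logical_col(vraw$rj_not_in_remission, "rj_not_in_remission", visits_path),
    rj_interval_relapse = parse_logical_col(vraw$rj_interval_relapse, "rj_interval_relapse", visits_path),
    dose_increased_since_prev = parse_logical_col(vraw$dose_increased_since_prev, "dose_increased_since_prev", visits_path),
    dmard_intensified_for_inefficacy = parse_logical_col(vraw$dmard_intensified_for_inefficacy, "dmard_intensified_for_inefficacy", visits_path),
    gc_injection_added = parse_logical_col(vraw$gc_injection_added, "gc_injection_added", visits_path),
    stringsAsFactors = FALSE
  )
  if (nrow(visits)) {
    if (any(visits$pred_dose < 0)) {
      pmr_stop("pmr_integrity_error", "visits: negative prednisolone dose")
    }
    key <- paste(visits$patient_id, visits$visit_date)
    if (anyDuplicated(key)) {
      pmr_stop("pmr_integrity_error",
               sprintf("duplicate visit for %s", key[duplicated(key)][1]))
    }
    orphan <- setdiff(visits$patient_id, patients$patient_id)
    if (length(orphan)) {
      pmr_stop("pmr_integrity_error",
               sprintf("visit(s) for unknown patient_id: %s", orphan[1]))
    }
    visits <- visits[order(visits$patient_id, visits$visit_date), , drop = FALSE]
    rownames(visits) <- NULL
  }
  list(patients = patients, visits = visits)
}

format_csv_value <- function(x) {
  if (inherits(x, "Date")) {
    out <- format(x, "%Y-%m-%d")
  } else if (is.logical(x)) {
    out <- ifelse(x, "1", "0")
  } else if (is.numeric(x)) {
    out <- vapply(x, function(v) if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE),
                  character(1))
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- ""
  out
}

write_table_csv <- function(df, path) {
  out <- vapply(df, format_csv_value, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = names(df))
  invisible(path)
}

#' Write a cohort to delimited text tables
#'
#' Writes `patients.csv`, `visits.csv` and (when the cohort carries
#' simulated ground truth) `truth.csv` in the documented schema: ISO-8601
#' dates, 0/1 booleans, empty field for missing.
#'
#' @param cohort a `"pmr_cohort"` object or a list with `patients` and
#'   `visits`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    visits = file.path(dir, "visits.csv")
  )
  write_table_csv(cohort$patients[, PATIENT_COLS], paths[["patients"]])
  write_table_csv(cohort$visits[, VISIT_COLS], paths[["visits"]])
  if (!is.null(cohort$truth$events)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    write_table_csv(cohort$truth$events, paths[["truth"]])
  }
  invisible(paths)
}

ELIGIBILITY_REASONS <- c("ok", "too_early", "dose_at_or_below_2_5",
                         "post_treatment_window", "after_followup_end")

#' Visit eligibility for relapse adjudication
#'
#' Applies the potential-relapse-visit rules for one patient: a visit is
#' eligible iff it falls strictly more than 30 days after baseline
#' (initial-response period), carries an oral prednisolone dose strictly
#' above 2.5 mg/day, is no more than 90 days after oral treatment ended,
#' and is not after the follow-up end date. "Treatment ended" is the first
#' zero-dose visit with no later positive dose (undefined while treatment
#' is ongoing).
#'
#' A visit can violate several rules at once; the single reported reason
#' follows the fixed precedence `after_followup_end` >
#' `post_treatment_window` > `too_early` > `dose_at_or_below_2_5`.
#'
#' @param patient one-row patient data frame (needs `baseline_date` and
#'   `followup_end_date`).
#' @param visits this patient's visits, sorted by date.
#' @return data frame with one row per input visit: `patient_id`,
#'   `visit_date`, `day` (days since baseline), `eligible`, `reason`.
#' @export
filter_eligible_visits <- function(patient, visits) {
  if (nrow(visits) == 0L) {
    return(data.frame(patient_id = character(0), visit_date = as.Date(character(0)),
                      day = numeric(0), eligible = logical(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!all(visits$patient_id == patient$patient_id)) {
    pmr_stop("pmr_contract_error", "filter_eligible_visits: visits do not all belong to the patient")
  }
  if (is.unsorted(visits$visit_date, strictly = TRUE)) {
    pmr_stop("pmr_contract_error", "filter_eligible_visits: visits must be strictly sorted by date")
  }
  day <- as.numeric(visits$visit_date - patient$baseline_date)
  if (any(day < 0)) {
    pmr_stop("pmr_integrity_error", "visit before the patient's baseline date")
  }
  reason <- eligibility_reasons(day, visits$pred_dose,
                                as.numeric(patient$followup_end_date - patient$baseline_date))
  data.frame(patient_id = visits$patient_id, visit_date = visits$visit_date,
             day = day, eligible = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

# vectorised core of the eligibility rules; `day` in days since baseline,
# sorted. Returns the reason per visit (precedence documented above).
eligibility_reasons <- function(day, dose, fup_day) {
  te <- treatment_end_day(day, dose)
  reason <- rep("ok", length(day))
  reason[dose <= 2.5] <- "dose_at_or_below_2_5"
  reason[day <= 30] <- "too_early"
  if (!is.na(te)) reason[day > te + 90] <- "post_treatment_window"
  reason[day > fup_day] <- "after_followup_end"
  reason
}

# first zero-dose visit day with no later positive dose (NA while treatment
# is ongoing)
treatment_end_day <- function(day, dose) {
  zero <- dose == 0
  if (!any(zero)) return(NA_real_)
  last_pos <- if (any(!zero)) max(which(!zero)) else 0L
  ffz <- which(zero & seq_along(zero) > last_pos)
  if (length(ffz)) day[ffz[1]] else NA_real_
}
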