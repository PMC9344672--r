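# Univariable association screening between baseline predictors and
# treatment-intensification relapse: logistic regression for relapse
# within a horizon (odds ratios), Poisson regression with a log
# person-time offset for the relapse rate (incidence rate ratios).

#' Candidate predictor specifications
#'
#' The twelve baseline candidate predictors: age, sex, cardiovascular
#' history, malignancy history, smoking (never/stopped/current, reference
#' never), pre-treatment symptom duration, the 0-8 clinical severity
#' score, peripheral arthritis, systemic symptoms, CRP, ESR and
#' haemoglobin. CRP and ESR are divided by 10 so coefficients are per
#' 10 mg/L and per 10 mm/h; symptom duration enters in months by default
#' (`weeks / 4.345`; set `symptom_duration_unit = "weeks"` for per-week
#' effects).
#'
#' @param symptom_duration_unit `"months"` (default) or `"weeks"`.
#' @return data frame with columns `name`, `field`, `transform`, `type`,
#'   `reference`.
#' @export
predictor_specs <- function(symptom_duration_unit = c("months", "weeks")) {
  symptom_duration_unit <- match.arg(symptom_duration_unit)
  specs <- data.frame(
    name = c("age", "sex", "cvd_history", "malignancy_history", "smoking",
             "symptom_duration", "severity_score", "arthritis",
             "systemic_symptoms", "crp10", "esr10", "hb"),
    field = c("age", "sex", "cvd_history", "malignancy_history", "smoking",
              "symptom_duration_weeks", "severity_score", "arthritis",
              "systemic_symptoms", "crp", "esr", "hb"),
    transform = c("identity", "categorical", "identity", "identity",
                  "categorical",
                  if (symptom_duration_unit == "months") "weeks_to_months" else "identity",
                  "identity", "identity", "identity",
                  "divide_by_10", "divide_by_10", "identity"),
    type = c("continuous", "binary", "binary", "binary", "categorical",
             "continuous", "continuous", "binary", "binary",
             "continuous", "continuous", "continuous"),
    reference = c(NA, "male", NA, NA, "never", NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  class(specs) <- c("pmr_predictor_specs", "data.frame")
  specs
}

#' Build one transformed predictor column
#'
#' @param patients patient table.
#' @param spec one row of [predictor_specs()] (or a list with the same
#'   fields).
#' @return numeric vector, logical vector or factor (reference level
#'   first), with `NA` where the source field is missing.
#' @export
build_predictor <- function(patients, spec) {
  x <- patients[[spec$field]]
  if (is.null(x)) {
    pmr_stop("pmr_contract_error",
             sprintf("build_predictor: no field '%s' in patient table", spec$field))
  }
  switch(spec$transform,
    identity = if (is.logical(x)) x else as.numeric(x),
    divide_by_10 = as.numeric(x) / 10,
    weeks_to_months = as.numeric(x) / WEEKS_PER_MONTH,
    categorical = {
      lev <- if (spec$field == "smoking") c("never", "stopped", "current")
             else c(spec$reference, setdiff(unique(x[!is.na(x)]), spec$reference))
      factor(x, levels = lev)
    },
    pmr_stop("pmr_config_error", sprintf("unknown transform '%s'", spec$transform))
  )
}

binary_outcome_within <- function(events, patients, horizon) {
  cut <- horizon * DAYS_PER_YEAR
  patients$patient_id %in% events$patient_id[events$event_day <= cut]
}

event_counts <- function(events, patients) {
  tab <- table(factor(events$patient_id, levels = patients$patient_id))
  as.integer(tab)
}

glm_rows <- function(fit, spec, outcome_label, n_used, conf = 0.95) {
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  sm <- sm[keep, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(
    predictor = spec$name,
    term = rownames(sm),
    outcome = outcome_label,
    effect = exp(sm[, 1]),
    ci_lo = exp(sm[, 1] - z * sm[, 2]),
    ci_hi = exp(sm[, 1] + z * sm[, 2]),
    p = sm[, 4],
    n_used = n_used,
    note = "",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

check_separation <- function(fit) {
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(co)) || any(abs(co[-1]) > 10) || any(!is.finite(se)) || any(se > 50)) {
    pmr_stop("pmr_separation_error",
             "univariable fit shows (quasi-)complete separation; estimate unreliable")
  }
  invisible(fit)
}

#' Univariable logistic association with relapse within a horizon
#'
#' Complete-case maximum-likelihood logistic regression of the binary
#' outcome "at least one adjudicated relapse within `horizon` years" on a
#' single transformed predictor. Effects are odds ratios with Wald 95%
#' confidence intervals and p-values.
#'
#' @param patients patient table.
#' @param events event stream ([relapse_events()]), normally under the TI
#'   criterion.
#' @param spec one row of [predictor_specs()].
#' @param horizon horizon in years.
#' @return data frame with one row per non-reference level (`predictor`,
#'   `term`, `outcome`, `effect` = OR, `ci_lo`, `ci_hi`, `p`, `n_used`).
#' @export
univariable_logistic <- function(patients, events, spec, horizon = 1) {
  y <- binary_outcome_within(events, patients, horizon)
  x <- build_predictor(patients, spec)
  cc <- !is.na(x)
  y <- y[cc]; x <- x[cc]
  if (length(unique(y)) < 2L) {
    pmr_stop("pmr_degenerate_error",
             "univariable_logistic: outcome constant among complete cases")
  }
  fit <- stats::glm(y ~ x, family = stats::binomial())
  check_separation(fit)
  rows <- glm_rows(fit, spec, sprintf("relapse_0_%gy", horizon), sum(cc))
  rows$term <- sub("^x", "", rows$term)
  rows$term[rows$term == ""] <- rows$predictor[rows$term == ""]
  rows
}

#' Univariable Poisson association with the relapse rate
#'
#' Complete-case Poisson regression of each patient's adjudicated relapse
#' count on a single transformed predictor, with a log person-years offset.
#' Effects are incidence rate ratios (per unit of the transformed
#' predictor) with Wald intervals.
#'
#' @inheritParams univariable_logistic
#' @param visits,person_time_rule passed to [person_years()].
#' @return data frame as in [univariable_logistic()], `effect` = IRR.
#' @export
univariable_poisson <- function(patients, events, spec, visits = NULL,
                                person_time_rule = "window") {
  cnt <- event_counts(events, patients)
  py <- person_years(patients, visits, rule = person_time_rule)
  x <- build_predictor(patients, spec)
  cc <- !is.na(x) & py > 0
  cnt <- cnt[cc]; py <- py[cc]; x <- x[cc]
  if (sum(py) <= 0) {
    pmr_stop("pmr_degenerate_error", "univariable_poisson: zero person-time")
  }
  if (sum(cnt) == 0L) {
    pmr_stop("pmr_degenerate_error", "univariable_poisson: zero events among complete cases")
  }
  fit <- stats::glm(cnt ~ x + offset(log(py)), family = stats::poisson())
  check_separation(fit)
  rows <- glm_rows(fit, spec, "relapse_rate", sum(cc))
  rows$term <- sub("^x", "", rows$term)
  rows$term[rows$term == ""] <- rows$predictor[rows$term == ""]
  rows
}

#' Full univariable association table
#'
#' Fits every candidate predictor against the three outcomes: relapse
#' within 1 year (OR), relapse within 2 years (OR) and the relapse rate
#' (IRR). Failing cells (degenerate outcome, separation, ...) are marked
#' in the `note` column rather than aborting the table. `significant`
#' flags p < 0.05.
#'
#' @param patients patient table.
#' @param events event stream (TI criterion).
#' @param specs predictor specifications, default [predictor_specs()].
#' @param visits,person_time_rule passed to [person_years()].
#' @return data frame of class `"pmr_association_table"`, one row per
#'   predictor contrast and outcome.
#' @export
association_table <- function(patients, events, specs = predictor_specs(),
                              visits = NULL, person_time_rule = "window") {
  out <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, , drop = FALSE]
    for (task in list(list(f = "logit", h = 1), list(f = "logit", h = 2),
                      list(f = "poisson"))) {
      lab <- if (task$f == "logit") sprintf("relapse_0_%gy", task$h) else "relapse_rate"
      rows <- tryCatch(
        if (task$f == "logit") univariable_logistic(patients, events, spec, task$h)
        else univariable_poisson(patients, events, spec, visits, person_time_rule),
        pmr_error = function(e) {
          nlev <- if (spec$type == "categorical") 2L else 1L
          data.frame(predictor = spec$name, term = spec$name, outcome = lab,
                     effect = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     p = NA_real_, n_used = NA_integer_,
                     note = conditionMessage(e),
                     stringsAsFactors = FALSE)[rep(1L, nlev), ]
        })
      out[[length(out) + 1L]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$significant <- !is.na(res$p) & res$p < 0.05
  class(res) <- c("pmr_association_table", "data.frame")
  res
}
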