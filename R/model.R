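# Development and internal validation of the multivariable model for
# treatment-intensification relapse within the first year: backward
# elimination within each imputed dataset, across-imputation inclusion
# fractions, Rubin pooling, and Harrell bootstrap optimism correction of
# the concordance statistic.

MODEL_CANDIDATES <- c("age", "sex", "cvd_history", "malignancy_history",
                      "smoking", "symptom_duration", "severity_score",
                      "arthritis", "systemic_symptoms", "crp10", "esr10", "hb")

#' Analysis-ready model frame for the prediction model
#'
#' Transforms a (completed) patient table into the covariates the model
#' uses: CRP and ESR per 10 units, symptom duration in months (default)
#' or weeks, factors with fixed reference levels (sex: male; smoking:
#' never).
#'
#' @param patients patient table.
#' @param symptom_duration_unit `"months"` or `"weeks"`.
#' @return data frame with columns `age, sex, cvd_history,
#'   malignancy_history, smoking, symptom_duration, severity_score,
#'   arthritis, systemic_symptoms, crp10, esr10, hb`.
#' @export
build_model_frame <- function(patients, symptom_duration_unit = c("months", "weeks")) {
  symptom_duration_unit <- match.arg(symptom_duration_unit)
  data.frame(
    age = as.numeric(patients$age),
    sex = factor(patients$sex, levels = c("male", "female")),
    cvd_history = as.numeric(patients$cvd_history),
    malignancy_history = as.numeric(patients$malignancy_history),
    smoking = factor(patients$smoking, levels = c("never", "stopped", "current")),
    symptom_duration = patients$symptom_duration_weeks /
      (if (symptom_duration_unit == "months") WEEKS_PER_MONTH else 1),
    severity_score = as.numeric(patients$severity_score),
    arthritis = as.numeric(patients$arthritis),
    systemic_symptoms = as.numeric(patients$systemic_symptoms),
    crp10 = patients$crp / 10,
    esr10 = patients$esr / 10,
    hb = as.numeric(patients$hb)
  )
}

# Wald chi-square p-value for every variable of a fitted glm (multi-df for
# factors), computed from one fit without refitting
wald_p_by_var <- function(fit) {
  asg <- attr(stats::model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  out <- stats::setNames(rep(NA_real_, length(labs)), labs)
  for (j in seq_along(labs)) {
    idx <- which(asg == j)
    idx <- idx[!is.na(co[idx])]
    if (!length(idx)) { out[j] <- 1; next }
    b <- co[idx]
    W <- tryCatch(drop(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b),
                  error = function(e) NA_real_)
    out[j] <- if (is.na(W)) 1 else stats::pchisq(W, df = length(idx), lower.tail = FALSE)
  }
  out
}

#' Across-imputation selection rule
#'
#' A variable enters the final model iff it was retained in strictly more
#' than `threshold` of the imputed datasets; e.g. a variable retained in
#' 40% of sets is dropped at the default threshold of 0.5.
#'
#' @param retained list (one element per imputed dataset) of retained
#'   variable-name vectors.
#' @param candidates candidate variable names.
#' @param threshold inclusion-fraction threshold.
#' @return list with `inclusion_fractions` (named) and `selected`.
#' @export
select_by_inclusion <- function(retained, candidates, threshold = 0.5) {
  incl <- vapply(candidates,
                 function(v) mean(vapply(retained, function(r) v %in% r, logical(1))),
                 numeric(1))
  list(inclusion_fractions = incl, selected = candidates[incl > threshold])
}

# backward elimination on one completed dataset; returns retained variables
backward_eliminate <- function(d, candidates, retention_p) {
  vars <- candidates
  while (length(vars)) {
    fit <- stats::glm(stats::reformulate(vars, "y"), family = stats::binomial(),
                      data = d)
    p <- wald_p_by_var(fit)
    if (max(p) <= retention_p) break
    vars <- setdiff(vars, names(which.max(p)))
  }
  vars
}

fit_on_set <- function(d, vars) {
  f <- if (length(vars)) stats::reformulate(vars, "y") else stats::as.formula(y ~ 1)
  stats::glm(f, family = stats::binomial(), data = d)
}

all_sets_identical <- function(frames) {
  if (length(frames) < 2L) return(TRUE)
  for (s in seq.int(2L, length(frames))) {
    if (!identical(frames[[s]], frames[[1L]])) return(FALSE)
  }
  TRUE
}

#' Develop the multivariable relapse model across imputed datasets
#'
#' Within each imputed dataset, backward elimination from the full
#' candidate set removes the variable with the largest Wald p-value until
#' all remaining variables satisfy `p < retention_p` (default 0.157, the
#' AIC-equivalent threshold). The final variable set consists of the
#' variables retained in more than `inclusion_threshold` of the imputed
#' datasets (default 0.5, so a variable kept in only 40% of sets is
#' dropped). The selected model is then refitted on every dataset and the
#' coefficients pooled by Rubin's rules: pooled estimate = mean estimate,
#' total variance = within + (1 + 1/m) x between.
#'
#' @param imputations `"pmr_imputations"` object (or list of completed
#'   patient tables).
#' @param outcome logical vector: relapse within the horizon, one per
#'   patient.
#' @param candidates candidate variable names (default all twelve).
#' @param retention_p backward-elimination retention threshold.
#' @param inclusion_threshold across-imputation inclusion fraction a
#'   variable must exceed.
#' @param symptom_duration_unit passed to [build_model_frame()].
#' @return list with `selected`, `inclusion_fractions`, `retained_per_set`,
#'   `coefficients` (pooled table), `per_set_coefs`, `formula`, `m`.
#' @export
develop_model <- function(imputations, outcome,
                          candidates = MODEL_CANDIDATES,
                          retention_p = 0.157,
                          inclusion_threshold = 0.5,
                          symptom_duration_unit = "months") {
  if (length(unique(outcome)) < 2L) {
    pmr_stop("pmr_degenerate_error", "develop_model: outcome is constant")
  }
  frames <- lapply(imputations, function(p) {
    d <- build_model_frame(p, symptom_duration_unit)[, candidates, drop = FALSE]
    d$y <- as.numeric(outcome)
    d
  })
  m <- length(frames)
  dedup <- all_sets_identical(frames)
  run_idx <- if (dedup) 1L else seq_len(m)

  retained <- vector("list", m)
  for (s in run_idx) {
    retained[[s]] <- backward_eliminate(frames[[s]], candidates, retention_p)
  }
  if (dedup) retained <- rep(retained[1L], m)

  sel <- select_by_inclusion(retained, candidates, inclusion_threshold)
  incl <- sel$inclusion_fractions
  selected <- sel$selected
  if (!length(selected)) {
    warning("develop_model: no variable exceeded the inclusion threshold; ",
            "returning an intercept-only model")
  }

  fits <- vector("list", m)
  for (s in run_idx) fits[[s]] <- fit_on_set(frames[[s]], selected)
  if (dedup) fits <- rep(fits[1L], m)
  coefs <- t(vapply(fits, stats::coef, stats::coef(fits[[1]])))
  if (length(stats::coef(fits[[1]])) == 1L) {
    coefs <- matrix(vapply(fits, stats::coef, numeric(1)), ncol = 1,
                    dimnames = list(NULL, names(stats::coef(fits[[1]]))))
  }
  vars_within <- t(vapply(fits, function(f) diag(stats::vcov(f)),
                          diag(stats::vcov(fits[[1]]))))
  if (ncol(coefs) == 1L) vars_within <- matrix(vapply(fits, function(f) diag(stats::vcov(f)), numeric(1)), ncol = 1)

  qbar <- colMeans(coefs)
  W <- colMeans(vars_within)
  B <- if (m > 1) apply(coefs, 2, stats::var) else rep(0, length(qbar))
  Tvar <- W + (1 + 1 / m) * B
  z <- stats::qnorm(0.975)
  pooled <- data.frame(
    term = names(qbar), estimate = qbar, se = sqrt(Tvar),
    ci_lo = qbar - z * sqrt(Tvar), ci_hi = qbar + z * sqrt(Tvar),
    within_var = W, between_var = B,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(selected = selected,
       inclusion_fractions = incl,
       retained_per_set = retained,
       coefficients = pooled,
       per_set_coefs = coefs,
       formula = if (length(selected)) stats::reformulate(selected, "y") else y ~ 1,
       m = m)
}

# mean (and range) of the per-set c-statistics of a pooled coefficient
# vector applied to a list of model frames
pooled_auc <- function(dev, frames, outcome) {
  beta <- stats::setNames(dev$coefficients$estimate, dev$coefficients$term)
  if (length(beta) == 1L) return(list(mean = 0.5, range = c(0.5, 0.5)))
  rhs <- stats::delete.response(stats::terms(dev$formula))
  aucs <- vapply(frames, function(d) {
    X <- stats::model.matrix(rhs, data = d)
    cstat(drop(X %*% beta[colnames(X)]), outcome)
  }, numeric(1))
  list(mean = mean(aucs), range = range(aucs))
}

#' Bootstrap optimism-corrected discrimination
#'
#' Harrell's bootstrap: patients are resampled with replacement (all of a
#' patient's rows across imputed datasets move together) and the *entire*
#' development procedure — backward elimination, across-imputation
#' selection, refit and pooling — is repeated in each bootstrap sample.
#' The optimism is the mean difference between the bootstrap model's AUC on
#' the bootstrap sample and its AUC on the original data; it is subtracted
#' from the apparent AUC. Bootstrap samples with a constant outcome are
#' redrawn (capped retries).
#'
#' @inheritParams develop_model
#' @param n_bootstrap number of bootstrap resamples (>= 100).
#' @param seed integer seed for the resampling.
#' @return list with `apparent_auc`, `apparent_auc_range`, `optimism`,
#'   `corrected_auc`, `n_bootstrap`, and the development result as
#'   `development`.
#' @export
validate_model <- function(imputations, outcome,
                           candidates = MODEL_CANDIDATES,
                           retention_p = 0.157, inclusion_threshold = 0.5,
                           n_bootstrap = 200L, seed = 1L,
                           symptom_duration_unit = "months") {
  if (!is_scalar_number(n_bootstrap) || n_bootstrap < 100) {
    pmr_stop("pmr_precondition_error",
             "validate_model: n_bootstrap must be at least 100")
  }
  dev <- develop_model(imputations, outcome, candidates, retention_p,
                       inclusion_threshold, symptom_duration_unit)
  frames <- lapply(imputations, function(p)
    build_model_frame(p, symptom_duration_unit)[, candidates, drop = FALSE])
  for (i in seq_along(frames)) frames[[i]]$y <- as.numeric(outcome)
  app <- pooled_auc(dev, frames, outcome)

  set.seed(seed)
  n <- length(outcome)
  opt <- numeric(n_bootstrap)
  skipped <- 0L
  for (b in seq_len(n_bootstrap)) {
    idx <- NULL
    for (try in 1:25) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcome[cand])) == 2L) { idx <- cand; break }
    }
    if (is.null(idx)) { skipped <- skipped + 1L; opt[b] <- NA_real_; next }
    frames_b <- lapply(frames, function(d) d[idx, , drop = FALSE])
    dev_b <- suppressWarnings(
      develop_model(frames_to_imputations(imputations, idx), outcome[idx],
                    candidates, retention_p, inclusion_threshold,
                    symptom_duration_unit))
    auc_boot <- pooled_auc(dev_b, frames_b, outcome[idx])$mean
    auc_orig <- pooled_auc(dev_b, frames, outcome)$mean
    opt[b] <- auc_boot - auc_orig
  }
  optimism <- mean(opt, na.rm = TRUE)
  list(apparent_auc = app$mean, apparent_auc_range = app$range,
       optimism = optimism, corrected_auc = app$mean - optimism,
       n_bootstrap = n_bootstrap, n_skipped = skipped, development = dev)
}

# resample the completed patient tables by patient index, preserving the
# imputation-set structure
frames_to_imputations <- function(imputations, idx) {
  out <- lapply(imputations, function(p) p[idx, , drop = FALSE])
  attributes(out) <- attributes(imputations)
  out
}

#' Fit the relapse prediction model
#'
#' The package's main modelling entry point: develops and internally
#' validates a multivariable logistic model for treatment-intensification
#' relapse within `horizon` years of starting prednisolone. The procedure
#' is: (1) multiple imputation of the incomplete baseline covariates by
#' chained equations ([impute_cohort()]); (2) backward elimination within
#' each imputed dataset and across-imputation selection
#' ([develop_model()]); (3) Rubin pooling of the refitted coefficients;
#' (4) bootstrap optimism correction of the concordance statistic
#' ([validate_model()]). An events-per-variable warning is raised when the
#' candidate count exceeds events/10.
#'
#' @param patients patient table (see [read_cohort()]).
#' @param events relapse event stream from [relapse_events()] (TI
#'   criterion).
#' @param horizon prediction horizon in years (default 1).
#' @param m number of imputed datasets.
#' @param n_bootstrap bootstrap resamples for optimism correction; set
#'   `validate = FALSE` to skip validation.
#' @param seed integer seed controlling imputation and bootstrap.
#' @param candidates candidate variables (default all twelve).
#' @param retention_p,inclusion_threshold selection tuning, see
#'   [develop_model()].
#' @param symptom_duration_unit `"months"` or `"weeks"`.
#' @param validate run the bootstrap validation (default TRUE).
#' @return object of class `"relapse_model"`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 150, seed = 5))
#' ev <- relapse_events(adjudicate(coh), "TI")
#' fit <- relapse_model(coh$patients, ev, m = 3, validate = FALSE)
#' fit
#' @export
relapse_model <- function(patients, events, horizon = 1, m = 20L,
                          n_bootstrap = 200L, seed = 1L,
                          candidates = MODEL_CANDIDATES,
                          retention_p = 0.157, inclusion_threshold = 0.5,
                          symptom_duration_unit = "months",
                          validate = TRUE) {
  cl <- match.call()
  y <- binary_outcome_within(events, patients, horizon)
  n_events <- sum(y)
  if (n_events == 0L || n_events == length(y)) {
    pmr_stop("pmr_degenerate_error", "relapse_model: outcome is constant")
  }
  if (length(candidates) > n_events / 10) {
    warning(sprintf(
      "relapse_model: %d candidate variables for %d events violates the 10-events-per-variable rule of thumb",
      length(candidates), n_events))
  }
  imp <- impute_cohort(patients, y, m = m, seed = seed)
  if (validate) {
    val <- validate_model(imp, y, candidates, retention_p, inclusion_threshold,
                          n_bootstrap = n_bootstrap, seed = seed + 1L,
                          symptom_duration_unit = symptom_duration_unit)
    dev <- val$development
  } else {
    dev <- develop_model(imp, y, candidates, retention_p, inclusion_threshold,
                         symptom_duration_unit)
    frames <- lapply(imp, function(p)
      build_model_frame(p, symptom_duration_unit)[, candidates, drop = FALSE])
    app <- pooled_auc(dev, frames, y)
    val <- list(apparent_auc = app$mean, apparent_auc_range = app$range,
                optimism = NA_real_, corrected_auc = NA_real_,
                n_bootstrap = 0L)
  }
  structure(list(
    call = cl,
    horizon = horizon,
    n = length(y), n_events = n_events,
    m = m,
    candidates = candidates,
    selected_variables = dev$selected,
    inclusion_fractions = dev$inclusion_fractions,
    coefficients = dev$coefficients,
    per_set_coefs = dev$per_set_coefs,
    formula = dev$formula,
    symptom_duration_unit = symptom_duration_unit,
    apparent_auc = val$apparent_auc,
    apparent_auc_range = val$apparent_auc_range,
    optimism = val$optimism,
    corrected_auc = val$corrected_auc,
    n_bootstrap = val$n_bootstrap,
    imputations = imp
  ), class = "relapse_model")
}

#' @export
coef.relapse_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Predict relapse risk for new patients
#'
#' Inverse-logit of the pooled linear predictor. Every selected covariate
#' must be observed (or already imputed) in `newdata`; a missing selected
#' covariate raises an error rather than silently dropping the patient.
#'
#' @param object a fitted [relapse_model()].
#' @param newdata patient table rows.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @return numeric vector of predicted risks in (0, 1) (or log-odds).
#' @export
predict.relapse_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  mf <- build_model_frame(newdata, object$symptom_duration_unit)
  need <- object$selected_variables
  if (length(need)) {
    bad <- need[vapply(need, function(v) anyNA(mf[[v]]), logical(1))]
    if (length(bad)) {
      pmr_stop("pmr_missing_covariate_error",
               sprintf("predict: missing values in selected covariate(s): %s",
                       paste(bad, collapse = ", ")))
    }
  }
  mf$y <- 0
  X <- stats::model.matrix(object$formula, data = mf)
  beta <- coef(object)
  lp <- drop(X %*% beta[colnames(X)])
  if (type == "link") lp else inv_logit(lp)
}

#' @rdname predict.relapse_model
#' @param model a fitted [relapse_model()].
#' @param patient one or more patient rows.
#' @export
predict_risk <- function(model, patient) {
  predict(model, patient, type = "response")
}

#' Sensitivity-analysis subset: EULAR/ACR core criteria
#'
#' Restricts the cohort to patients fulfilling the 2012 EULAR/ACR core
#' classification criteria (without the scoring scale), so the full
#' development and validation pipeline can be rerun unchanged on the
#' subset.
#'
#' @param patients patient table with `meets_eular_acr_core`.
#' @return the filtered patient table.
#' @export
sensitivity_subset <- function(patients) {
  if (is.null(patients$meets_eular_acr_core)) {
    pmr_stop("pmr_contract_error",
             "sensitivity_subset: meets_eular_acr_core column missing")
  }
  out <- patients[!is.na(patients$meets_eular_acr_core) &
                    patients$meets_eular_acr_core, , drop = FALSE]
  if (nrow(out) == 0L) {
    pmr_stop("pmr_empty_error",
             "sensitivity_subset: no patient meets the EULAR/ACR core criteria")
  }
  rownames(out) <- NULL
  out
}

#' @export
print.relapse_model <- function(x, ...) {
  cat(sprintf("Relapse prediction model (TI relapse within %g year%s)\n",
              x$horizon, if (x$horizon == 1) "" else "s"))
  cat(sprintf("  n = %d patients, %d events; %d imputed datasets\n",
              x$n, x$n_events, x$m))
  if (length(x$selected_variables)) {
    cat("  selected:", paste(x$selected_variables, collapse = ", "), "\n")
  } else {
    cat("  selected: (intercept only)\n")
  }
  cat(sprintf("  apparent AUC: %.3f (per-set range %.3f-%.3f)\n",
              x$apparent_auc, x$apparent_auc_range[1], x$apparent_auc_range[2]))
  if (x$n_bootstrap > 0) {
    cat(sprintf("  optimism: %.3f (%d bootstrap resamples) -> corrected AUC: %.3f\n",
                x$optimism, x$n_bootstrap, x$corrected_auc))
  }
  invisible(x)
}

#' @export
summary.relapse_model <- function(object, ...) {
  tab <- object$coefficients
  tab$odds_ratio <- exp(tab$estimate)
  tab$or_lo <- exp(tab$ci_lo)
  tab$or_hi <- exp(tab$ci_hi)
  structure(list(model = object, coefficients = tab,
                 inclusion_fractions = sort(object$inclusion_fractions,
                                            decreasing = TRUE)),
            class = "summary.relapse_model")
}

#' @export
print.summary.relapse_model <- function(x, digits = 3, ...) {
  print(x$model)
  cat("\nPooled coefficients (Rubin's rules):\n")
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(cl) signif(cl, digits))
  print(tab[, c("term", "estimate", "se", "odds_ratio", "or_lo", "or_hi")],
        row.names = FALSE)
  cat("\nInclusion fractions across imputation sets:\n")
  print(round(x$inclusion_fractions, 2))
  invisible(x)
}
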