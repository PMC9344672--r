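# Chained-equations multiple imputation for the baseline covariates with
# missingness (smoking, symptom duration, CRP, ESR, Hb). Continuous
# covariates are imputed by predictive mean matching on a Bayesian linear
# regression draw (so imputed values are always observed values and skewed
# or bounded distributions keep their support); three-level smoking by a
# multinomial model fitted to a bootstrap resample of the observed rows
# (the resample approximating the parameter draw). All candidate
# predictors and the outcome enter every imputation model.

IMPUTABLE_COLS <- c("smoking", "symptom_duration_weeks", "crp", "esr", "hb")

# Bayesian-draw PMM: returns imputed values for rows `mis` of y
pmm_impute <- function(X, y, obs, mis, k = 5L) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  p <- ncol(Xo)
  XtX <- crossprod(Xo) + diag(1e-8, p)
  XtXinv <- solve(XtX)
  betahat <- XtXinv %*% crossprod(Xo, yo)
  res <- yo - Xo %*% betahat
  df <- max(length(yo) - p, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- betahat + t(chol(XtXinv)) %*% stats::rnorm(p) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% betahat)
  yhat_mis <- drop(X[mis, , drop = FALSE] %*% beta_star)
  out <- numeric(length(mis))
  kk <- min(k, length(yo))
  for (j in seq_along(mis)) {
    d <- abs(yhat_obs - yhat_mis[j])
    donors <- order(d)[seq_len(kk)]
    out[j] <- yo[donors[sample.int(kk, 1L)]]
  }
  out
}

# bootstrap-multinomial draw for a factor variable
multinom_impute <- function(X, y, obs, mis) {
  bs <- obs[sample.int(length(obs), length(obs), replace = TRUE)]
  dat <- data.frame(.target = droplevels(y[bs]), X[bs, -1, drop = FALSE])
  fit <- nnet::multinom(.target ~ ., data = dat, trace = FALSE, maxit = 200)
  nd <- data.frame(X[mis, -1, drop = FALSE])
  pr <- stats::predict(fit, newdata = nd, type = "probs")
  lev <- levels(droplevels(y[bs]))
  if (length(lev) == 1L) return(factor(rep(lev, length(mis)), levels = levels(y)))
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = length(mis),
                                     ncol = length(lev), byrow = length(mis) == 1L)
  drawn <- apply(pr, 1L, function(p) sample(lev, 1L, prob = p))
  factor(drawn, levels = levels(y))
}

impute_design <- function(work, target) {
  rhs <- setdiff(names(work), target)
  stats::model.matrix(stats::reformulate(rhs), data = work)
}

#' Multiple imputation of baseline covariates
#'
#' Generates `m` completed copies of the patient table by chained
#' equations over the covariates with missing values (among smoking,
#' symptom duration, CRP, ESR, Hb). Every imputation model includes all
#' twelve candidate predictors plus the relapse outcome. Originally
#' observed values are never altered; only originally missing cells differ
#' across the returned sets. Deterministic under a fixed seed.
#'
#' @param patients patient table (see [read_cohort()]).
#' @param outcome logical/0-1 vector, one per patient: relapse within the
#'   modelling horizon. Included in the imputation models so that
#'   imputations are compatible with the analysis model.
#' @param m number of imputed datasets (>= 2).
#' @param seed integer seed.
#' @param maxit chained-equation sweeps per dataset.
#' @param pmm_k donor-pool size for predictive mean matching.
#' @return object of class `"pmr_imputations"`: a list of `m` completed
#'   patient tables, with attributes `m` and `seed`.
#' @export
impute_cohort <- function(patients, outcome, m = 20L, seed = 1L,
                          maxit = 5L, pmm_k = 5L) {
  if (!is_scalar_number(m) || m < 2) {
    pmr_stop("pmr_precondition_error", "impute_cohort: m must be at least 2")
  }
  if (length(outcome) != nrow(patients)) {
    pmr_stop("pmr_contract_error", "impute_cohort: outcome length must match patients")
  }
  targets <- IMPUTABLE_COLS[vapply(IMPUTABLE_COLS,
                                   function(cl) anyNA(patients[[cl]]), logical(1))]
  for (cl in targets) {
    if (all(is.na(patients[[cl]]))) {
      pmr_stop("pmr_infeasible_error",
               sprintf("impute_cohort: covariate '%s' has no observed values", cl))
    }
  }
  set.seed(seed)
  if (!length(targets)) {
    sets <- replicate(m, patients, simplify = FALSE)
    return(structure(sets, class = "pmr_imputations", m = m, seed = seed,
                     targets = character(0)))
  }

  base_work <- data.frame(
    y = as.numeric(outcome),
    age = patients$age,
    sex = factor(patients$sex, levels = c("male", "female")),
    cvd_history = as.numeric(patients$cvd_history),
    malignancy_history = as.numeric(patients$malignancy_history),
    smoking = factor(patients$smoking, levels = c("never", "stopped", "current")),
    symptom_duration_weeks = patients$symptom_duration_weeks,
    severity_score = patients$severity_score,
    arthritis = as.numeric(patients$arthritis),
    systemic_symptoms = as.numeric(patients$systemic_symptoms),
    crp = patients$crp, esr = patients$esr, hb = patients$hb
  )
  miss <- lapply(base_work, function(cl) which(is.na(cl)))
  work_targets <- intersect(names(base_work), targets)

  sets <- vector("list", m)
  for (s in seq_len(m)) {
    work <- base_work
    # initial fill: random draws from the observed values
    for (cl in work_targets) {
      mis <- miss[[cl]]
      obs_vals <- work[[cl]][-mis]
      work[[cl]][mis] <- obs_vals[sample.int(length(obs_vals), length(mis),
                                             replace = TRUE)]
    }
    for (it in seq_len(maxit)) {
      for (cl in work_targets) {
        mis <- miss[[cl]]
        obs <- setdiff(seq_len(nrow(work)), mis)
        X <- impute_design(work, cl)
        if (is.factor(work[[cl]])) {
          work[[cl]][mis] <- multinom_impute(X, work[[cl]], obs, mis)
        } else {
          work[[cl]][mis] <- pmm_impute(X, work[[cl]], obs, mis, k = pmm_k)
        }
      }
    }
    done <- patients
    for (cl in work_targets) {
      filled <- work[[cl]]
      done[[cl]][miss[[cl]]] <- if (is.factor(filled))
        as.character(filled[miss[[cl]]]) else filled[miss[[cl]]]
    }
    sets[[s]] <- done
  }
  structure(sets, class = "pmr_imputations", m = m, seed = seed,
            targets = targets)
}

#' @export
print.pmr_imputations <- function(x, ...) {
  cat(sprintf("Multiple imputation: %d completed datasets (seed %d)\n",
              attr(x, "m"), attr(x, "seed")))
  tg <- attr(x, "targets")
  if (length(tg)) cat("  imputed covariates:", paste(tg, collapse = ", "), "\n")
  else cat("  no missing values; all sets identical to the input\n")
  invisible(x)
}
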