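# simulate a complete-covariate cohort whose 1-year outcome depends only on
# chosen linear-predictor columns of the model frame
sim_outcome_cohort <- function(n, seed, beta = c(), intercept = -0.8) {
  coh <- generate_cohort(test_config(n, seed, lambda = 0))
  mf <- build_model_frame(coh$patients)
  lp <- rep(intercept, n)
  for (nm in names(beta)) lp <- lp + beta[[nm]] * (mf[[nm]] - mean(mf[[nm]]))
  set.seed(seed + 99)
  y <- runif(n) < plogis(lp)
  events <- mk_events(coh$patients$patient_id[y], 120)
  list(patients = coh$patients, events = events, y = y)
}

test_that("selection by inclusion fraction drops variables at or below the threshold", {
  retained <- c(rep(list(c("esr10", "malignancy_history")), 8),
                rep(list("esr10"), 12))
  sel <- select_by_inclusion(retained, c("esr10", "malignancy_history", "hb"), 0.5)
  expect_equal(unname(sel$inclusion_fractions),
               c(1, 0.4, 0))  # 8 of 20 sets = 40% -> excluded
  expect_identical(sel$selected, "esr10")
  # exactly at the threshold is still excluded (strict >)
  sel2 <- select_by_inclusion(rep(list("hb", character(0)), 10), "hb", 0.5)
  expect_identical(sel2$selected, character(0))
})

test_that("Rubin pooling collapses to the single complete-data fit", {
  d <- sim_outcome_cohort(500, seed = 51, beta = c(esr10 = 0.6))
  imp <- impute_cohort(d$patients, d$y, m = 5, seed = 1)
  dev <- develop_model(imp, d$y, candidates = c("esr10", "hb", "age"))
  expect_true(all(dev$coefficients$between_var == 0))
  mf <- build_model_frame(d$patients)
  mf$y <- as.numeric(d$y)
  ref <- stats::glm(dev$formula, family = stats::binomial(), data = mf)
  expect_equal(stats::setNames(dev$coefficients$estimate, dev$coefficients$term),
               coef(ref), tolerance = 1e-10)
  expect_equal(dev$coefficients$se^2, unname(diag(vcov(ref))), tolerance = 1e-10)
})

test_that("a strong predictor is always selected and reported with fraction 1", {
  d <- sim_outcome_cohort(1500, seed = 52, beta = c(esr10 = 1.1))
  imp <- impute_cohort(d$patients, d$y, m = 3, seed = 1)
  dev <- develop_model(imp, d$y)
  expect_true("esr10" %in% dev$selected)
  expect_equal(unname(dev$inclusion_fractions["esr10"]), 1)
})

test_that("an intercept-only model predicts the sample event proportion", {
  d <- sim_outcome_cohort(400, seed = 53, intercept = qlogis(0.32))
  imp <- impute_cohort(d$patients, d$y, m = 2, seed = 1)
  expect_warning(dev <- develop_model(imp, d$y, candidates = character(0)),
                 "intercept-only")
  expect_identical(dev$selected, character(0))
  beta0 <- dev$coefficients$estimate[dev$coefficients$term == "(Intercept)"]
  expect_equal(plogis(beta0), mean(d$y), tolerance = 1e-9)
})

test_that("predictions are monotone in a selected positive coefficient", {
  d <- sim_outcome_cohort(1500, seed = 54, beta = c(esr10 = 1.1))
  fit <- relapse_model(d$patients, d$events, m = 2, validate = FALSE)
  expect_s3_class(fit, "relapse_model")
  expect_true("esr10" %in% fit$selected_variables)
  newp <- d$patients[rep(1, 3), ]
  newp$esr <- c(20, 40, 80)
  risks <- predict(fit, newp)
  expect_true(all(risks > 0 & risks < 1))
  if (coef(fit)[["esr10"]] > 0) expect_true(all(diff(risks) > 0))
  expect_equal(predict_risk(fit, newp), risks)
  # log-odds link is the logit of the response
  expect_equal(plogis(predict(fit, newp, type = "link")), risks, tolerance = 1e-12)
})

test_that("prediction refuses a missing selected covariate", {
  d <- sim_outcome_cohort(1200, seed = 55, beta = c(esr10 = 1.1))
  fit <- relapse_model(d$patients, d$events, m = 2, validate = FALSE)
  newp <- d$patients[1, ]
  newp$esr <- NA_real_
  expect_error(predict(fit, newp), class = "pmr_missing_covariate_error")
})

test_that("validation preconditions and capacity warnings fire", {
  d <- sim_outcome_cohort(300, seed = 56)
  imp <- impute_cohort(d$patients, d$y, m = 2, seed = 1)
  expect_error(validate_model(imp, d$y, n_bootstrap = 50),
               class = "pmr_precondition_error")
  # 12 candidates but well under 120 events here
  expect_warning(relapse_model(d$patients, d$events, m = 2, validate = FALSE),
                 "10-events-per-variable")
})

test_that("the rank c-statistic agrees with an independent ROC implementation", {
  set.seed(57)
  y <- runif(400) < 0.35
  score <- rnorm(400) + y
  expect_equal(cstat(score, y),
               as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  # ties count one half
  expect_equal(cstat(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("the EULAR/ACR sensitivity subset filters and errors as specified", {
  p <- do.call(rbind, lapply(1:10, function(i)
    mk_patient(id = sprintf("P%02d", i), eular = i <= 7)))
  sub <- sensitivity_subset(p)
  expect_identical(nrow(sub), 7L)
  all_in <- sensitivity_subset(sub)
  expect_identical(all_in$patient_id, sub$patient_id)
  p$meets_eular_acr_core <- FALSE
  expect_error(sensitivity_subset(p), class = "pmr_empty_error")

  coh <- generate_cohort(cohort_config(n_patients = 800, seed = 58))
  frac <- nrow(sensitivity_subset(coh$patients)) / 800
  expect_lt(abs(frac - 0.79), 4 * sqrt(0.79 * 0.21 / 800))
})
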