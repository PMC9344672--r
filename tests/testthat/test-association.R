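specs <- predictor_specs()
spec_of <- function(nm) specs[specs$name == nm, , drop = FALSE]

# complete-covariate cohort with outcome-generating events attached
sim_screening_cohort <- function(n, seed, event_prob = 0.3) {
  coh <- generate_cohort(test_config(n, seed, lambda = 0))
  set.seed(seed + 1)
  hit <- runif(n) < event_prob
  events <- mk_events(coh$patients$patient_id[hit], 100)
  list(patients = coh$patients, events = events)
}

test_that("dividing a predictor by 10 scales the log odds ratio exactly tenfold", {
  d <- sim_screening_cohort(600, seed = 31)
  raw_spec <- spec_of("crp10")
  raw_spec$transform <- "identity"
  or_raw <- univariable_logistic(d$patients, d$events, raw_spec)$effect
  or_div <- univariable_logistic(d$patients, d$events, spec_of("crp10"))$effect
  expect_equal(log(or_div), 10 * log(or_raw), tolerance = 1e-6)

  irr_raw <- univariable_poisson(d$patients, d$events, raw_spec)$effect
  irr_div <- univariable_poisson(d$patients, d$events, spec_of("crp10"))$effect
  expect_equal(log(irr_div), 10 * log(irr_raw), tolerance = 1e-6)
})

test_that("the logistic OR for a binary predictor equals the cross-product ratio", {
  d <- sim_screening_cohort(500, seed = 32, event_prob = 0.4)
  x <- d$patients$cvd_history
  y <- d$patients$patient_id %in% d$events$patient_id
  tab <- table(x, y)
  cpr <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  res <- univariable_logistic(d$patients, d$events, spec_of("cvd_history"))
  expect_equal(res$effect, unname(cpr), tolerance = 1e-8)
})

test_that("a null Poisson fit recovers the overall incidence rate in its intercept", {
  d <- sim_screening_cohort(400, seed = 33)
  # arthritis is independent of the events here; the IRR should be near 1
  res <- univariable_poisson(d$patients, d$events, spec_of("arthritis"))
  expect_gt(res$ci_lo, 0.5)
  expect_lt(res$ci_hi, 2.0)
  py <- person_years(d$patients)
  # fitted marginal rate equals events / person-time (Poisson MLE identity)
  cnt <- as.integer(table(factor(d$events$patient_id,
                                 levels = d$patients$patient_id)))
  fit <- stats::glm(cnt ~ 1 + offset(log(py)), family = stats::poisson())
  expect_equal(exp(unname(coef(fit))), nrow(d$events) / sum(py), tolerance = 1e-6)
})

test_that("symptom duration can be screened per month or per week", {
  d <- sim_screening_cohort(400, seed = 34)
  m <- univariable_logistic(d$patients, d$events,
                            predictor_specs("months")[6, ])
  w <- univariable_logistic(d$patients, d$events,
                            predictor_specs("weeks")[6, ])
  expect_equal(log(m$effect), 4.345 * log(w$effect), tolerance = 1e-6)
})

test_that("complete-case counts track per-predictor missingness", {
  coh <- generate_cohort(cohort_config(n_patients = 300, seed = 35))
  ev <- relapse_events(adjudicate(coh), "TI")
  res <- univariable_logistic(coh$patients, ev, spec_of("hb"))
  expect_equal(res$n_used, sum(!is.na(coh$patients$hb)))
  expect_lt(res$n_used, 300)
})

test_that("degenerate outcomes are refused", {
  coh <- generate_cohort(test_config(50, seed = 36, lambda = 0))
  all_pos <- mk_events(coh$patients$patient_id, 100)
  expect_error(univariable_logistic(coh$patients, all_pos, spec_of("age")),
               class = "pmr_degenerate_error")
  none <- mk_events(character(0), numeric(0))
  expect_error(univariable_logistic(coh$patients, none, spec_of("age")),
               class = "pmr_degenerate_error")
  expect_error(univariable_poisson(coh$patients, none, spec_of("age")),
               class = "pmr_degenerate_error")
})

test_that("the association table covers every predictor contrast by 3 outcomes and flags failures", {
  coh <- generate_cohort(cohort_config(n_patients = 200, seed = 37))
  ev <- relapse_events(adjudicate(coh), "TI")
  tab <- association_table(coh$patients, ev)
  # 11 single-contrast predictors + smoking's 2 contrasts, times 3 outcomes
  expect_identical(nrow(tab), 39L)
  expect_setequal(unique(tab$outcome), c("relapse_0_1y", "relapse_0_2y", "relapse_rate"))
  expect_identical(sum(tab$outcome == "relapse_0_1y"), 13L)
  ok <- is.na(tab$effect) == (tab$note != "")
  expect_true(all(ok))
  expect_identical(tab$significant, !is.na(tab$p) & tab$p < 0.05)
})

test_that("a tiny cohort still yields a table with failure markers rather than an error", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 38))
  ev <- relapse_events(adjudicate(coh), "TI")
  expect_silent(tab <- association_table(coh$patients, ev))
  expect_identical(nrow(tab), 39L)
})
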