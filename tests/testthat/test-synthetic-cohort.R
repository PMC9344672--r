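test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_patients = 40, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth$events, b$truth$events)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$visits, c2$visits))
})

test_that("zero hazard yields no events and a monotone taper", {
  coh <- generate_cohort(test_config(60, seed = 1, lambda = 0))
  expect_identical(nrow(coh$truth$events), 0L)
  expect_false(any(coh$visits$dose_increased_since_prev |
                     coh$visits$dmard_intensified_for_inefficacy |
                     coh$visits$gc_injection_added))
  for (pv in split(coh$visits$pred_dose, coh$visits$patient_id)) {
    expect_true(all(diff(pv) <= 0))
  }
  expect_identical(nrow(relapse_events(adjudicate(coh), "TI")), 0L)
})

test_that("visit doses come from the taper schedule and dates are ordered", {
  cfg <- cohort_config(n_patients = 80, seed = 9)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$visits$pred_dose %in% cfg$taper_schedule))
  expect_true(all(coh$visits$pred_dose >= 0))
  for (pv in split(coh$visits, coh$visits$patient_id)) {
    expect_false(is.unsorted(pv$visit_date, strictly = TRUE))
  }
})

test_that("truth events lie inside follow-up and every TI action traces to a truth event", {
  coh <- generate_cohort(cohort_config(n_patients = 120, seed = 5))
  fup <- setNames(as.numeric(coh$patients$followup_end_date - coh$patients$baseline_date),
                  coh$patients$patient_id)
  expect_true(all(coh$truth$events$event_day >= 0))
  expect_true(all(coh$truth$events$event_day <= fup[coh$truth$events$patient_id]))

  # a visit records a TI action iff a true event fell in its interval
  ev_by_pid <- split(coh$truth$events$event_day, coh$truth$events$patient_id)
  for (pid in unique(coh$visits$patient_id)) {
    pv <- coh$visits[coh$visits$patient_id == pid, ]
    day <- as.numeric(pv$visit_date - coh$patients$baseline_date[coh$patients$patient_id == pid])
    acted <- pv$dose_increased_since_prev | pv$dmard_intensified_for_inefficacy |
      pv$gc_injection_added
    evd <- ev_by_pid[[pid]]
    has_event <- vapply(seq_along(day), function(k) {
      lo <- if (k == 1) -Inf else day[k - 1]
      !is.null(evd) && any(evd > lo & evd <= day[k])
    }, logical(1))
    expect_identical(acted, has_event)
  }
})

test_that("baseline covariate marginals are recovered at n = 2000", {
  cfg <- cohort_config(n_patients = 2000, seed = 7, missing_rates = c())
  coh <- generate_cohort(cfg)
  p <- coh$patients
  n <- nrow(p)
  within_se <- function(x, target, se, k = 4) expect_lt(abs(x - target), k * se)
  within_se(mean(p$age), 66.4, 8.8 / sqrt(n))
  within_se(mean(p$sex == "female"), 0.559, sqrt(0.559 * 0.441 / n))
  within_se(mean(p$cvd_history), 0.141, sqrt(0.141 * 0.859 / n))
  within_se(mean(p$malignancy_history), 0.122, sqrt(0.122 * 0.878 / n))
  within_se(mean(log(p$crp)), log(29), cfg$crp_log_sd / sqrt(n))
  within_se(mean(log(p$esr)), log(37), cfg$esr_log_sd / sqrt(n))
  within_se(mean(p$hb), 8.2, cfg$hb_sd / sqrt(n))
  within_se(mean(p$symptom_duration_weeks), 14, 13.7 / sqrt(n))
  within_se(mean(p$meets_eular_acr_core), 0.79, sqrt(0.79 * 0.21 / n))
  sev_mean <- sum(0:8 * default_severity_probs())
  sev_sd <- sqrt(sum((0:8 - sev_mean)^2 * default_severity_probs()))
  within_se(mean(p$severity_score), sev_mean, sev_sd / sqrt(n))
})

test_that("default cohort of 417 patients matches the reference baseline table", {
  coh <- generate_cohort(cohort_config(n_patients = 417, seed = 1))
  p <- coh$patients
  expect_lt(abs(mean(p$age) - 66.4), 3 * 8.8 / sqrt(417))
  expect_lt(abs(mean(p$sex == "female") - 0.559), 3 * sqrt(0.559 * 0.441 / 417))
})

test_that("missingness injection hits its configured rates", {
  rates <- c(smoking = 0.19, symptom_duration = 0.01, crp = 0.13,
             esr = 0.05, hb = 0.24)
  coh <- generate_cohort(test_config(417, seed = 3))
  base <- coh$patients
  expect_false(anyNA(base$smoking))

  n_seeds <- 200
  hits <- matrix(0, n_seeds, length(rates), dimnames = list(NULL, names(rates)))
  cols <- c(smoking = "smoking", symptom_duration = "symptom_duration_weeks",
            crp = "crp", esr = "esr", hb = "hb")
  for (s in seq_len(n_seeds)) {
    out <- inject_missingness(base, rates, seed = 1000 + s)
    hits[s, ] <- vapply(names(rates), function(nm) mean(is.na(out[[cols[nm]]])),
                        numeric(1))
  }
  for (nm in names(rates)) {
    se <- sqrt(rates[nm] * (1 - rates[nm]) / (417 * n_seeds))
    expect_lt(abs(mean(hits[, nm]) - rates[nm]), 3 * se)
  }
})

test_that("missingness injection respects identity and saturation edges", {
  coh <- generate_cohort(test_config(30, seed = 4))
  expect_identical(inject_missingness(coh$patients, c(hb = 0), seed = 1),
                   coh$patients)
  out <- inject_missingness(coh$patients, c(hb = 1), seed = 1)
  expect_true(all(is.na(out$hb)))
  expect_identical(out$crp, coh$patients$crp)
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients", class = "pmr_config_error")
  expect_error(cohort_config(prop_female = 1.2), "prop_female", class = "pmr_config_error")
  expect_error(cohort_config(taper_schedule = c(10, 10, 5)), "taper_schedule",
               class = "pmr_config_error")
  expect_error(cohort_config(start_dose = 2.5), "start_dose", class = "pmr_config_error")
  expect_error(cohort_config(start_dose = 10), "start_dose", class = "pmr_config_error")
  expect_error(cohort_config(relapse_log_hazard_betas = c(not_a_field = 1)),
               "relapse_log_hazard_betas", class = "pmr_config_error")
  expect_error(cohort_config(missing_rates = c(weight = 0.1)), "missing_rates",
               class = "pmr_config_error")
  expect_error(cohort_config(missing_rates = c(hb = 1.4)), "missing_rates",
               class = "pmr_config_error")
  expect_error(cohort_config(ti_action_probs = c(0.5, 0.2, 0.2)), "ti_action_probs",
               class = "pmr_config_error")
  expect_error(inject_missingness(mk_patient(), c(hb = -0.1)),
               class = "pmr_config_error")
})
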