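test_that("a generated cohort survives a write/read round trip", {
  coh <- generate_cohort(cohort_config(n_patients = 25, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  back <- read_cohort(paths[["patients"]], paths[["visits"]])
  expect_identical(back$patients$patient_id, coh$patients$patient_id)
  expect_identical(back$patients$smoking, coh$patients$smoking)
  expect_identical(back$patients$baseline_date, coh$patients$baseline_date)
  expect_equal(back$patients$crp, coh$patients$crp, tolerance = 1e-9)
  expect_equal(back$patients$hb, coh$patients$hb, tolerance = 1e-9)
  # reader sorts visits by (patient, date); compare on the sorted original
  ord <- order(coh$visits$patient_id, coh$visits$visit_date)
  expect_identical(back$visits$visit_date, coh$visits$visit_date[ord])
  expect_equal(back$visits$pred_dose, coh$visits$pred_dose[ord], tolerance = 1e-9)
  expect_identical(back$visits$gc_injection_added, coh$visits$gc_injection_added[ord])
})

test_that("a header-only visits file reads as an empty visit list", {
  dir <- withr::local_tempdir()
  write_cohort(list(patients = mk_patient(), visits = mk_visits(numeric(0), numeric(0))),
               dir)
  back <- read_cohort(file.path(dir, "patients.csv"), file.path(dir, "visits.csv"))
  expect_identical(nrow(back$visits), 0L)
  expect_identical(nrow(back$patients), 1L)
})

test_that("comma decimals are rejected with the offending line number", {
  dir <- withr::local_tempdir()
  paths <- write_cohort(list(patients = mk_patient(),
                             visits = mk_visits(c(40, 80), c(15, 12.5))), dir)
  txt <- readLines(paths[["visits"]])
  txt[3] <- sub("12.5", "\"12,5\"", txt[3], fixed = TRUE)
  writeLines(txt, paths[["visits"]])
  err <- expect_error(read_cohort(paths[["patients"]], paths[["visits"]]),
                      class = "pmr_parse_error")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "pred_dose")
})

test_that("duplicate and orphan visits are integrity errors", {
  dir <- withr::local_tempdir()
  vis <- mk_visits(c(40, 40), c(15, 12.5))
  write_cohort(list(patients = mk_patient(), visits = vis), dir)
  expect_error(read_cohort(file.path(dir, "patients.csv"), file.path(dir, "visits.csv")),
               "duplicate", class = "pmr_integrity_error")

  vis <- mk_visits(c(40, 80), c(15, 12.5), id = "GHOST")
  write_cohort(list(patients = mk_patient(id = "P1"), visits = vis), dir)
  expect_error(read_cohort(file.path(dir, "patients.csv"), file.path(dir, "visits.csv")),
               "GHOST", class = "pmr_integrity_error")
})

test_that("eligibility boundaries follow the strict day-30 / dose-2.5 / day-90 rules", {
  p <- mk_patient(fup_days = 2000)
  # day 30 exactly is still inside the initial-response period
  d <- filter_eligible_visits(p, mk_visits(c(30, 31), c(10, 10)))
  expect_identical(d$reason, c("too_early", "ok"))
  # dose 2.5 exactly is excluded, 2.6 is not
  d <- filter_eligible_visits(p, mk_visits(c(60, 90), c(2.5, 2.6)))
  expect_identical(d$reason, c("dose_at_or_below_2_5", "ok"))
  # treatment ends at the first terminal zero-dose visit; +90 days inclusive
  d <- filter_eligible_visits(p, mk_visits(c(40, 100, 190, 191), c(10, 0, 0, 0)))
  expect_identical(d$reason, c("ok", "dose_at_or_below_2_5",
                               "dose_at_or_below_2_5", "post_treatment_window"))
  # a later positive dose reopens treatment: the zero at day 100 is not terminal
  d <- filter_eligible_visits(p, mk_visits(c(40, 100, 150, 300, 500), c(10, 0, 10, 0, 0)))
  expect_identical(d$reason, c("ok", "dose_at_or_below_2_5", "ok",
                               "dose_at_or_below_2_5", "post_treatment_window"))
  expect_identical(d$eligible, d$reason == "ok")
})

test_that("visits after follow-up end are excluded with their own reason", {
  p <- mk_patient(fup_days = 100)
  d <- filter_eligible_visits(p, mk_visits(c(40, 99, 101), c(10, 10, 10)))
  expect_identical(d$reason, c("ok", "ok", "after_followup_end"))
})

test_that("eligibility is idempotent and locally stable when dropping ineligible visits", {
  p <- mk_patient(fup_days = 2000)
  v <- mk_visits(c(10, 40, 60, 100, 400, 500), c(15, 12.5, 2.5, 10, 0, 0))
  d1 <- filter_eligible_visits(p, v)
  expect_identical(filter_eligible_visits(p, v), d1)
  # dropping the too-early visit changes nothing for the rest
  keep <- d1$reason != "too_early"
  d2 <- filter_eligible_visits(p, v[keep, ])
  expect_identical(d2$reason, d1$reason[keep])
  # dropping the terminal zero-dose visit moves treatment end and can
  # re-include later visits
  v3 <- v[v$pred_dose > 0, ]
  d3 <- filter_eligible_visits(p, v3)
  expect_identical(d3$reason, c("too_early", "ok", "dose_at_or_below_2_5", "ok"))
})

test_that("contract violations are rejected", {
  p <- mk_patient()
  v <- mk_visits(c(80, 40), c(10, 12.5))
  expect_error(filter_eligible_visits(p, v), class = "pmr_contract_error")
  v2 <- mk_visits(c(40, 80), c(12.5, 10), id = "OTHER")
  expect_error(filter_eligible_visits(p, v2), class = "pmr_contract_error")
})
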