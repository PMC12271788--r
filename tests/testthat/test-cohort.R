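test_that("index dates add the offset in calendar days, including leap years", {
  expect_equal(derive_index_date(as.Date("2018-03-01"), 90),
               as.Date("2018-05-30"))
  expect_equal(derive_index_date(as.Date("2021-07-04"), 0),
               as.Date("2021-07-04"))
  # crosses 29 Feb 2020
  expect_equal(derive_index_date(as.Date("2019-12-15"), 90),
               as.Date("2020-03-14"))
  # same span one year earlier, no leap day
  expect_equal(derive_index_date(as.Date("2018-12-15"), 90),
               as.Date("2019-03-15"))
  expect_error(derive_index_date(as.Date("2018-01-01"), -1))
})

test_that("each exclusion rule fires with its recorded reason", {
  idx <- as.Date("2018-04-01") # index note date; index date +90 = 2018-06-30
  candidates <- tibble::tibble(
    patient_id = c("ok", "dead", "olt", "tx", "nosex", "young", "late_tx"),
    index_note_date = idx
  )
  reg <- make_registry(
    patients = dplyr::bind_rows(
      basic_patient("ok"),
      basic_patient("dead", death_date = as.Date("2018-06-20")),
      basic_patient("olt"),
      basic_patient("tx"),
      basic_patient("nosex", sex = NA_character_),
      basic_patient("young", birth_date = as.Date("2005-01-01")),
      basic_patient("late_tx")
    ),
    procedures = tibble::tibble(
      patient_id = c("olt", "tx", "late_tx"),
      code = "47135",
      date = as.Date(c("2017-01-01",  # before the index note -> post-OLT dx
                       "2018-05-15",  # between note and index date
                       "2020-06-30")) # 2 years after index -> included
    )
  )
  cohort <- apply_exclusions(candidates, reg)
  reasons <- stats::setNames(cohort$exclusion_reason, cohort$patient_id)
  expect_true(cohort$included[cohort$patient_id == "ok"])
  expect_true(cohort$included[cohort$patient_id == "late_tx"])
  expect_equal(unname(reasons["dead"]), "death_before_index")
  expect_equal(unname(reasons["olt"]), "mash_after_olt")
  expect_equal(unname(reasons["tx"]), "transplant_before_index")
  expect_equal(unname(reasons["nosex"]), "missing_age_or_sex")
  expect_equal(unname(reasons["young"]), "age_under_18")
  # partition: every candidate exactly once, reasons only on excluded rows
  expect_equal(sort(cohort$patient_id), sort(candidates$patient_id))
  expect_identical(is.na(cohort$exclusion_reason), cohort$included)
})

test_that("subcohort assignment uses an inclusive baseline boundary", {
  idx <- as.Date("2018-04-01")
  candidates <- tibble::tibble(patient_id = c("on_index", "later", "none"),
                               index_note_date = idx)
  reg <- make_registry(
    patients = dplyr::bind_rows(basic_patient("on_index"),
                                basic_patient("later"),
                                basic_patient("none")),
    coded_events = tibble::tibble(
      patient_id = c("on_index", "later"), code_system = "ICD",
      code = "K74.60",
      date = c(derive_index_date(idx), derive_index_date(idx) + 1)
    )
  )
  cohort <- assign_subcohort(apply_exclusions(candidates, reg), reg)
  sub <- stats::setNames(cohort$subcohort, cohort$patient_id)
  expect_equal(unname(sub["on_index"]), "cirrhosis") # boundary inclusive
  expect_equal(unname(sub["later"]), "no_cirrhosis")
  expect_equal(unname(sub["none"]), "no_cirrhosis")
  # subcohorts partition the included cohort
  expect_false(any(is.na(cohort$subcohort[cohort$included])))
})

test_that("BMI categories use Asian-specific cut-points", {
  expect_equal(bmi_category(27.5, asian = TRUE), "obese")
  expect_equal(bmi_category(27.5, asian = FALSE), "overweight")
  expect_equal(bmi_category(18.4, asian = TRUE), "underweight")
  expect_equal(bmi_category(18.4, asian = FALSE), "underweight")
  expect_equal(bmi_category(c(23, 23), c(TRUE, FALSE)),
               c("overweight", "normal"))
  expect_equal(bmi_category(c(30, 29.9), c(FALSE, FALSE)),
               c("obese", "overweight"))
  expect_equal(bmi_category(NA_real_, TRUE), "missing")
  expect_error(bmi_category(-1, TRUE), "positive")
})

test_that("MELD 3.0 matches the published definition and clamps inputs", {
  # all log and interaction terms vanish: constant only
  expect_equal(meld3("male", 1.0, 137, 1.0, 1.0, 3.5), 6)
  # female additive term
  expect_equal(meld3("female", 1.0, 137, 1.0, 1.0, 3.5), 6 + 1.33)
  # sodium below range is clamped to 125
  expect_equal(meld3("male", 1.0, 120, 1.0, 1.0, 3.5),
               meld3("male", 1.0, 125, 1.0, 1.0, 3.5))
  # creatinine capped at 3.0, floors at 1.0
  expect_equal(meld3("male", 1.0, 137, 1.0, 5.0, 3.5),
               meld3("male", 1.0, 137, 1.0, 3.0, 3.5))
  expect_equal(meld3("male", 0.4, 137, 0.9, 0.5, 3.5), 6)
  # hand-evaluated non-trivial case
  expect_equal(
    meld3("female", 2.0, 130, 1.5, 1.2, 3.0),
    round(1.33 + 4.56 * log(2) + 0.82 * 7 - 0.24 * 7 * log(2) +
            9.09 * log(1.5) + 11.14 * log(1.2) + 1.85 * 0.5 -
            1.83 * 0.5 * log(1.2) + 6, 2)
  )
  expect_true(is.na(meld3("male", NA, 137, 1, 1, 3.5)))
  expect_error(meld3("male", -1, 137, 1, 1, 3.5), "positive")
})

make_tte_fixture <- function() {
  candidates <- tibble::tibble(
    patient_id = c("dies", "quiet", "tx_then_dies", "prior_outcome"),
    index_note_date = as.Date("2017-10-03") # index date = 2018-01-01
  )
  reg <- make_registry(
    patients = dplyr::bind_rows(
      basic_patient("dies", death_date = as.Date("2018-12-31")),
      basic_patient("quiet"),
      basic_patient("tx_then_dies", death_date = as.Date("2019-06-01")),
      basic_patient("prior_outcome")
    ),
    coded_events = tibble::tibble(
      # all four carry baseline cirrhosis so the transplant outcome applies
      patient_id = c("dies", "quiet", "tx_then_dies", "prior_outcome"),
      code_system = "ICD", code = "K74.60", date = as.Date("2015-01-01")
    ),
    procedures = tibble::tibble(
      patient_id = c("tx_then_dies", "prior_outcome"), code = "47135",
      date = as.Date(c("2020-03-01", "2017-12-15"))
    )
  )
  cohort <- assign_subcohort(apply_exclusions(candidates, reg), reg)
  list(cohort = cohort, reg = reg)
}

test_that("time-to-event rows code events, admin censoring and competing risks", {
  fx <- make_tte_fixture()
  mort <- build_tte(fx$cohort, fx$reg, "all_cause_mortality",
                    follow_up_end = as.Date("2023-12-31"))
  rows <- stats::setNames(split(mort, mort$patient_id), NULL)
  m <- mort[mort$patient_id == "dies", ]
  expect_equal(m$status, "event")
  expect_equal(m$time_days, 364L)
  q <- mort[mort$patient_id == "quiet", ]
  expect_equal(q$status, "censored_admin")
  expect_equal(q$time_days, as.integer(as.Date("2023-12-31") -
                                         as.Date("2018-01-01")))

  tx <- build_tte(fx$cohort, fx$reg, "liver_transplant",
                  follow_up_end = as.Date("2023-12-31"))
  # transplant precedes death -> event; death competing only if earlier
  t1 <- tx[tx$patient_id == "tx_then_dies", ]
  expect_equal(t1$status, "censored_competing") # death 2019-06 < tx 2020-03
  expect_equal(t1$time_days,
               as.integer(as.Date("2019-06-01") - as.Date("2018-01-01")))
  # outcome before index -> out of the risk set entirely
  expect_false("prior_outcome" %in% tx$patient_id)
  # mortality has no competing events
  expect_true(all(mort$status != "censored_competing"))
})

test_that("the guard-window reading keeps outcomes shortly after competing events", {
  candidates <- tibble::tibble(patient_id = "p", index_note_date = as.Date("2017-10-03"))
  reg <- make_registry(
    patients = basic_patient("p", death_date = as.Date("2019-01-10")),
    coded_events = tibble::tibble(patient_id = "p", code_system = "ICD",
                                  code = "K74.60",
                                  date = as.Date("2015-01-01")),
    procedures = tibble::tibble(patient_id = "p", code = "47135",
                                date = as.Date("2019-02-01"))
  )
  cohort <- assign_subcohort(apply_exclusions(candidates, reg), reg)
  strict <- build_tte(cohort, reg, "liver_transplant", strict = TRUE)
  expect_equal(strict$status, "censored_competing")
  # transplant 22 days after death is inside the 90-day guard: still an event
  # under the literal "more than 3 months before" reading
  loose <- build_tte(cohort, reg, "liver_transplant", strict = FALSE,
                     guard_days = 90)
  expect_equal(loose$status, "event")
})

test_that("outcome/subcohort mismatches are errors", {
  fx <- make_tte_fixture()
  expect_error(build_tte(fx$cohort, fx$reg, "incident_cirrhosis"),
               "no-cirrhosis")
  no_sub <- fx$cohort[, setdiff(names(fx$cohort), "subcohort")]
  expect_error(build_tte(no_sub, fx$reg, "liver_transplant"), "subcohort")
})

test_that("incidence arithmetic and internal consistency", {
  expect_equal(incidence_rate(0, 123.4), 0)
  expect_error(incidence_rate(5, 0), "positive")
  expect_error(incidence_rate(-1, 10), "non-negative")

  fx <- make_tte_fixture()
  mort <- build_tte(fx$cohort, fx$reg, "all_cause_mortality")
  s <- incidence_summary(mort)
  expect_identical(
    s$rate_per_100py,
    100 * sum(mort$status == "event") / (sum(mort$time_days) / 365.25)
  )
  expect_equal(s$person_years, person_years(mort))
  # TTE sanity bounds
  horizon <- as.integer(as.Date("2023-12-31") - as.Date("2018-01-01"))
  expect_true(all(mort$time_days >= 0 & mort$time_days <= horizon))
})

test_that("baseline covariates pick the latest pre-index labs", {
  candidates <- tibble::tibble(patient_id = "p",
                               index_note_date = as.Date("2018-04-01"))
  idx <- derive_index_date(candidates$index_note_date)
  labs <- dplyr::bind_rows(
    tibble::tibble(patient_id = "p", name = "bilirubin", value = 4,
                   date = idx - 400),          # superseded
    tibble::tibble(patient_id = "p", name = "bilirubin", value = 1,
                   date = idx - 10),           # latest pre-index
    tibble::tibble(patient_id = "p", name = "bilirubin", value = 9,
                   date = idx + 5),            # post-index, ignored
    tibble::tibble(patient_id = "p",
                   name = c("sodium", "inr", "creatinine", "albumin"),
                   value = c(137, 1, 1, 3.5), date = idx - 10)
  )
  reg <- make_registry(patients = basic_patient("p", sex = "male"),
                       labs = labs)
  cohort <- baseline_covariates(apply_exclusions(candidates, reg), reg)
  expect_equal(cohort$meld3, 6) # all-normal labs -> intercept only
  expect_equal(cohort$bmi_cat, "obese")
})

test_that("code lists match exact codes and prefix wildcards", {
  expect_equal(code_matches(c("K74.60", "K74.69", "K74.3", "K70.9"),
                            c("K74.6*", "K74.3")),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(code_matches("k74.60", "K74.6*")) # case-insensitive
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cirrhosis", "K74.6*", "", "571.5  # legacy"), path)
  expect_equal(read_code_list(path), c("K74.6*", "571.5"))
})
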