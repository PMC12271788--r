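#' Derive the cohort index date from the index note date
#'
#' The cohort entry date is the earliest MASH-positive note date plus an
#' offset (default 90 days) that allows for delayed recording of the
#' diagnosis in clinical notes.
#'
#' @param index_note_date `Date` (vectorized).
#' @param offset_days Non-negative integer, default 90.
#' @return `Date` vector.
#' @export
derive_index_date <- function(index_note_date, offset_days = 90L) {
  stopifnot(offset_days >= 0)
  as.Date(index_note_date) + as.integer(offset_days)
}

# whole-year floor age
age_years <- function(birth_date, at_date) {
  by <- as.integer(format(birth_date, "%Y"))
  ay <- as.integer(format(at_date, "%Y"))
  before_birthday <- format(at_date, "%m%d") < format(birth_date, "%m%d")
  ay - by - as.integer(before_birthday)
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Candidates (NLP-flagged patients with an index note date) are excluded,
#' with a recorded reason, when: the death date precedes the index date
#' (`death_before_index`); the earliest MASH-positive note follows a liver
#' transplant, i.e. a transplant procedure precedes the index *note* date
#' (`mash_after_olt` — patients diagnosed after orthotopic transplantation
#' are clinically distinct); any transplant precedes the index date
#' (`transplant_before_index`); age or sex is missing
#' (`missing_age_or_sex`); or age at index is under 18 (`age_under_18`,
#' adult-notes corpus). The first matching reason in that order is
#' recorded; every candidate appears exactly once, included or excluded.
#'
#' @param candidates Tibble with `patient_id` and `index_note_date`
#'   (e.g. the case rows of [classify_patients()]).
#' @param registry Registry list as from [gen_registry()] or
#'   [read_registry()]: `patients`, `coded_events`, `procedures`, `labs`.
#' @param offset_days Index offset, default 90.
#' @param transplant_codes Procedure code patterns, default CPT 47135.
#' @return Cohort tibble: `patient_id`, `index_note_date`, `index_date`,
#'   `sex`, `age_at_index`, `included`, `exclusion_reason` (`NA` when
#'   included).
#' @export
apply_exclusions <- function(candidates, registry, offset_days = 90L,
                             transplant_codes = default_transplant_codes()) {
  stopifnot(all(c("patient_id", "index_note_date") %in% names(candidates)))
  pts <- registry$patients
  df <- dplyr::left_join(
    candidates[, c("patient_id", "index_note_date")],
    pts, by = "patient_id"
  )
  df$index_date <- derive_index_date(df$index_note_date, offset_days)

  for (col in c("sex", "birth_date", "death_date")) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "sex") NA_character_ else as.Date(NA)
    }
  }

  procs <- registry$procedures
  tx <- procs[code_matches(procs$code, transplant_codes), , drop = FALSE]
  df$first_transplant <- as.Date(rep(NA, nrow(df)))
  if (nrow(tx) > 0) {
    agg <- tx |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first = min(.data$date), .groups = "drop")
    agg <- agg[agg$patient_id %in% df$patient_id, , drop = FALSE]
    df$first_transplant[match(agg$patient_id, df$patient_id)] <- agg$first
  }

  sex_missing <- is.na(df$sex) | df$sex == "missing"
  if ("age_at_first_note" %in% names(df)) {
    # age carried forward unadjusted when only age-at-first-note is known
    age <- ifelse(!is.na(df$birth_date),
                  age_years(df$birth_date, df$index_date),
                  df$age_at_first_note)
  } else {
    age <- age_years(df$birth_date, df$index_date)
  }
  age_missing <- is.na(age)

  reason <- rep(NA_character_, nrow(df))
  cond <- function(x) !is.na(x) & x
  hit <- function(new, r) ifelse(is.na(reason) & cond(new), r, reason)
  reason <- hit(df$death_date < df$index_date, "death_before_index")
  reason <- hit(df$first_transplant < df$index_note_date, "mash_after_olt")
  reason <- hit(df$first_transplant < df$index_date, "transplant_before_index")
  reason <- hit(sex_missing | age_missing, "missing_age_or_sex")
  reason <- hit(age < 18, "age_under_18")

  tibble::tibble(
    patient_id = df$patient_id,
    index_note_date = df$index_note_date,
    index_date = df$index_date,
    sex = df$sex,
    age_at_index = as.integer(age),
    included = is.na(reason),
    exclusion_reason = reason
  )
}

#' Split the cohort into baseline cirrhosis / no-cirrhosis subcohorts
#'
#' A patient is in the cirrhosis subcohort when any coded cirrhosis event is
#' dated on or before the index date (the baseline boundary is inclusive);
#' a `decompensated` flag is set analogously from the decompensation list.
#' Excluded rows get `NA` subcohort.
#'
#' @param cohort Cohort tibble from [apply_exclusions()].
#' @param registry Registry list.
#' @param cirrhosis_codes,decompensation_codes ICD code pattern lists.
#' @return `cohort` with `subcohort` (`"cirrhosis"`/`"no_cirrhosis"`) and
#'   `decompensated` columns added.
#' @export
assign_subcohort <- function(cohort, registry,
                             cirrhosis_codes = default_cirrhosis_codes(),
                             decompensation_codes = default_decompensation_codes()) {
  stopifnot(length(cirrhosis_codes) > 0)
  ev <- registry$coded_events
  baseline_flag <- function(patterns) {
    sel <- ev[code_matches(ev$code, patterns), , drop = FALSE]
    if (nrow(sel) == 0) {
      return(rep(FALSE, nrow(cohort)))
    }
    joined <- dplyr::inner_join(
      sel, cohort[, c("patient_id", "index_date")], by = "patient_id"
    )
    joined <- joined[joined$date <= joined$index_date, , drop = FALSE]
    cohort$patient_id %in% joined$patient_id
  }
  cirr <- baseline_flag(cirrhosis_codes)
  dec <- baseline_flag(decompensation_codes)
  cohort$subcohort <- ifelse(cohort$included,
                             ifelse(cirr, "cirrhosis", "no_cirrhosis"),
                             NA_character_)
  cohort$decompensated <- ifelse(cohort$included, dec, NA)
  cohort
}

#' BMI category with Asian-specific cut-points
#'
#' Asian cut-points: underweight < 18.5, normal 18.5–22.9, overweight
#' 23–27.4, obese >= 27.5. Non-Asian: underweight < 18.5, normal
#' 18.5–24.9, overweight 25–29.9, obese >= 30. Missing BMI returns
#' `"missing"`.
#'
#' @param bmi Numeric, kg/m^2 (vectorized); must be positive or `NA`.
#' @param asian Logical flag (vectorized).
#' @return Character vector in
#'   `{"underweight","normal","overweight","obese","missing"}`.
#' @export
bmi_category <- function(bmi, asian) {
  if (any(!is.na(bmi) & bmi <= 0)) {
    stop("bmi must be positive", call. = FALSE)
  }
  n <- max(length(bmi), length(asian))
  bmi <- rep_len(bmi, n)
  asian <- rep_len(as.logical(asian), n)
  lower <- ifelse(asian, 23, 25)
  upper <- ifelse(asian, 27.5, 30)
  out <- rep("missing", n)
  ok <- !is.na(bmi)
  out[ok & bmi < 18.5] <- "underweight"
  out[ok & bmi >= 18.5 & bmi < lower] <- "normal"
  out[ok & bmi >= lower & bmi < upper] <- "overweight"
  out[ok & bmi >= upper] <- "obese"
  out
}

#' MELD 3.0 score
#'
#' The published MELD 3.0 score (Kim et al. 2021): female sex term plus
#' log-linear terms in bilirubin, sodium, INR, creatinine and albumin with
#' two interactions and a constant of 6. Inputs are clamped per the
#' published definition: bilirubin/INR/creatinine floored at 1.0,
#' creatinine capped at 3.0, sodium clamped to \[125, 137\] mEq/L, albumin
#' clamped to \[1.5, 3.5\] g/dL. Any missing input gives a missing score
#' (imputation is out of scope).
#'
#' @param sex `"female"`/`"male"` (vectorized).
#' @param bilirubin mg/dL. @param sodium mEq/L. @param inr INR ratio.
#' @param creatinine mg/dL. @param albumin g/dL.
#' @param digits Rounding of the returned score, default 2.
#' @return Numeric score (dimensionless), `NA` where any input is missing.
#' @export
meld3 <- function(sex, bilirubin, sodium, inr, creatinine, albumin,
                  digits = 2) {
  vals <- list(bilirubin = bilirubin, sodium = sodium, inr = inr,
               creatinine = creatinine, albumin = albumin)
  for (nm in names(vals)) {
    if (any(!is.na(vals[[nm]]) & vals[[nm]] <= 0)) {
      stop(nm, " must be positive", call. = FALSE)
    }
  }
  female <- as.numeric(sex == "female")
  bili <- pmax(bilirubin, 1)
  cr <- pmin(pmax(creatinine, 1), 3)
  inr <- pmax(inr, 1)
  na_ <- pmin(pmax(sodium, 125), 137)
  alb <- pmin(pmax(albumin, 1.5), 3.5)
  score <- 1.33 * female +
    4.56 * log(bili) +
    0.82 * (137 - na_) -
    0.24 * (137 - na_) * log(bili) +
    9.09 * log(inr) +
    11.14 * log(cr) +
    1.85 * (3.5 - alb) -
    1.83 * (3.5 - alb) * log(cr) +
    6
  round(score, digits)
}

#' Attach baseline covariates to a cohort
#'
#' Adds the BMI category and the MELD 3.0 score computed from each
#' patient's latest lab values dated on or before the index date (lab
#' names: `bilirubin`, `sodium`, `inr`, `creatinine`, `albumin`).
#'
#' @param cohort Cohort tibble (after [apply_exclusions()]).
#' @param registry Registry list.
#' @return `cohort` with `bmi`, `bmi_cat` and `meld3` columns.
#' @export
baseline_covariates <- function(cohort, registry) {
  pts <- registry$patients
  cohort <- dplyr::left_join(
    cohort, pts[, intersect(c("patient_id", "asian", "bmi"), names(pts))],
    by = "patient_id"
  )
  cohort$bmi_cat <- bmi_category(cohort$bmi, cohort$asian)

  labs <- registry$labs
  lab_at_baseline <- function(name) {
    sel <- labs[labs$name == name, , drop = FALSE]
    out <- rep(NA_real_, nrow(cohort))
    if (nrow(sel) == 0) return(out)
    joined <- dplyr::inner_join(sel,
                                cohort[, c("patient_id", "index_date")],
                                by = "patient_id")
    joined <- joined[joined$date <= joined$index_date, , drop = FALSE]
    if (nrow(joined) == 0) return(out)
    latest <- joined |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_max(.data$date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    out[match(latest$patient_id, cohort$patient_id)] <- latest$value
    out
  }
  cohort$meld3 <- meld3(
    cohort$sex,
    bilirubin = lab_at_baseline("bilirubin"),
    sodium = lab_at_baseline("sodium"),
    inr = lab_at_baseline("inr"),
    creatinine = lab_at_baseline("creatinine"),
    albumin = lab_at_baseline("albumin")
  )
  cohort
}

#' Build a time-to-event table for one outcome
#'
#' Follow-up runs from the index date to `follow_up_end`. Per patient:
#' excluded from the risk set when the outcome date is on or before the
#' index date (delayed-coding rule); `status = "event"` with
#' `time_days = outcome - index` when the outcome occurs in
#' `(index, follow_up_end]` and no competing event precedes it;
#' `status = "censored_competing"` at the earliest competing-event date
#' otherwise when one occurs in follow-up; else `status = "censored_admin"`
#' at `follow_up_end`. Death is always a competing event for non-mortality
#' outcomes. Outcomes: `all_cause_mortality` on the full cohort,
#' `incident_cirrhosis` (first cirrhosis code after index) on the
#' no-cirrhosis subcohort, `liver_transplant` (first CPT 47135 after index)
#' on the cirrhosis subcohort; a subcohort mismatch is an error.
#'
#' The competing-risk clause supports two readings. Strict (default): any
#' competing event strictly before the outcome censors it. Guard-window
#' (`strict = FALSE`): the outcome is only censored when the competing
#' event precedes it by more than `guard_days` (default 90, i.e. the
#' "3 months before" reading); outcomes recorded within the guard after a
#' competing event still count as events in that mode.
#'
#' @param cohort Cohort tibble with `subcohort` (from [assign_subcohort()]).
#' @param registry Registry list.
#' @param outcome One of `"all_cause_mortality"`, `"incident_cirrhosis"`,
#'   `"liver_transplant"`.
#' @param follow_up_end Administrative censoring date, default 2023-12-31.
#' @param cirrhosis_codes,transplant_codes Code pattern lists.
#' @param guard_days Guard window in days for the non-strict reading.
#' @param strict Use the strict competing-event reading (default `TRUE`).
#' @return Tibble: `patient_id`, `outcome`, `time_days`, `status`.
#' @export
build_tte <- function(cohort, registry,
                      outcome = c("all_cause_mortality", "incident_cirrhosis",
                                  "liver_transplant"),
                      follow_up_end = as.Date("2023-12-31"),
                      cirrhosis_codes = default_cirrhosis_codes(),
                      transplant_codes = default_transplant_codes(),
                      guard_days = 90L, strict = TRUE) {
  outcome <- match.arg(outcome)
  entries <- cohort[cohort$included, , drop = FALSE]
  if (outcome != "all_cause_mortality" && !"subcohort" %in% names(entries)) {
    stop("cohort must carry subcohort assignments for outcome ", outcome,
         call. = FALSE)
  }
  if (outcome == "incident_cirrhosis" &&
      any(entries$subcohort != "no_cirrhosis")) {
    stop("incident_cirrhosis is studied in the no-cirrhosis subcohort only",
         call. = FALSE)
  }
  if (outcome == "liver_transplant" &&
      any(entries$subcohort != "cirrhosis")) {
    stop("liver_transplant is studied in the cirrhosis subcohort only",
         call. = FALSE)
  }
  follow_up_end <- as.Date(follow_up_end)
  if (any(entries$index_date > follow_up_end)) {
    stop("index_date after follow_up_end", call. = FALSE)
  }

  first_after_index <- function(events, patterns) {
    sel <- events[code_matches(events$code, patterns), , drop = FALSE]
    out <- rep(as.Date(NA), nrow(entries))
    if (nrow(sel) == 0) return(out)
    joined <- dplyr::inner_join(sel,
                                entries[, c("patient_id", "index_date")],
                                by = "patient_id")
    joined <- joined[joined$date > joined$index_date, , drop = FALSE]
    if (nrow(joined) == 0) return(out)
    agg <- joined |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first = min(.data$date), .groups = "drop")
    out[match(agg$patient_id, entries$patient_id)] <- agg$first
    out
  }

  pts <- registry$patients
  death <- pts$death_date[match(entries$patient_id, pts$patient_id)]
  cirr_date <- first_after_index(registry$coded_events, cirrhosis_codes)
  tx_date <- first_after_index(registry$procedures, transplant_codes)

  if (outcome == "all_cause_mortality") {
    out_date <- death
    competing <- rep(as.Date(NA), nrow(entries))
  } else if (outcome == "incident_cirrhosis") {
    out_date <- cirr_date
    competing <- pmin(death, tx_date, na.rm = TRUE)
  } else {
    out_date <- tx_date
    competing <- death
  }

  # risk-set exclusion: outcome recorded on/before index
  at_risk <- is.na(out_date) | out_date > entries$index_date
  entries <- entries[at_risk, , drop = FALSE]
  out_date <- out_date[at_risk]
  competing <- competing[at_risk]

  in_fu <- function(d) !is.na(d) & d <= follow_up_end
  out_in <- in_fu(out_date)
  comp_in <- in_fu(competing)

  precedes <- if (strict) {
    comp_in & out_in & competing < out_date
  } else {
    comp_in & out_in & competing < (out_date - as.integer(guard_days))
  }
  is_event <- out_in & !precedes
  is_comp <- !is_event & comp_in

  end_date <- rep(follow_up_end, nrow(entries))
  status <- rep("censored_admin", nrow(entries))
  end_date[is_comp] <- competing[is_comp]
  status[is_comp] <- "censored_competing"
  end_date[is_event] <- out_date[is_event]
  status[is_event] <- "event"

  tibble::tibble(
    patient_id = entries$patient_id,
    outcome = outcome,
    time_days = as.integer(end_date - entries$index_date),
    status = status
  )
}

#' Incidence rate per 100 person-years
#'
#' @param n_events Non-negative event count.
#' @param person_years Total person-years at risk (> 0).
#' @return Rate per 100 person-years: `100 * n_events / person_years`.
#' @export
incidence_rate <- function(n_events, person_years) {
  if (any(person_years <= 0)) {
    stop("person_years must be positive", call. = FALSE)
  }
  if (any(n_events < 0)) {
    stop("n_events must be non-negative", call. = FALSE)
  }
  100 * n_events / person_years
}

#' Person-years of a time-to-event table
#'
#' Uses the 365.25 days/year convention.
#' @param tte Tibble from [build_tte()].
#' @return Total person-years.
#' @export
person_years <- function(tte) {
  sum(tte$time_days) / 365.25
}

#' Summarize a time-to-event table
#'
#' @param tte Tibble from [build_tte()] (one outcome or several stacked).
#' @return Tibble per outcome: `n_at_risk`, `n_events`, `person_years`,
#'   `rate_per_100py`.
#' @export
incidence_summary <- function(tte) {
  tte |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(
      n_at_risk = dplyr::n(),
      n_events = sum(.data$status == "event"),
      person_years = sum(.data$time_days) / 365.25,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate_per_100py = incidence_rate(.data$n_events, .data$person_years)
    )
}
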