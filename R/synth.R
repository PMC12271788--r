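#' Configuration for the synthetic note and registry generator
#'
#' Defaults mirror the study conditions the generator emulates: a
#' 2012–2022 specialist-note corpus, a 90-day index offset, follow-up
#' through 2023-12-31, event hazards equal to the reported incidence rates
#' (death 0.044, incident cirrhosis 0.045, liver transplant 0.031 events
#' per person-year) and a 55.4% baseline-cirrhosis fraction. Quantities the
#' study does not report (notes per patient, case prevalence among clinic
#' patients, negated-mention and header-less note rates) are fixed
#' realistic choices, documented in the methods vignette.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(min, max)`; per-patient counts
#'   are uniform on it.
#' @param case_prevalence Probability a patient is a true MASH case.
#' @param negated_mention_rate Probability a non-positive note carries a
#'   negated keyword mention (rather than no mention).
#' @param headerless_note_rate Probability a note lacks section headers.
#' @param date_range `Date` pair bounding note dates.
#' @param hazards Named list of event hazards (events/person-year):
#'   `death`, `cirrhosis`, `transplant`.
#' @param baseline_cirrhosis_fraction Probability a cohort patient carries
#'   a baseline cirrhosis code.
#' @param quotas Optional exact planted counts: `n_excluded` (patients
#'   given a death/transplant-before-index or missing age/sex condition),
#'   `n_baseline_cirrhosis`.
#' @param index_offset_days Index offset used when planting pre/post-index
#'   events (default 90).
#' @param follow_up_end Administrative end of follow-up.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 200L,
                         notes_per_patient = c(1L, 4L),
                         case_prevalence = 0.3,
                         negated_mention_rate = 0.3,
                         headerless_note_rate = 0.1,
                         date_range = as.Date(c("2012-01-01", "2022-12-31")),
                         hazards = list(death = 0.044, cirrhosis = 0.045,
                                        transplant = 0.031),
                         baseline_cirrhosis_fraction = 0.554,
                         quotas = list(),
                         index_offset_days = 90L,
                         follow_up_end = as.Date("2023-12-31"),
                         seed = 1L) {
  probs <- c(case_prevalence, negated_mention_rate, headerless_note_rate,
             baseline_cirrhosis_fraction)
  stopifnot(
    n_patients >= 1,
    length(notes_per_patient) == 2, notes_per_patient[1] >= 1,
    notes_per_patient[1] <= notes_per_patient[2],
    all(probs >= 0 & probs <= 1),
    date_range[1] <= date_range[2],
    all(unlist(hazards) >= 0)
  )
  if (!is.null(quotas$n_excluded) && quotas$n_excluded > n_patients) {
    stop("exclusion quota exceeds n_patients", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      notes_per_patient = as.integer(notes_per_patient),
      case_prevalence = case_prevalence,
      negated_mention_rate = negated_mention_rate,
      headerless_note_rate = headerless_note_rate,
      date_range = as.Date(date_range),
      hazards = hazards,
      baseline_cirrhosis_fraction = baseline_cirrhosis_fraction,
      quotas = quotas,
      index_offset_days = as.integer(index_offset_days),
      follow_up_end = as.Date(follow_up_end),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Template sentences. These deliberately use only phenomena the rule model
# covers (same-sentence triggers, standard headers) so planted gold labels
# are exactly recoverable; adversarial_templates() below exercises known
# failure modes and is kept out of any acceptance property.
synth_templates <- function() {
  list(
    positive = c(
      "NASH cirrhosis, continue current management.",
      "Biopsy consistent with nonalcoholic steatohepatitis.",
      "MASH with stage 2 fibrosis on recent elastography.",
      "Metabolic dysfunction-associated steatohepatitis, clinically stable.",
      "Steatohepatitis confirmed on liver biopsy."
    ),
    negated = c(
      "No evidence of NASH on biopsy.",
      "Negative for steatohepatitis on histology.",
      "MASH ruled out by imaging.",
      "Denies prior diagnosis of NASH.",
      "Not consistent with nonalcoholic steatohepatitis."
    ),
    control = c(
      "Hypertension, continue lisinopril 10 mg daily.",
      "Type 2 diabetes, A1c improving on metformin.",
      "GERD, continue omeprazole.",
      "Chronic hepatitis B, undetectable viral load.",
      "Obesity, counseled on dietary changes and weight loss."
    ),
    hpi = c(
      "Patient returns for routine follow-up of chronic liver disease.",
      "Patient seen in clinic for ongoing hepatology care.",
      "Doing well overall with stable weight and good adherence."
    )
  )
}

#' Adversarial note templates outside the rule model
#'
#' Notes whose correct reading requires phenomena the detector does not
#' model (cross-sentence negation, mentions confined to non-A&P sections).
#' Useful for probing failure modes; never part of gold-recovery
#' properties.
#'
#' @return Tibble with `text` and the `intended` human reading.
#' @export
adversarial_templates <- function() {
  tibble::tibble(
    text = c(
      "HPI: Known NASH cirrhosis.\n\nAssessment and Plan:\nFollow up imaging.",
      paste0("Assessment and Plan:\nWe discussed NASH. This diagnosis was ",
             "excluded after review."),
      "Assessment and Plan:\nFamily history of NASH in mother."
    ),
    intended = c("negative", "negative", "negative")
  )
}

#' Generate a synthetic note corpus with gold labels
#'
#' Each case patient gets at least one note whose Assessment & Plan
#' contains an affirmed keyword sentence; other notes carry a negated
#' mention at `negated_mention_rate` or no mention. Header-less notes are
#' generated at the configured rate. Byte-identical output for the same
#' config.
#'
#' @param config A [synth_config()].
#' @return List: `notes` (corpus tibble), `gold` (tibble with `note_id`,
#'   `patient_id`, `note_date`, `gold_label`, `is_case`).
#' @export
gen_notes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tpl <- synth_templates()
  ndays <- as.integer(config$date_range[2] - config$date_range[1]) + 1L

  all_rows <- withr::with_seed(config$seed, {
    n <- config$n_patients
    patient_id <- sprintf("P%05d", seq_len(n))
    is_case <- runif(n) < config$case_prevalence
    n_notes <- sample(
      seq(config$notes_per_patient[1], config$notes_per_patient[2]),
      n, replace = TRUE
    )

    rows <- vector("list", n)
    note_counter <- 0L
    for (i in seq_len(n)) {
      k <- n_notes[i]
      dates <- sort(config$date_range[1] + sample.int(ndays, k,
                                                      replace = TRUE) - 1L)
      pos_slot <- if (is_case[i]) sample.int(k, 1) else 0L
      kinds <- ifelse(
        seq_len(k) == pos_slot, "positive",
        ifelse(runif(k) < config$negated_mention_rate, "negated", "control")
      )
      headerless <- runif(k) < config$headerless_note_rate
      texts <- character(k)
      for (j in seq_len(k)) {
        hpi <- sample(tpl$hpi, 1)
        ap <- switch(
          kinds[j],
          positive = c(sample(tpl$positive, 1), sample(tpl$control, 1)),
          negated = c(sample(tpl$negated, 1), sample(tpl$control, 1)),
          control = sample(tpl$control, 2)
        )
        texts[j] <- if (headerless[j]) {
          paste(c(hpi, ap), collapse = " ")
        } else {
          paste0("Clinic note.\n\nHPI: ", hpi,
                 "\n\nAssessment and Plan:\n", paste(ap, collapse = " "),
                 "\n")
        }
      }
      rows[[i]] <- tibble::tibble(
        note_id = sprintf("N%06d", note_counter + seq_len(k)),
        patient_id = patient_id[i],
        note_date = dates,
        specialty = sample(c("hepatology", "gastroenterology"), k,
                           replace = TRUE),
        text = texts,
        gold_label = ifelse(kinds == "positive", "mash_positive",
                            "mash_negative")
      )
      note_counter <- note_counter + k
    }
    all_rows <- dplyr::bind_rows(rows)
    all_rows$is_case <- all_rows$patient_id %in% patient_id[is_case]
    all_rows
  })

  list(
    notes = all_rows[, c("note_id", "patient_id", "note_date", "specialty",
                         "text")],
    gold = all_rows[, c("note_id", "patient_id", "note_date", "gold_label",
                        "is_case")]
  )
}

#' Generate a synthetic patient registry
#'
#' Emits demographics, coded diagnosis events, transplant procedures and
#' the labs needed for MELD 3.0, for the flagged patients in `cases`.
#' Event times are exponential at the configured hazards, measured from
#' each patient's index date (index note date + offset) — a memoryless
#' model chosen for rate-recovery testing, not a claim about disease
#' biology. Baseline cirrhosis codes are planted for the configured
#' fraction (or exact quota); transplant events are generated for baseline
#' cirrhosis carriers and incident cirrhosis codes for non-carriers,
#' matching the subcohorts in which those outcomes are studied. When
#' `quotas$n_excluded` is set, exactly that many patients are planted with
#' an exclusion condition (cycling death-before-index,
#' transplant-before-index-note, missing sex/age); all other patients are
#' guaranteed to satisfy the inclusion rules.
#'
#' @param config A [synth_config()].
#' @param cases Tibble with `patient_id` and `index_note_date` (e.g. the
#'   case rows of [classify_patients()]).
#' @return Registry list: `patients`, `coded_events`, `procedures`, `labs`.
#' @export
gen_registry <- function(config, cases) {
  stopifnot(inherits(config, "synth_config"),
            all(c("patient_id", "index_note_date") %in% names(cases)))
  n <- nrow(cases)
  quota_ex <- config$quotas$n_excluded %||% NA_integer_
  if (!is.na(quota_ex) && quota_ex > n) {
    stop("exclusion quota (", quota_ex, ") exceeds number of patients (",
         n, ")", call. = FALSE)
  }
  quota_cirr <- config$quotas$n_baseline_cirrhosis %||% NA_integer_
  if (!is.na(quota_cirr) && quota_cirr > n) {
    stop("baseline-cirrhosis quota exceeds number of patients", call. = FALSE)
  }

  withr::with_seed(config$seed + 1L, {
    pid <- cases$patient_id
    index_note <- as.Date(cases$index_note_date)
    index_date <- index_note + config$index_offset_days

    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(0.537, 0.463))
    age <- sample(25:85, n, replace = TRUE)
    birth_date <- index_date - round(age * 365.25) -
      sample.int(300, n, replace = TRUE)
    asian <- runif(n) < 0.158
    bmi <- round(pmax(rnorm(n, 30.7, 5.5), 15), 1)
    bmi[runif(n) < 0.145] <- NA_real_

    # baseline cirrhosis carriers
    if (!is.na(quota_cirr)) {
      carrier <- rep(FALSE, n)
      carrier[sample.int(n, quota_cirr)] <- TRUE
    } else {
      carrier <- runif(n) < config$baseline_cirrhosis_fraction
    }

    # latent exponential event times (years) from index
    death_date <- index_date +
      round(rexp(n, rate = max(config$hazards$death, 1e-12)) * 365.25)
    if (config$hazards$death == 0) death_date <- as.Date(rep(NA, n))

    tx_time <- rexp(n, rate = max(config$hazards$transplant, 1e-12))
    tx_date <- index_date + round(tx_time * 365.25)
    has_tx <- carrier & config$hazards$transplant > 0

    cirr_time <- rexp(n, rate = max(config$hazards$cirrhosis, 1e-12))
    incident_cirr_date <- index_date + pmax(round(cirr_time * 365.25), 1)
    has_incident <- !carrier & config$hazards$cirrhosis > 0

    # planted exclusion conditions
    if (!is.na(quota_ex) && quota_ex > 0) {
      planted <- sample.int(n, quota_ex)
      cond <- (seq_len(quota_ex) - 1L) %% 3L
      for (k in seq_len(quota_ex)) {
        i <- planted[k]
        if (cond[k] == 0L) {
          death_date[i] <- index_date[i] - sample(5:80, 1)
        } else if (cond[k] == 1L) {
          tx_date[i] <- index_note[i] - sample(5:80, 1)
          has_tx[i] <- TRUE
        } else {
          sex[i] <- NA_character_
        }
      }
    }

    patients <- tibble::tibble(
      patient_id = pid, sex = sex, birth_date = birth_date,
      death_date = death_date, asian = asian, bmi = bmi
    )

    events <- list()
    if (any(carrier)) {
      events[[1]] <- tibble::tibble(
        patient_id = pid[carrier], code_system = "ICD", code = "K74.60",
        date = index_date[carrier] - sample.int(365, sum(carrier),
                                                replace = TRUE)
      )
    }
    if (any(has_incident)) {
      events[[length(events) + 1]] <- tibble::tibble(
        patient_id = pid[has_incident], code_system = "ICD", code = "K74.60",
        date = incident_cirr_date[has_incident]
      )
    }
    coded_events <- if (length(events) > 0) {
      dplyr::bind_rows(events)
    } else {
      tibble::tibble(patient_id = character(), code_system = character(),
                     code = character(), date = as.Date(character()))
    }

    procedures <- if (any(has_tx)) {
      tibble::tibble(patient_id = pid[has_tx], code = "47135",
                     date = tx_date[has_tx])
    } else {
      tibble::tibble(patient_id = character(), code = character(),
                     date = as.Date(character()))
    }

    labs <- dplyr::bind_rows(lapply(
      list(
        list(name = "bilirubin", value = round(rlnorm(n, log(0.8), 0.5), 2)),
        list(name = "sodium", value = round(rnorm(n, 138, 2.5), 1)),
        list(name = "inr", value = round(rlnorm(n, log(1.1), 0.15), 2)),
        list(name = "creatinine", value = round(rlnorm(n, log(0.8), 0.3), 2)),
        list(name = "albumin", value = round(pmax(rnorm(n, 3.9, 0.5), 1.6), 1))
      ),
      function(l) {
        tibble::tibble(patient_id = pid, name = l$name,
                       value = pmax(l$value, 0.1), date = index_note)
      }
    ))

    list(patients = patients, coded_events = coded_events,
         procedures = procedures, labs = labs)
  })
}
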