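# Shared fixture builders; everything is generated in code, no files.

make_note <- function(text, note_id = "n1", patient_id = "p1",
                      note_date = as.Date("2018-01-01")) {
  list(note_id = note_id, patient_id = patient_id,
       note_date = note_date, text = text)
}

# detect one note end-to-end, returning its label string
note_label <- function(text, ...) {
  classify_note(make_note(text), ...)$label
}

# a tiny handcrafted registry around a single index constellation
make_registry <- function(patients = NULL, coded_events = NULL,
                          procedures = NULL, labs = NULL) {
  list(
    patients = patients %||% tibble::tibble(
      patient_id = character(), sex = character(),
      birth_date = as.Date(character()), death_date = as.Date(character()),
      asian = logical(), bmi = double()
    ),
    coded_events = coded_events %||% tibble::tibble(
      patient_id = character(), code_system = character(),
      code = character(), date = as.Date(character())
    ),
    procedures = procedures %||% tibble::tibble(
      patient_id = character(), code = character(),
      date = as.Date(character())
    ),
    labs = labs %||% tibble::tibble(
      patient_id = character(), name = character(), value = double(),
      date = as.Date(character())
    )
  )
}

basic_patient <- function(patient_id = "p1", sex = "female",
                          birth_date = as.Date("1970-06-15"),
                          death_date = as.Date(NA), asian = FALSE,
                          bmi = 31) {
  tibble::tibble(patient_id = patient_id, sex = sex,
                 birth_date = birth_date, death_date = death_date,
                 asian = asian, bmi = bmi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
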