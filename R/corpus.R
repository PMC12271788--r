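#' Read a clinical note corpus
#'
#' Reads one note per record from a delimited table (comma-separated, UTF-8,
#' header row) or JSON Lines file. Required fields are `patient_id`,
#' `note_id`, `note_date` (ISO-8601 `YYYY-MM-DD`) and `text`; `specialty` is
#' optional. Record order is preserved.
#'
#' @param path Path to the corpus file.
#' @param format `"delimited_table"`, `"json_lines"`, or `"auto"` (default),
#'   which picks JSON Lines for `.jsonl`/`.ndjson`/`.json` extensions.
#' @param on_error What to do with a record whose required field is missing
#'   or whose date does not parse: `"fail"` (default) stops with the
#'   offending `note_id`; `"skip"` drops the record with a warning.
#' @param corpus_end Optional `Date`; notes dated after it are treated as
#'   errors under the same policy (a note cannot post-date the corpus).
#'
#' @return A tibble with columns `note_id`, `patient_id`, `note_date`
#'   (`Date`), `specialty` and `text`, one row per retained note.
#' @export
read_corpus <- function(path,
                        format = c("auto", "delimited_table", "json_lines"),
                        on_error = c("fail", "skip"),
                        corpus_end = NULL) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
      "json_lines"
    } else {
      "delimited_table"
    }
  }
  if (file.size(path) == 0) {
    return(empty_corpus())
  }

  if (format == "json_lines") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(empty_corpus())
    }
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    pick <- function(r, key) {
      v <- r[[key]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[[1]])
    }
    df <- tibble::tibble(
      note_id    = vapply(recs, pick, character(1), key = "note_id"),
      patient_id = vapply(recs, pick, character(1), key = "patient_id"),
      note_date  = vapply(recs, pick, character(1), key = "note_date"),
      specialty  = vapply(recs, pick, character(1), key = "specialty"),
      text       = vapply(recs, pick, character(1), key = "text")
    )
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          comment = "#", progress = FALSE)
    required <- c("note_id", "patient_id", "note_date", "text")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      stop("corpus is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (!"specialty" %in% names(df)) df$specialty <- NA_character_
    df <- df[, c("note_id", "patient_id", "note_date", "specialty", "text")]
  }
  if (nrow(df) == 0) {
    return(empty_corpus())
  }

  # text may legitimately be empty; a missing value is read as ""
  df$text[is.na(df$text)] <- ""
  parsed_date <- as.Date(df$note_date, format = "%Y-%m-%d")

  bad_field <- is.na(df$note_id) | !nzchar(df$note_id) |
    is.na(df$patient_id) | !nzchar(df$patient_id) |
    is.na(df$note_date) | !nzchar(df$note_date)
  bad_date <- !bad_field & is.na(parsed_date)
  bad_future <- rep(FALSE, nrow(df))
  if (!is.null(corpus_end)) {
    bad_future <- !bad_field & !bad_date & parsed_date > as.Date(corpus_end)
  }
  bad <- bad_field | bad_date | bad_future
  if (any(bad)) {
    ids <- ifelse(is.na(df$note_id) | !nzchar(df$note_id),
                  paste0("<record ", which(bad), ">"), df$note_id)[bad]
    msg <- paste0("invalid note record(s): ", paste(ids, collapse = ", "))
    if (on_error == "fail") stop(msg, call. = FALSE)
    warning("skipping ", sum(bad), " record(s): ", paste(ids, collapse = ", "),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    parsed_date <- parsed_date[!bad]
  }

  dup <- duplicated(df$note_id)
  if (any(dup)) {
    msg <- paste0("duplicate note_id(s): ",
                  paste(unique(df$note_id[dup]), collapse = ", "))
    if (on_error == "fail") stop(msg, call. = FALSE)
    warning("skipping ", sum(dup), " duplicate record(s)", call. = FALSE)
    parsed_date <- parsed_date[!dup]
    df <- df[!dup, , drop = FALSE]
  }

  tibble::tibble(
    note_id = df$note_id,
    patient_id = df$patient_id,
    note_date = parsed_date,
    specialty = df$specialty,
    text = df$text
  )
}

empty_corpus <- function() {
  tibble::tibble(
    note_id = character(), patient_id = character(),
    note_date = as.Date(character()), specialty = character(),
    text = character()
  )
}

#' Write a note corpus
#'
#' Inverse of [read_corpus()]: writes notes as CSV or JSON Lines in the
#' formats the reader accepts.
#'
#' @param notes Tibble as returned by [read_corpus()].
#' @param path Output path.
#' @param format `"delimited_table"` or `"json_lines"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(notes, path,
                         format = c("delimited_table", "json_lines")) {
  format <- match.arg(format)
  notes <- notes[, c("note_id", "patient_id", "note_date", "specialty", "text")]
  if (format == "delimited_table") {
    readr::write_csv(notes, path, progress = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(list(
        note_id = notes$note_id[i], patient_id = notes$patient_id[i],
        note_date = format(notes$note_date[i], "%Y-%m-%d"),
        specialty = notes$specialty[i], text = notes$text[i]
      ), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
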