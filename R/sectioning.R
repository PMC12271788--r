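#' Default Assessment & Plan header patterns
#'
#' Regular expressions (case-insensitive, tried in order) that mark the start
#' of the Assessment & Plan section. Shipped as an editable default — real
#' note templates differ by institution; see
#' `system.file("extdata", "ap_headers.txt", package = "mashcohort")`.
#'
#' @return Character vector of regex patterns.
#' @export
default_ap_headers <- function() {
  c(
    "assessment and plan",
    "assessment & plan",
    "a&p",
    "assessment:",
    "impression and plan",
    "impression:"
  )
}

# Headers that can terminate a section without themselves being A&P headers.
# Used only to find where the A&P section ends.
default_other_headers <- function() {
  c(
    "history of present illness", "hpi", "chief complaint", "subjective",
    "objective", "physical exam(ination)?", "review of systems",
    "past medical history", "past surgical history", "social history",
    "family history", "medications", "allergies", "labs", "laboratory data",
    "imaging", "vitals", "interval history"
  )
}

#' Read header patterns from a plain-text config file
#'
#' One regex per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the pattern file.
#' @return Character vector of patterns.
#' @export
read_header_patterns <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# Compile a header pattern. Anchored form requires the header at a line
# start; the unanchored form is a second pass for single-line notes.
# Both consume an optional ":"/"." and trailing whitespace so the section
# text starts at content.
header_regex <- function(pattern, anchored) {
  core <- paste0("(?:", pattern, ")")
  if (anchored) {
    paste0("(?im)^[ \t]*", core, "[:.]?[ \t]*\\r?\\n?[ \t]*")
  } else {
    paste0("(?i)", core, "[:.]?[ \t]*")
  }
}

# All matches of a perl regex as a data.frame of 0-based half-open spans.
regex_spans <- function(rx, text) {
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start0 = integer(0), end0 = integer(0)))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start0 = start1 - 1L, end0 = start1 - 1L + len)
}

#' Locate the Assessment & Plan section of a note
#'
#' Header patterns are tried in order; for the first pattern with a match,
#' the *last* occurrence in the note anchors the section (A&P conventionally
#' ends a note). The section runs from the end of the matched header to the
#' next recognized section header or the end of the note. Line-anchored
#' matching is attempted first; if no pattern matches at a line start, an
#' unanchored pass is attempted, so single-line notes still section. When no
#' pattern matches at all (or the note is empty), the whole note is returned
#' with `section_name = "whole_note_fallback"` — header-less notes are
#' scanned in full rather than dropped.
#'
#' @param note A list or one-row data frame with at least `text` (and
#'   ideally `note_id`).
#' @param header_patterns A&P header regexes, tried in order.
#' @param end_patterns Full header inventory used to find the section end;
#'   defaults to the A&P patterns plus [default_other_headers()].
#'
#' @return One-row tibble: `note_id`, `section_name` (one of
#'   `"assessment_and_plan"`, `"whole_note_fallback"`), `start_offset`,
#'   `end_offset` (0-based, half-open) and `text`, the exact substring of the
#'   note at those offsets.
#' @export
extract_ap_section <- function(note,
                               header_patterns = default_ap_headers(),
                               end_patterns = c(header_patterns,
                                                default_other_headers())) {
  stopifnot(length(header_patterns) > 0)
  text <- note$text %||% ""
  if (length(text) != 1 || is.na(text)) text <- ""
  note_id <- as.character(note$note_id %||% NA_character_)
  n <- nchar(text)

  fallback <- tibble::tibble(
    note_id = note_id, section_name = "whole_note_fallback",
    start_offset = 0L, end_offset = n, text = text
  )
  if (n == 0) {
    return(fallback)
  }

  hit <- NULL
  for (anchored in c(TRUE, FALSE)) {
    for (pat in header_patterns) {
      spans <- regex_spans(header_regex(pat, anchored), text)
      if (nrow(spans) > 0) {
        hit <- spans[nrow(spans), ] # last occurrence wins
        break
      }
    }
    if (!is.null(hit)) break
  }
  if (is.null(hit)) {
    return(fallback)
  }

  sec_start <- hit$end0
  # section ends at the next recognized header (line-anchored) or note end
  combined <- paste0("(?:", paste(end_patterns, collapse = "|"), ")")
  spans <- regex_spans(header_regex(combined, anchored = TRUE), text)
  ends <- spans$start0[spans$start0 >= sec_start]
  sec_end <- if (length(ends) > 0) min(ends) else n

  tibble::tibble(
    note_id = note_id, section_name = "assessment_and_plan",
    start_offset = as.integer(sec_start), end_offset = as.integer(sec_end),
    text = slice_text(text, sec_start, sec_end)
  )
}

#' Default sentence-splitting abbreviation list
#'
#' Tokens ending in a period that never terminate a sentence.
#' @return Lowercase character vector.
#' @export
default_abbreviations <- function() {
  c("dr.", "mr.", "mrs.", "ms.", "st.", "vs.", "e.g.", "i.e.", "etc.",
    "approx.", "pt.", "hx.", "dx.", "tx.", "fx.", "wt.", "b.i.d.", "q.d.",
    "p.o.", "prn.")
}

#' Split a note section into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?` followed by
#' whitespace) and on list-item boundaries (newline followed by a
#' bullet or numbering marker). Tokens in the abbreviation list and
#' line-initial list numbering ("1.", "2)") do not split. Offsets are
#' section-relative, 0-based and half-open; the returned sentences are
#' non-overlapping, ordered, and jointly cover every non-whitespace
#' character of the section.
#'
#' @param section One-row tibble from [extract_ap_section()].
#' @param abbreviations Lowercase tokens that suppress a split.
#' @return Tibble with `index` (1-based ordinal), `start`, `end`
#'   (section-relative offsets) and `text`.
#' @export
split_sentences <- function(section, abbreviations = default_abbreviations()) {
  empty <- tibble::tibble(index = integer(), start = integer(),
                          end = integer(), text = character())
  text <- section$text
  if (length(text) != 1 || is.na(text) || !grepl("\\S", text)) {
    return(empty)
  }
  n <- nchar(text)

  breaks <- integer(0) # 0-based positions where a new sentence begins

  # sentence-final punctuation
  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1]]
  if (m[1] != -1) {
    punct_end1 <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in punct_end1) {
      prefix <- substr(text, 1, e)
      parts <- strsplit(prefix, "[ \t\r\n]+")[[1]]
      tok <- tolower(tail(parts[nzchar(parts)], 1))
      if (length(tok) == 0) next
      line_prefix <- sub(".*\n", "", prefix)
      # line-initial list numbering ("1." / "2)") is a marker, not an end
      if (grepl("^[ \t]*[0-9]+[.)]$", line_prefix)) next
      if (tok %in% tolower(abbreviations)) next
      breaks <- c(breaks, e) # next sentence starts at 0-based offset e
    }
  }

  # list-item boundaries: newline followed by bullet or numbering
  m2 <- gregexpr("\\n(?=[ \t]*(?:[0-9]+[.)]|[-*•#])[ \t])", text,
                 perl = TRUE)[[1]]
  if (m2[1] != -1) {
    breaks <- c(breaks, as.integer(m2) - 1L) # break before the newline
  }

  bounds <- sort(unique(c(0L, breaks[breaks > 0 & breaks < n], n)))
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(length(bounds) - 1)) {
    s0 <- bounds[i]
    e0 <- bounds[i + 1]
    seg <- slice_text(text, s0, e0)
    lead <- regexpr("^\\s+", seg, perl = TRUE)
    if (lead != -1) s0 <- s0 + attr(lead, "match.length")
    trail <- regexpr("\\s+$", seg, perl = TRUE)
    if (trail != -1) e0 <- e0 - attr(trail, "match.length")
    if (e0 <= s0) next
    starts <- c(starts, as.integer(s0))
    ends <- c(ends, as.integer(e0))
  }
  if (length(starts) == 0) {
    return(empty)
  }
  tibble::tibble(index = seq_along(starts), start = starts, end = ends,
                 text = slice_text(text, starts, ends))
}
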