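#' Find lexicon mentions in a note section
#'
#' Runs every lexicon entry over each sentence and returns the
#' non-overlapping, leftmost-longest matches. Matching is case-insensitive
#' unless the entry sets `case_sensitive`. Spans are reported both
#' note-level (`start`, `end`) and sentence-relative (`sstart`, `send`),
#' all 0-based half-open; `assertion` is left `NA` for
#' [classify_assertion()] to fill.
#'
#' @param section One-row tibble from [extract_ap_section()].
#' @param sentences Tibble from [split_sentences()] on that section.
#' @param lexicon Tibble as from [default_lexicon()].
#' @return Tibble: `note_id`, `sentence_index`, `surface`, `start`, `end`,
#'   `sstart`, `send`, `label`, `assertion`.
#' @export
find_mentions <- function(section, sentences, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  empty <- tibble::tibble(
    note_id = character(), sentence_index = integer(), surface = character(),
    start = integer(), end = integer(), sstart = integer(), send = integer(),
    label = character(), assertion = character()
  )
  if (nrow(sentences) == 0) {
    return(empty)
  }

  out <- list()
  for (si in seq_len(nrow(sentences))) {
    stext <- sentences$text[si]
    cand <- list()
    for (li in seq_len(nrow(lexicon))) {
      rx <- lexicon$pattern[li]
      if (!lexicon$case_sensitive[li]) rx <- paste0("(?i)", rx)
      spans <- regex_spans(rx, stext)
      if (nrow(spans) > 0) {
        spans$label <- lexicon$label[li]
        cand[[length(cand) + 1]] <- spans
      }
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    # leftmost-longest, non-overlapping
    cand <- cand[order(cand$start0, -(cand$end0 - cand$start0)), ,
                 drop = FALSE]
    cursor <- -1L
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (cand$start0[k] >= cursor) {
        keep[k] <- TRUE
        cursor <- cand$end0[k]
      }
    }
    cand <- cand[keep, , drop = FALSE]
    base <- section$start_offset + sentences$start[si]
    out[[length(out) + 1]] <- data.frame(
      note_id = section$note_id,
      sentence_index = sentences$index[si],
      surface = slice_text(stext, cand$start0, cand$end0),
      start = as.integer(base + cand$start0),
      end = as.integer(base + cand$end0),
      sstart = as.integer(cand$start0),
      send = as.integer(cand$end0),
      label = cand$label,
      assertion = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) empty else tibble::as_tibble(do.call(rbind, out))
}

# Whitespace tokens with spans; `norm` is lowercased with leading/trailing
# punctuation stripped — the unit used for scope counting.
tokenize <- function(text) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      raw = character(0), norm = character(0)))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  raw <- substring(text, start1, start1 + len - 1L)
  norm <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw))
  data.frame(start0 = start1 - 1L, end0 = start1 - 1L + len,
             raw = raw, norm = norm, stringsAsFactors = FALSE)
}

phrase_tokens <- function(phrase) {
  toks <- strsplit(tolower(phrase), "\\s+")[[1]]
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks[nzchar(toks)])
}

# positions (token indices) at which `ptoks` occurs as consecutive tokens
phrase_positions <- function(norm, ptoks) {
  L <- length(ptoks)
  n <- length(norm)
  if (L == 0 || n < L) return(integer(0))
  hits <- integer(0)
  for (j in seq_len(n - L + 1)) {
    if (all(norm[j:(j + L - 1)] == ptoks)) hits <- c(hits, j)
  }
  hits
}

is_terminator <- function(tok_raw, tok_norm, terminators) {
  word_terms <- terminators[grepl("[[:alnum:]]", terminators)]
  punct_terms <- setdiff(terminators, word_terms)
  hit <- tok_norm %in% tolower(word_terms)
  for (p in punct_terms) {
    hit <- hit | grepl(p, tok_raw, fixed = TRUE)
  }
  hit
}

#' Classify mentions as affirmed or negated
#'
#' NegEx-style scoping within the sentence: a mention is negated when a
#' pre-trigger ends within `scope_window` tokens before it, or a
#' post-trigger starts within `scope_window` tokens after it, with no
#' terminator token in the gap. Otherwise it is affirmed.
#'
#' @param mentions Tibble from [find_mentions()].
#' @param sentences The sentences the mentions were found in.
#' @param rules Negation rules as from [default_negation_rules()].
#' @return `mentions` with `assertion` set to `"affirmed"` or `"negated"`.
#' @export
classify_assertion <- function(mentions, sentences,
                               rules = default_negation_rules()) {
  validate_negation_rules(rules)
  if (nrow(mentions) == 0) {
    return(mentions)
  }
  pre <- lapply(rules$pre_triggers, phrase_tokens)
  post <- lapply(rules$post_triggers, phrase_tokens)
  window <- rules$scope_window

  for (i in seq_len(nrow(mentions))) {
    sent <- sentences[sentences$index == mentions$sentence_index[i], ]
    toks <- tokenize(sent$text[1])
    ms <- mentions$sstart[i]
    me <- mentions$send[i]
    covering <- which(toks$end0 > ms & toks$start0 < me)
    if (length(covering) == 0) {
      mentions$assertion[i] <- "affirmed"
      next
    }
    i1 <- min(covering)
    i2 <- max(covering)

    gap_clear <- function(from, to) {
      if (from > to) return(TRUE)
      idx <- from:to
      if (length(idx) > window) return(FALSE)
      !any(is_terminator(toks$raw[idx], toks$norm[idx], rules$terminators))
    }

    negated <- FALSE
    for (pt in pre) {
      for (j in phrase_positions(toks$norm, pt)) {
        jend <- j + length(pt) - 1L
        if (jend < i1 && gap_clear(jend + 1L, i1 - 1L)) {
          negated <- TRUE
          break
        }
      }
      if (negated) break
    }
    if (!negated) {
      for (pt in post) {
        for (j in phrase_positions(toks$norm, pt)) {
          if (j > i2 && gap_clear(i2 + 1L, j - 1L)) {
            negated <- TRUE
            break
          }
        }
        if (negated) break
      }
    }
    mentions$assertion[i] <- if (negated) "negated" else "affirmed"
  }
  mentions
}

#' Classify one note for the presence of MASH
#'
#' Composes sectioning, sentence splitting, mention finding and assertion
#' classification. A note is `mash_positive` if and only if it contains at
#' least one affirmed mention; empty or mention-less notes are
#' `mash_negative`.
#'
#' @param note List or one-row tibble with `note_id`, `patient_id`,
#'   `note_date`, `text`.
#' @param lexicon,rules,header_patterns Detector configuration.
#' @return One-row tibble: `note_id`, `patient_id`, `note_date`, `label`
#'   and a `mentions` list-column.
#' @export
classify_note <- function(note,
                          lexicon = default_lexicon(),
                          rules = default_negation_rules(),
                          header_patterns = default_ap_headers()) {
  res <- classify_note_engine(note, lexicon, rules, header_patterns)
  tibble::tibble(
    note_id = as.character(note$note_id %||% NA_character_),
    patient_id = as.character(note$patient_id %||% NA_character_),
    note_date = as.Date(note$note_date %||% NA),
    label = res$label,
    mentions = list(res$mentions)
  )
}

classify_note_engine <- function(note, lexicon, rules, header_patterns) {
  section <- extract_ap_section(note, header_patterns)
  sentences <- split_sentences(section)
  mentions <- find_mentions(section, sentences, lexicon)
  mentions <- classify_assertion(mentions, sentences, rules)
  label <- if (nrow(mentions) > 0 && any(mentions$assertion == "affirmed")) {
    "mash_positive"
  } else {
    "mash_negative"
  }
  list(label = label, mentions = mentions)
}

#' Classify every note in a corpus
#'
#' @param notes Corpus tibble as from [read_corpus()].
#' @inheritParams classify_note
#' @return Tibble of note labels, one row per note, in corpus order.
#' @export
classify_corpus <- function(notes,
                            lexicon = default_lexicon(),
                            rules = default_negation_rules(),
                            header_patterns = default_ap_headers()) {
  validate_lexicon(lexicon)
  if (nrow(notes) == 0) {
    return(tibble::tibble(
      note_id = character(), patient_id = character(),
      note_date = as.Date(character()), label = character(),
      mentions = list()
    ))
  }
  n <- nrow(notes)
  labels <- character(n)
  mentions <- vector("list", n)
  for (i in seq_len(n)) {
    res <- classify_note_engine(
      list(note_id = notes$note_id[i], text = notes$text[i]),
      lexicon, rules, header_patterns
    )
    labels[i] <- res$label
    mentions[[i]] <- res$mentions
  }
  tibble::tibble(
    note_id = notes$note_id, patient_id = notes$patient_id,
    note_date = notes$note_date, label = labels, mentions = mentions
  )
}

#' Summarize note labels to patient level
#'
#' A patient is a case if any of their notes is `mash_positive`; the index
#' note is the earliest positive note (date ties broken by lexicographic
#' `note_id`, which leaves the date unchanged).
#'
#' @param labels Tibble from [classify_corpus()].
#' @return Tibble: `patient_id`, `is_case`, `index_note_date` (`NA` for
#'   non-cases), `index_note_id`.
#' @export
classify_patients <- function(labels) {
  if (nrow(labels) == 0) {
    return(tibble::tibble(
      patient_id = character(), is_case = logical(),
      index_note_date = as.Date(character()), index_note_id = character()
    ))
  }
  labels |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      is_case = any(.data$label == "mash_positive"),
      index_note_date = if (any(.data$label == "mash_positive")) {
        min(.data$note_date[.data$label == "mash_positive"])
      } else {
        as.Date(NA)
      },
      index_note_id = if (any(.data$label == "mash_positive")) {
        pos <- .data$label == "mash_positive"
        d <- .data$note_date[pos]
        ids <- .data$note_id[pos]
        min(ids[d == min(d)])
      } else {
        NA_character_
      },
      .groups = "drop"
    )
}

#' Write and read note labels as JSON Lines
#'
#' One JSON object per note with its supporting mentions (spans and
#' assertions) nested.
#'
#' @param labels Tibble from [classify_corpus()].
#' @param path Output path.
#' @return `path` invisibly (`write_note_labels`); a label tibble
#'   (`read_note_labels`).
#' @export
write_note_labels <- function(labels, path) {
  lines <- vapply(seq_len(nrow(labels)), function(i) {
    men <- labels$mentions[[i]]
    jsonlite::toJSON(list(
      note_id = labels$note_id[i],
      patient_id = labels$patient_id[i],
      note_date = format(labels$note_date[i], "%Y-%m-%d"),
      label = labels$label[i],
      mentions = lapply(seq_len(nrow(men)), function(k) {
        list(surface = men$surface[k], start = men$start[k],
             end = men$end[k], sentence_index = men$sentence_index[k],
             label = men$label[k], assertion = men$assertion[k])
      })
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_note_labels
#' @export
read_note_labels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    men <- dplyr::bind_rows(lapply(r$mentions, function(m) {
      tibble::tibble(
        note_id = r$note_id, sentence_index = as.integer(m$sentence_index),
        surface = m$surface, start = as.integer(m$start),
        end = as.integer(m$end), label = m$label, assertion = m$assertion
      )
    }))
    tibble::tibble(
      note_id = r$note_id, patient_id = r$patient_id,
      note_date = as.Date(r$note_date), label = r$label,
      mentions = list(men)
    )
  })
  dplyr::bind_rows(rows)
}
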