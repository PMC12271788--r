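test_that("read_corpus reads delimited tables and preserves record order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "note_id,patient_id,note_date,specialty,text",
    'n3,p1,2019-05-02,hepatology,"Assessment: NASH."',
    'n1,p2,2017-11-30,gastroenterology,"Stable."',
    "n2,p1,2018-01-01,hepatology,"
  ), path)
  notes <- read_corpus(path)
  expect_equal(nrow(notes), 3)
  expect_equal(notes$note_id, c("n3", "n1", "n2"))
  expect_s3_class(notes$note_date, "Date")
  expect_equal(notes$note_date[2], as.Date("2017-11-30"))
  expect_identical(notes$text[3], "") # empty text is legal
})

test_that("records with missing required fields follow the error policy", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "note_id,patient_id,note_date,text",
    "n1,p1,2018-01-01,ok",
    "n2,p1,,missing date",
    "n3,p2,2018-02-01,ok"
  ), path)
  expect_error(read_corpus(path, on_error = "fail"), "n2")
  expect_warning(notes <- read_corpus(path, on_error = "skip"), "n2")
  expect_equal(notes$note_id, c("n1", "n3"))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("note_id,patient_id,note_date,text",
               "n1,p1,2018-13-45,bad date"), path2)
  expect_error(read_corpus(path2), "n1")
})

test_that("an empty corpus file yields an empty collection without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  notes <- read_corpus(path)
  expect_equal(nrow(notes), 0)
  expect_named(notes,
               c("note_id", "patient_id", "note_date", "specialty", "text"))
})

test_that("json-lines corpora round-trip through write_corpus", {
  notes <- tibble::tibble(
    note_id = c("a", "b"), patient_id = c("p1", "p1"),
    note_date = as.Date(c("2020-01-01", "2020-06-01")),
    specialty = "hepatology",
    text = c("Assessment: NASH.", "Line one.\nLine two.")
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(notes, path, format = "json_lines")
  back <- read_corpus(path, format = "json_lines")
  expect_equal(back, notes)
})

test_that("duplicate note ids and future-dated notes are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("note_id,patient_id,note_date,text",
               "n1,p1,2018-01-01,x", "n1,p2,2019-01-01,y"), path)
  expect_error(read_corpus(path), "duplicate")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("note_id,patient_id,note_date,text",
               "n1,p1,2030-01-01,x"), path2)
  expect_error(read_corpus(path2, corpus_end = as.Date("2022-12-31")), "n1")
  expect_equal(nrow(read_corpus(path2)), 1) # no corpus end configured
})

test_that("the A&P section starts after the header and ends at the next header", {
  note <- make_note("HPI: stable. Assessment and Plan: NASH cirrhosis, follow up.")
  sec <- extract_ap_section(note)
  expect_equal(sec$section_name, "assessment_and_plan")
  expect_equal(sec$text, "NASH cirrhosis, follow up.")

  multi <- make_note(paste0(
    "HPI: feeling well.\n",
    "Assessment and Plan:\nNASH, stable.\n",
    "Medications: aspirin.\n"
  ))
  sec2 <- extract_ap_section(multi)
  expect_equal(sec2$text, "NASH, stable.\n")
})

test_that("notes without any header fall back to the whole note", {
  note <- make_note("Patient doing well. Continue meds.")
  sec <- extract_ap_section(note)
  expect_equal(sec$section_name, "whole_note_fallback")
  expect_equal(sec$start_offset, 0L)
  expect_equal(sec$end_offset, nchar(note$text))
  expect_equal(sec$text, note$text)

  empty <- extract_ap_section(make_note(""))
  expect_equal(empty$section_name, "whole_note_fallback")
  expect_equal(empty$text, "")
})

test_that("the last occurrence of a header anchors the section", {
  pre <- strrep("x", 10)
  mid <- strrep("y", 200 - 10 - nchar("\nAssessment: early text\n"))
  text <- paste0(pre, "\nAssessment: early text\n", mid,
                 "\nAssessment: late text")
  note <- make_note(text)
  sec <- extract_ap_section(note, header_patterns = "assessment:")
  expect_equal(sec$text, "late text")
  # anchor is at the final header, past the first one
  expect_gt(sec$start_offset, 200)
})

test_that("section offsets round-trip and sectioning is deterministic", {
  sim <- gen_notes(synth_config(n_patients = 30, seed = 301))
  for (i in seq_len(nrow(sim$notes))) {
    note <- sim$notes[i, ]
    sec <- extract_ap_section(note)
    expect_identical(
      substring(note$text, sec$start_offset + 1, sec$end_offset),
      sec$text
    )
    sec2 <- extract_ap_section(note)
    expect_identical(sec, sec2)
  }
})

test_that("sentences split on terminal punctuation and list items", {
  sec <- extract_ap_section(make_note("No NASH. Has cirrhosis."))
  s <- split_sentences(sec)
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("No NASH.", "Has cirrhosis."))

  lst <- split_sentences(extract_ap_section(make_note("1. NASH\n2. HTN")))
  expect_equal(nrow(lst), 2)
  expect_equal(lst$text, c("1. NASH", "2. HTN"))

  expect_equal(nrow(split_sentences(extract_ap_section(make_note("")))), 0)
})

test_that("abbreviations do not end sentences", {
  s <- split_sentences(extract_ap_section(
    make_note("Seen by Dr. Smith today. Stable on meds.")
  ))
  expect_equal(nrow(s), 2)
  expect_equal(s$text[1], "Seen by Dr. Smith today.")
})

test_that("sentence offsets round-trip and cover all non-whitespace text", {
  sim <- gen_notes(synth_config(n_patients = 30, seed = 302))
  for (i in seq_len(nrow(sim$notes))) {
    sec <- extract_ap_section(sim$notes[i, ])
    s <- split_sentences(sec)
    if (nrow(s) == 0) next
    # round-trip
    expect_identical(substring(sec$text, s$start + 1, s$end), s$text)
    # ordered, non-overlapping
    expect_true(all(diff(s$start) > 0))
    expect_true(all(utils::head(s$end, -1) <= utils::tail(s$start, -1)))
    # joint coverage of non-whitespace characters
    covered <- logical(nchar(sec$text))
    for (k in seq_len(nrow(s))) covered[(s$start[k] + 1):s$end[k]] <- TRUE
    chars <- strsplit(sec$text, "")[[1]]
    expect_true(all(covered[grepl("\\S", chars)]))
  }
})
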