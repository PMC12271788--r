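#' Default MASH keyword lexicon
#'
#' Word-boundary regex patterns for steatohepatitis mentions. The two
#' acronyms are matched case-sensitively in upper case so the common words
#' "mash" and "gnash" never fire. The lexicon is a configurable default
#' (see `system.file("extdata", "detector_rules.yml", package =
#' "mashcohort")`), not a fixed code path: institutions extend it to their
#' own documentation habits.
#'
#' @return Tibble with columns `pattern`, `label`, `case_sensitive`.
#' @export
default_lexicon <- function() {
  tibble::tibble(
    pattern = c(
      "\\bNASH\\b",
      "\\bMASH\\b",
      "\\bnon[-‐ ]?alcoholic steatohepatitis\\b",
      "\\bmetabolic dysfunction[\\s–—-]+associated steatohepatitis\\b",
      "\\bsteatohepatitis\\b"
    ),
    label = "MASH",
    case_sensitive = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Default negation rules
#'
#' NegEx-style assertion rules: trigger phrases before (`pre_triggers`) or
#' after (`post_triggers`) a mention negate it when they fall within
#' `scope_window` tokens with no scope-breaking `terminators` in between.
#' "rule out" is treated as a negation trigger; uncertainty hedges
#' ("possible NASH") are not modeled and count as affirmed.
#'
#' @return List with `pre_triggers`, `post_triggers`, `terminators`,
#'   `scope_window`.
#' @export
default_negation_rules <- function() {
  list(
    pre_triggers = c(
      "no evidence of", "no evidence for", "without evidence of",
      "no signs of", "no history of", "negative for", "not consistent with",
      "rule out", "ruled out", "r/o", "denies", "denied", "no", "not"
    ),
    post_triggers = c(
      "is ruled out", "was ruled out", "has been ruled out", "ruled out",
      "is excluded", "unlikely"
    ),
    terminators = c("but", "however", "although", "though", "except",
                    ";", ":"),
    scope_window = 6L
  )
}

#' Validate a lexicon
#'
#' Checks that the lexicon is non-empty, every pattern compiles, and no
#' pattern matches the empty string.
#'
#' @param lexicon Tibble as from [default_lexicon()].
#' @return The lexicon, invisibly; errors otherwise.
#' @export
validate_lexicon <- function(lexicon) {
  stopifnot(is.data.frame(lexicon),
            all(c("pattern", "label", "case_sensitive") %in% names(lexicon)))
  if (nrow(lexicon) == 0) stop("lexicon is empty", call. = FALSE)
  for (i in seq_len(nrow(lexicon))) {
    pat <- lexicon$pattern[i]
    ok <- tryCatch({
      grepl(pat, "probe", perl = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("lexicon pattern does not compile: ", pat, call. = FALSE)
    if (grepl(pat, "", perl = TRUE)) {
      stop("lexicon pattern matches the empty string: ", pat, call. = FALSE)
    }
  }
  invisible(lexicon)
}

validate_negation_rules <- function(rules) {
  stopifnot(is.list(rules),
            all(c("pre_triggers", "post_triggers", "terminators",
                  "scope_window") %in% names(rules)))
  if (rules$scope_window < 0) stop("scope_window must be >= 0", call. = FALSE)
  invisible(rules)
}

#' Read detector rules from a YAML config file
#'
#' The file has one section per component: `lexicon` (list of entries with
#' `pattern`, `label`, `case_sensitive`), `pre_triggers`, `post_triggers`,
#' `terminators` and `scope_window`. A shipped default lives at
#' `system.file("extdata", "detector_rules.yml", package = "mashcohort")`.
#'
#' @param path Path to the YAML file.
#' @return List with `lexicon` (tibble) and `negation` (rules list).
#' @export
read_detector_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  lex <- dplyr::bind_rows(lapply(cfg$lexicon, function(e) {
    tibble::tibble(
      pattern = e$pattern,
      label = e$label %||% "MASH",
      case_sensitive = isTRUE(e$case_sensitive)
    )
  }))
  rules <- list(
    pre_triggers = as.character(cfg$pre_triggers),
    post_triggers = as.character(cfg$post_triggers),
    terminators = as.character(cfg$terminators),
    scope_window = as.integer(cfg$scope_window %||% 6L)
  )
  validate_lexicon(lex)
  validate_negation_rules(rules)
  list(lexicon = lex, negation = rules)
}
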