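#' Match clinical codes against a pattern list
#'
#' Patterns are exact codes or prefix wildcards with a trailing `*`
#' (e.g. `"K74.6*"` matches `K74.60`, `K74.69`). Matching is
#' case-insensitive and literal otherwise.
#'
#' @param codes Character vector of codes.
#' @param patterns Character vector of code patterns.
#' @return Logical vector: does each code match any pattern?
#' @export
code_matches <- function(codes, patterns) {
  codes <- toupper(trimws(as.character(codes)))
  hit <- rep(FALSE, length(codes))
  for (p in toupper(trimws(patterns))) {
    if (endsWith(p, "*")) {
      hit <- hit | startsWith(codes, substr(p, 1, nchar(p) - 1L))
    } else {
      hit <- hit | codes == p
    }
  }
  hit
}

#' Read a code list from a plain-text config file
#'
#' One code (or prefix wildcard) per line; `#` comments and blank lines
#' are ignored.
#'
#' @param path Path to the file.
#' @return Character vector of code patterns.
#' @export
read_code_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Default ICD code lists for cirrhosis and decompensation
#'
#' Editable defaults (the study system's exact lists are institution
#' configuration): ICD-10 and legacy ICD-9 cirrhosis codes, and codes for
#' decompensating complications (ascites, hepatic encephalopathy, varices,
#' hepatorenal syndrome). Shipped as plain-text files under
#' `system.file("extdata", package = "mashcohort")`.
#'
#' @return Character vector of code patterns.
#' @export
default_cirrhosis_codes <- function() {
  c("K74.6*", "K74.3", "K74.4", "K74.5", "K70.3*", "K71.7",
    "571.2", "571.5", "571.6")
}

#' @rdname default_cirrhosis_codes
#' @export
default_decompensation_codes <- function() {
  c("R18*", "789.5*", "K72.9*", "K72.1*", "572.2", "I85*", "456.0",
    "456.1", "456.2*", "K76.7", "572.4", "K65.2")
}

#' Default liver-transplant procedure code (CPT)
#' @return Character vector of code patterns.
#' @export
default_transplant_codes <- function() {
  "47135"
}
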