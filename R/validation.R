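#' Sample development and test note sets
#'
#' Uniformly samples `n_total` note ids without replacement, then splits
#' them into disjoint development (`n_dev`) and test (`n_total - n_dev`)
#' sets. Reproducible given `seed`.
#'
#' @param note_ids Candidate note ids.
#' @param n_total Total notes to sample (default 300).
#' @param n_dev Development-set size (default 150).
#' @param seed Integer RNG seed.
#' @return List with `dev` and `test` id vectors.
#' @export
sample_split <- function(note_ids, n_total = 300L, n_dev = 150L, seed) {
  if (length(note_ids) < n_total) {
    stop("corpus too small: ", length(note_ids), " notes < n_total = ",
         n_total, call. = FALSE)
  }
  if (n_dev < 0 || n_dev > n_total) {
    stop("n_dev must be in [0, n_total]", call. = FALSE)
  }
  sampled <- withr::with_seed(seed, sample(note_ids, n_total))
  list(
    dev = sampled[seq_len(n_dev)],
    test = sampled[setdiff(seq_len(n_total), seq_len(n_dev))]
  )
}

#' Adjudicate dual-reviewer labels
#'
#' Agreements keep the shared label; disagreements take the third-review
#' label. An uncovered disagreement is an error naming the offending notes.
#'
#' @param labels Tibble with `note_id`, `reviewer_a`, `reviewer_b`
#'   (values `"positive"`/`"negative"`).
#' @param third_review Named character vector or tibble
#'   (`note_id`, `label`) covering every disagreement. May be `NULL` when
#'   the reviewers fully agree.
#' @return `labels` with an `adjudicated` column.
#' @export
adjudicate <- function(labels, third_review = NULL) {
  if (is.data.frame(third_review)) {
    third_review <- stats::setNames(third_review$label, third_review$note_id)
  }
  agree <- labels$reviewer_a == labels$reviewer_b
  adjudicated <- ifelse(agree, labels$reviewer_a, NA_character_)
  need <- labels$note_id[!agree]
  uncovered <- setdiff(need, names(third_review))
  if (length(uncovered) > 0) {
    stop("disagreement(s) without a third review: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  if (length(need) > 0) {
    adjudicated[!agree] <- unname(third_review[need])
  }
  labels$adjudicated <- adjudicated
  labels
}

#' Evaluate predictions against adjudicated gold labels
#'
#' Standard 2x2 evaluation with MASH-positive as the positive class.
#' Metrics with a zero denominator are reported as `NA`, never as 0.
#'
#' @param predictions Tibble with `note_id` and `label`
#'   (`"mash_positive"`/`"mash_negative"` or `"positive"`/`"negative"`).
#' @param gold Tibble with `note_id` and `adjudicated`
#'   (from [adjudicate()]). Every gold note must have a prediction.
#' @return List with `confusion` (tp, fp, fn, tn) and `metrics` (tibble:
#'   sensitivity, specificity, accuracy, f1, ppv, n).
#' @export
evaluate <- function(predictions, gold) {
  missing <- setdiff(gold$note_id, predictions$note_id)
  if (length(missing) > 0) {
    stop("gold note(s) without a prediction: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  normalize <- function(x) {
    ifelse(x %in% c("mash_positive", "positive"), "positive", "negative")
  }
  pred <- normalize(predictions$label[match(gold$note_id,
                                            predictions$note_id)])
  truth <- normalize(gold$adjudicated)
  tp <- sum(pred == "positive" & truth == "positive")
  fp <- sum(pred == "positive" & truth == "negative")
  fn <- sum(pred == "negative" & truth == "positive")
  tn <- sum(pred == "negative" & truth == "negative")
  list(
    confusion = list(tp = tp, fp = fp, fn = fn, tn = tn),
    metrics = confusion_metrics(tp, fp, fn, tn)
  )
}

#' Classification metrics from 2x2 counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`, `f1`,
#'   `ppv`, `n`; `NA` where the denominator is 0.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  n <- tp + fp + fn + tn
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, n),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    ppv = safe_div(tp, tp + fp),
    n = n
  )
}

#' Enumerate confusion matrices consistent with printed percentages
#'
#' Exhaustively enumerates every integer 2x2 matrix summing to `n` whose
#' sensitivity, specificity and accuracy round (half-up, to the nearest
#' integer percent) to the given values. Used as an oracle to check that a
#' printed metric quadruple is internally consistent.
#'
#' @param n Total note count (> 0).
#' @param sensitivity_pct,specificity_pct,accuracy_pct Printed integer
#'   percentages.
#' @return Tibble of matching matrices (`tp`, `fp`, `fn`, `tn`); possibly
#'   empty.
#' @export
consistent_matrices <- function(n, sensitivity_pct, specificity_pct,
                                accuracy_pct) {
  stopifnot(n > 0)
  pos <- unlist(lapply(0:n, function(p) rep.int(p, (p + 1) * (n - p + 1))))
  tp <- unlist(lapply(0:n, function(p) rep(0:p, each = n - p + 1)))
  tn <- unlist(lapply(0:n, function(p) rep.int(0:(n - p), p + 1)))
  fn <- pos - tp
  fp <- n - pos - tn
  neg <- n - pos

  ok <- pos > 0 & neg > 0
  sens <- round_half_up(100 * tp / pos)
  spec <- round_half_up(100 * tn / neg)
  acc <- round_half_up(100 * (tp + tn) / n)
  keep <- ok & sens == sensitivity_pct & spec == specificity_pct &
    acc == accuracy_pct
  tibble::tibble(tp = tp[keep], fp = fp[keep], fn = fn[keep], tn = tn[keep])
}
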