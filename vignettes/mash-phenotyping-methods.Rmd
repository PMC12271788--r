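---
title: "Rule-based MASH phenotyping and cohort construction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based MASH phenotyping and cohort construction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mashcohort)
```

## The problem

Metabolic dysfunction–associated steatohepatitis (MASH, formerly NASH) is
poorly captured by ICD codes alone: the diagnosis usually lives in the
free-text assessment of a hepatology or gastroenterology note. `mashcohort`
implements a rule-based phenotyping pipeline for this setting — find keyword
mentions of steatohepatitis in the Assessment & Plan (A&P) section of
specialist notes, decide whether each mention is affirmed or negated, reduce
note labels to patient case status, and then build an epidemiological cohort
from a structured registry: index dates, exclusions, cirrhosis subcohorts,
baseline covariates, competing-risk time-to-event tables and person-year
incidence rates.

Everything is exercisable without protected health information: the `synth`
functions generate notes and registries with known ground truth, and the
validation functions implement a dual-review chart-validation workflow.

## Note model

A note is sectioned before any matching happens. A&P header patterns
(`default_ap_headers()`, editable in `inst/extdata/ap_headers.txt`) are
tried in order; for the first pattern that matches, the *last* occurrence
anchors the section, because the A&P conventionally closes a note. The
section runs to the next recognized header (from the full header inventory,
not only A&P headers) or to the end of the note.

Two deliberate design choices:

* **Anchoring.** Patterns are matched at line starts first. If nothing
  matches line-anchored, a second, unanchored case-insensitive pass runs, so
  single-line notes ("HPI: ... Assessment and Plan: ...") still section
  correctly. Only if both passes fail is the note handled by fallback.
* **Fallback totality.** A note without any recognizable header is scanned
  in full (`whole_note_fallback`) rather than dropped. This maximizes
  sensitivity; the cost is that mentions outside a *missing* A&P can count,
  which is the intended trade-off for header-less dictation styles.

Offsets are 0-based and half-open everywhere; every section and sentence
stores offsets such that slicing the parent text reproduces the stored text
exactly, and the test suite asserts this round-trip as a property.

Sentences split on terminal punctuation and on list-item boundaries
(newline followed by numbering or a bullet), with a configurable
abbreviation list ("Dr.", "vs.", ...) and protection for line-initial list
markers ("1." never ends a sentence). The sentence is the negation scope
unit.

## Detector

The lexicon (`default_lexicon()`) is a set of word-boundary regular
expressions. The acronyms NASH and MASH match in upper case only, so the
common words "mash" and "gnash" cannot fire; the spelled-out forms match
case-insensitively, including hyphen and en-dash variants. Overlapping
matches resolve leftmost-longest ("nonalcoholic steatohepatitis" beats
"steatohepatitis"). The shipped list is a configurable default
(`inst/extdata/detector_rules.yml`), not a fixed vocabulary — institutional
keyword inventories belong in configuration.

Assertion classification follows the NegEx convention: pre-triggers ("no
evidence of", "rule out", "denies", ...), post-triggers ("ruled out",
"unlikely"), scope-breaking terminators ("but", "however", ";") and a
scope window, default **6 tokens** (whitespace tokens, punctuation
stripped). A mention is negated when a trigger falls within the window on
the appropriate side with no terminator in between; otherwise affirmed.
Uncertainty hedges ("possible NASH") are *not* modeled as a separate class
and count as affirmed — with a presence/absence target, hedged mentions in
a specialist A&P usually reflect working diagnoses. Historical and
family-history assertions are likewise not modeled; the adversarial
templates (`adversarial_templates()`) document what this misses.

A note is `mash_positive` iff it has at least one affirmed mention. A
patient is a case iff any note is positive, and the index note is the
earliest positive note (date ties broken by lexicographic note id, which
cannot change the date).

## Cohort construction

* **Index date** = earliest positive note date + 90 days
  (`derive_index_date()`), allowing for delayed recording of the diagnosis.
* **Exclusions** (`apply_exclusions()`), first matching reason recorded:
  death before index; transplant before the index *note* date (diagnosis
  after orthotopic transplant — checked before the generic transplant rule,
  otherwise it could never be recorded as its own reason); transplant
  before the index date; missing age or sex; age under 18. Included and
  excluded rows partition the candidates.
* **Subcohorts** (`assign_subcohort()`): baseline cirrhosis iff any coded
  cirrhosis event is dated on or before the index date. The boundary is
  inclusive: a code recorded on the index date describes baseline status.
  Incident cirrhosis is studied in the no-cirrhosis subcohort, transplant
  in the cirrhosis subcohort, all-cause mortality in the full cohort.
* **Covariates**: BMI categories use Asian cut-points 18.5/23/27.5 and
  non-Asian 18.5/25/30. `meld3()` implements the published MELD 3.0 score
  (Kim et al. 2021) with its clamps (bilirubin/INR/creatinine floored at
  1.0, creatinine capped at 3.0, sodium in [125, 137], albumin in
  [1.5, 3.5]); a missing lab gives a missing score — imputation is out of
  scope.

### Competing risks and the guard window

`build_tte()` excludes patients whose outcome is recorded on or before the
index date, codes events in `(index, follow-up end]`, and censors
administratively at the follow-up end (default 2023-12-31). The
competing-event rule ships with two readings because the underlying
"censored if the competing event occurred before 3 months before the
outcome" convention is genuinely ambiguous:

* `strict = TRUE` (default): any competing event strictly before the
  outcome censors it at the competing-event date. This keeps the risk set
  well defined and never counts an outcome observed after the patient has
  died or been transplanted.
* `strict = FALSE, guard_days = 90`: the literal reading — the outcome is
  only censored when the competing event precedes it by more than the
  guard window; outcomes recorded within 90 days after a competing event
  still count (delayed coding of a genuinely earlier outcome).

Person-years use 365.25 days/year, and
`incidence_rate(n, py) = 100 n / py` per 100 person-years, exactly equal by
construction to what `incidence_summary()` reports on the package's own
tables.

## Validation workflow

`sample_split()` draws the development/test note samples (defaults 300
sampled, 150/150 split), `adjudicate()` resolves dual-review disagreements
by third review, and `evaluate()` computes the 2×2 metrics with
MASH-positive as the positive class. Metrics with zero denominators are
reported as missing, never as zero. Printed percentages are matched with
half-up rounding (`round_half_up()`); the convention is the package's
choice, as chart-review reports rarely state theirs.

`consistent_matrices()` exhaustively enumerates the integer 2×2 matrices
of a given size whose sensitivity/specificity/accuracy round to printed
values — an oracle for checking whether a reported metric quadruple is
internally consistent. For n = 150 and 89/84/86%, twelve matrices qualify
and their F1 values round across 0.80–0.86, so sensitivity/specificity/
accuracy at integer-percent precision do **not** pin down F1 to two
decimals; a printed F1 of 0.84 is consistent with (but not implied by) the
other three. The test suite asserts both facts.

## Synthetic data

The generator's defaults are the study conditions, fixed once:

| parameter | default | basis |
|---|---|---|
| corpus window | 2012-01-01 – 2022-12-31 | reported inclusion window |
| index offset | 90 days | reported index rule |
| follow-up end | 2023-12-31 | reported follow-up |
| death hazard | 0.044 /PY | reported incidence, full cohort |
| cirrhosis hazard | 0.045 /PY | reported incidence, no-cirrhosis subcohort |
| transplant hazard | 0.031 /PY | reported incidence, cirrhosis subcohort |
| baseline cirrhosis | 0.554 | reported subcohort fraction |
| sex split | 53.7% female | reported demographics |
| notes per patient | uniform 1–4 | realistic clinic volume, unreported |
| case prevalence | 0.3 | realistic specialist-clinic mix, unreported |
| negated-mention rate | 0.3 | unreported; exercises the negation path |
| header-less note rate | 0.1 | unreported; exercises the fallback path |

Event times are exponential (memoryless) from the index date — the
simplest model sufficient for rate-recovery testing, not a claim about
MASH biology; latent event times are independent, with competing-event
structure imposed downstream by `build_tte()`. Quota mode plants *exact*
counts of exclusion conditions or baseline-cirrhosis carriers, and
guarantees that non-quota patients satisfy the inclusion rules, so fixture
cohort sizes are deterministic.

Note templates deliberately use only phenomena the rule model covers:
same-sentence triggers, standard headers, no cross-sentence negation. That
makes planted gold labels exactly recoverable — the suite asserts 100%
detector–gold agreement on 1000 template-conforming notes — and it bounds
what such tests show about real notes: real clinical text contains
cross-sentence anaphora, hedging, templated boilerplate and improper
redaction that this generator does not emulate. The reported chart-review
validation workflow exists precisely because rule recovery on conforming
text is necessary but not sufficient.

## Numerical and scale choices

Simulation sizes used by the test suite were chosen to make the
statistical assertions sharp at desk scale: property loops run on 30–120
patient corpora, gold recovery on 1000 notes, and rate recovery on a 5000
patient registry, where three standard errors correspond to roughly ±0.004
events/PY for the mortality hazard. The quota fixtures use the reported
sizes (2824 flagged, 129 excluded, 1494 carriers) exactly, since quota
planting is deterministic. All randomness flows from a single integer seed
per config; reruns are byte-identical.

## Known limitations

* The detector has no statistical NER, no spelling correction, no
  hedge/history/family assertion classes, and negation scope never crosses
  a sentence boundary.
* Section detection depends on the header inventory; unusual templates fall
  back to whole-note scanning, trading specificity for sensitivity.
* The cohort builder performs no imputation, no hazard modeling and no
  comorbidity-index computation; it produces the tables such models would
  consume.
* ICD/CPT code lists ship as editable defaults and should be reviewed
  against local coding practice before use on real registries.
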