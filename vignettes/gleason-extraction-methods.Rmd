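---
title: "Extracting Gleason scores from narrative biopsy reports: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting Gleason scores from narrative biopsy reports: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gleasonminer)
```

## The extraction problem

A prostate biopsy report is a semi-structured narrative: a clinical history
(age, PSA, referral reason), a macroscopy section (core counts and
millimetre measurements) and a pathological diagnosis in which the Gleason
score is dictated in free text. The score itself is two graded histological
patterns — the major (most prevalent) and minor (second most prevalent)
pattern, each 1–5 — summed to a total of 2–10 and mapped to a guideline
risk category: low (total ≤ 6), intermediate (= 7), high (≥ 8).

Because reporting style is pathologist-dependent, the same score surfaces
in many textual shapes (`GLEASON 4, 3`, `5 PLUS 4 EQUALS 9`, `7 (3 + 4)`,
`SCORE 8 (MAJOR 5; MINOR 3)`, `3 (MAJOR) + 4 (MINOR) = 7/10`, …). The
linear structure of these shapes makes them well suited to regular
expressions, and the package takes that rule-based route rather than a
learned model: the grammar is inspectable, editable and auditable, which
matters in a registry setting.

## Pipeline

Each report passes through: text normalization → spelling-variant mapping →
section segmentation → grammar matching → candidate selection → total
computation → standardized rendering → risk classification.

**Normalization** lowercases and collapses whitespace, deleting nothing:
digits and the symbols `+ = ( ) / ; , :` are what the grammar consumes.
**Spelling mapping** canonicalizes dictation variants of the keyword
("gleeson", "gleasen", …) via a shipped, editable map. Two deliberate
asymmetries separate the extraction path from the feature path:

- *Stemming* is applied only on the term-frequency feature path (a small
  rule-based suffix stripper for plurals, *-ed*, *-ing*), never before
  grammar matching — a general stemmer could corrupt score-adjacent tokens.
- *Stopword removal* likewise only affects term-frequency tables. The
  shipped stoplist is a standard English list with the score vocabulary
  (`major`, `minor`, `gleason`, `score`, `pattern`, numerals, `+`, `=`)
  excluded, and the remover rejects any stoplist containing those tokens.

**Segmentation** splits at the first occurrence of each standard heading
(word boundary, optional colon); text before any heading is `unsectioned`.
Sections tile the text exactly, so every grammar match can be attributed to
a section by its character span.

## The grammar

The grammar is an ordered set of PCRE rules in
`inst/extdata/grammar.tsv`, each naming the role (major / minor / total)
of every capture group. Design points that were genuinely open:

- **Overlap resolution.** All rules run over the whole normalized text;
  overlapping matches are resolved longest-match-first, then
  earliest-start, then rule order. This lets a specific rule
  (`score 8 (major 5; minor 3)`) win over the generic pair rule matching
  its inside.
- **Keyword windows.** Bare digit pairs (`4, 3`, `4;4`) are valid only
  adjacent to a `gleason` keyword; a free-floating comma pair
  (`SPECIMEN 3, 4 CORES`) must not parse. Pairs joined by an explicit
  `+`/`plus` are distinctive enough to match anywhere.
- **Range guards.** Components must lie in 1–5 and totals in 2–10;
  candidates violating the ranges are discarded rather than clamped, so a
  PSA of 7.9 or a 15 mm core measurement can never become a score.
  Lookarounds additionally refuse digits embedded in larger numbers or
  decimals.
- **Denominators** (`4/5` patterns, `7/10` totals) are consumed by the
  rules so only the scores remain.

**Selection.** When several candidates survive, candidates carrying both
components outrank total-only mentions, and by default the *last* candidate
in document order is reported (`take_latter = TRUE`). The rationale: the
pathological diagnosis follows the clinical history in report layout, so
the last mention is the current score even when the history quotes a prior
one. The pre-fix first-mention behaviour is kept (`take_latter = FALSE`)
to let users reproduce the degradation it causes, and a stricter
"prefer the diagnosis section" mode is available behind
`prefer_diagnosis = TRUE`.

**Statuses.** A report yields `ok` (components found, total = major +
minor), `incomplete` (total-only mention, e.g. `GLEASON SCORE 7`: total
and risk are reported, components absent), `conflict` (stated total ≠
computed; the computed total is authoritative since the total is by
definition the sum), or `no_score_found`. Malformed input never raises an
error per report. The standardized string `"M + m = T"` is emitted only
for `ok` rows, and re-parsing it reproduces the triple exactly.

## Evaluation

Exact match is defined on the (major, minor, total) triple against the
manually coded gold standard — robust to formatting, equivalent to string
comparison given the standardization. The confusion matrix counts TP
(exact match), FN (truth has a score, prediction absent or different), FP
(score fabricated on a score-free report) and TN (both absent). Precision,
recall and F = 2PR/(P+R) are computed at full precision and rounded only
for display (default 2 dp, configurable to 3); an undefined metric (zero
denominator) stays `NA`/null and is never coerced to 0. Multi-class risk
performance uses one-vs-rest confusion per category and macro averages
(arithmetic mean of the defined per-class values). A chi-square
homogeneity comparison of predicted vs coded category counts is offered as
this package's own optional check; it is not part of the core harness.

## The synthetic generator

Real biopsy corpora cannot be shared, so the generator produces uppercase
three-section reports with planted truth. What it emulates:

- the standard heading structure, with randomized numeric decoys (age,
  PSA with one decimal, core counts, millimetre lengths) that must never
  parse as scores;
- the catalogued reporting formats (ten primary templates plus three
  auxiliary n-gram shapes), drawn from configurable weights (uniform by
  default);
- a (major, minor) distribution defaulting to routine surveillance
  proportions — 17.6% `5 + 4 = 9`, 17.5% `3 + 3 = 6`, 16.4% `4 + 3 = 7`,
  14.7% `3 + 4 = 7`, 14.2% `4 + 4 = 8` — with the residual 19.6% spread
  uniformly over the remaining pairs with totals ≤ 7, so the high-risk
  fraction stays 31.8% in expectation;
- clinical-history duplicates at rate 0.016 (16 per 1000 in expectation)
  that always *differ* from the diagnosis score, mirroring the failure
  mode that motivates the take-latter rule; same-score duplicates would be
  harmless and are not injected;
- keyword misspellings ("GLEESON", "GLEASEN") at rate 0.05 by default;
- optionally score-free reports (rate 0 by default: prevalence of such
  reports in routine data is unknown, so the default is conservative and
  configurable).

Generation is driven by R's seeded RNG; the same configuration reproduces
byte-identical corpora, and the seed is recorded on the result.

What the generator does *not* emulate: free prose variation beyond the
templates, per-core scores, negated or historical score discussions,
non-English reports, OCR noise. A perfect F-score on synthetic corpora
therefore demonstrates that the grammar covers the catalogued formats and
that selection and decoy guards behave as designed — not that recall on an
arbitrary real-world laboratory's style would be perfect.

## Numerical and scale choices

Test and benchmark corpora are sized for quick, deterministic runs: the
selection-rule experiment uses 1000 reports (matching the scale at which
the 0.016 duplicate rate yields ~16 affected reports), round-trip property
checks use 20 seeds of 10–15 reports, and distribution checks use 10,000
draws with a three-standard-error band. N-gram features are capped at
quadgrams — by four tokens the score-bearing word combinations are
exhausted. Top-k term ranking breaks count ties lexicographically so
output is deterministic. Empty inputs yield empty, well-typed outputs
throughout.

## Known limitations

- A report whose *only* score mention is a bare pair far from any keyword
  is missed by design (the keyword window trades that recall for decoy
  precision).
- Grade-group (ISUP 1–5) conversion, per-core extraction and
  PSA/stage-augmented risk stratification are out of scope.
- The grammar is English-only; extending it means editing
  `grammar.tsv` and the variant map, not code.
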