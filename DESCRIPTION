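Package: gleasonminer
Title: Rule-Based Extraction of Gleason Scores from Narrative Prostate
    Biopsy Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the Gleason score (major pattern, minor pattern, total,
    standardized rendering and guideline risk category) from semi-structured
    narrative prostate biopsy reports using an expert rule-based grammar over
    the reporting formats observed in routine anatomical pathology practice.
    Includes text pre-processing (normalization, spelling-variant mapping,
    tokenization, stopword removal, section segmentation), n-gram
    term-frequency feature tables, an evaluation harness (exact-match
    confusion matrix, precision/recall/F-score, one-vs-rest macro-averaged
    multi-class metrics, score-frequency and high-risk summaries) and a
    seedable synthetic-report generator with planted ground truth for
    benchmarking extraction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
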