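# The ten reporting-format strings observed in routine practice, with the
# score each must yield.
table4_formats <- function() {
  tibble::tribble(
    ~reported,                                ~major, ~minor, ~total,
    "5, 4",                                   5L, 4L, 9L,
    "5 PLUS 4 EQUALS 9",                      5L, 4L, 9L,
    "3 + 3 = 6 OR 3 + 3",                     3L, 3L, 6L,
    "MAJOR PATTERN 3, MINOR PATTERN 5",       3L, 5L, 8L,
    "MAJOR PATTERN: 4/5 MINOR PATTERN: 3/5",  4L, 3L, 7L,
    "MAJOR 4 PLUS MINOR 3 EQUALS 7",          4L, 3L, 7L,
    "SCORE 8 (MAJOR 5; MINOR 3)",             5L, 3L, 8L,
    "7 (3 + 4)",                              3L, 4L, 7L,
    "(4 + 3) = 7",                            4L, 3L, 7L,
    "3 (MAJOR) + 4 (MINOR) = 7/10",           3L, 4L, 7L
  )
}

# Near-miss strings that must never yield a candidate: PSA values, ages,
# core measurements and other numeric decoys.
decoy_strings <- function() {
  c(
    "A 67 YEAR OLD MALE PATIENT WITH A PSA OF 7.9 UG/L",
    "SIXTEEN CORES OF TISSUE, THE LONGEST MEASURING 15MM AND THE SHORTEST MEASURING 7MM",
    "TWO CORES ARE INVOLVED AND < 5% OF THE TISSUE",
    "P63 AND CK5/6: BASAL CELLS ARE NOT DEMONSTRATED",
    "PSA 12.4 NG/ML ON 12/10/2015",
    "SPECIMEN 3, 4 CORES SUBMITTED"
  )
}

path_example_report <- function() {
  system.file("extdata", "example_report.csv", package = "gleasonminer")
}

# Build a knowledge table holding `count` copies of each standardized score.
make_knowledge_records <- function(scores, counts) {
  parsed <- parse_standardized(scores)
  rows <- lapply(seq_along(scores), function(i) {
    tibble::tibble(
      episode_id = sprintf("%s-%04d", gsub("[ +=]", "", scores[i]),
                           seq_len(counts[i])),
      major = parsed$major[i], minor = parsed$minor[i],
      total = parsed$total[i], standardized = scores[i],
      risk = as.character(classify_risk(parsed$total[i])),
      status = "ok")
  })
  dplyr::bind_rows(rows)
}

# Independent brute-force n-gram tally: nested loops, no shared code with
# term_frequencies().
brute_force_ngram_counts <- function(corpus, n) {
  counts <- new.env(parent = emptyenv())
  for (doc in corpus) {
    if (length(doc) < n) next
    for (s in 1:(length(doc) - n + 1)) {
      key <- paste(doc[s:(s + n - 1)], collapse = " ")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) counts[[k]], integer(1)), keys)
}
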