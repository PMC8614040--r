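test_that("every catalogued reporting format yields its expected score", {
  suite <- table4_formats()
  for (i in seq_len(nrow(suite))) {
    got <- parse_score_string(suite$reported[i])
    expect_identical(got$major, suite$major[i], label = suite$reported[i])
    expect_identical(got$minor, suite$minor[i], label = suite$reported[i])
    expect_identical(got$total, suite$total[i], label = suite$reported[i])
    expect_identical(got$standardized,
                     render_standardized(suite$major[i], suite$minor[i]),
                     label = suite$reported[i])
  }
})

test_that("n-gram-shaped mentions are detected", {
  shapes <- list(
    list(txt = "major 4 minor 5", major = 4L, minor = 5L),
    list(txt = "gleason 4 + 5", major = 4L, minor = 5L),
    list(txt = "major 4 + minor 3", major = 4L, minor = 3L),
    list(txt = "gleason 4;4", major = 4L, minor = 4L)
  )
  for (s in shapes) {
    cand <- find_candidates(list(episode_id = "x", text = s$txt))
    expect_identical(nrow(cand), 1L, label = s$txt)
    expect_identical(cand$major, s$major, label = s$txt)
    expect_identical(cand$minor, s$minor, label = s$txt)
  }
})

test_that("candidates carry spans, sections and conflict flags", {
  rep <- list(episode_id = "x", text = paste(
    "CLINICAL HISTORY: PRIOR GLEASON SCORE 3 + 2.",
    "PATHOLOGICAL DIAGNOSIS: GLEASON 4, 3."))
  cand <- find_candidates(rep)
  expect_identical(nrow(cand), 2L)
  expect_identical(cand$section, c("clinical_history", "pathological_diagnosis"))
  expect_true(all(diff(cand$start) > 0))
  seg <- segment_sections(rep)
  expect_identical(substring(seg$text, cand$start, cand$end), cand$raw)

  conflicted <- find_candidates(list(episode_id = "y",
                                     text = "gleason 4 + 4 = 7"))
  expect_true(conflicted$conflict)
})

test_that("numeric decoys never parse as scores", {
  for (d in decoy_strings()) {
    cand <- find_candidates(list(episode_id = "d", text = d))
    expect_identical(nrow(cand), 0L, label = d)
  }
  # out-of-range components are discarded, not clamped
  expect_identical(nrow(find_candidates(list(episode_id = "r",
                                             text = "gleason 7 + 9"))), 0L)
  expect_identical(nrow(find_candidates(list(episode_id = "r2",
                                             text = "major 8 minor 6"))), 0L)
})

test_that("strip_non_numeric keeps digits in order", {
  expect_identical(strip_non_numeric("major 4 + minor 3"), c(4L, 3L))
  expect_identical(strip_non_numeric("abc"), integer(0))
  expect_identical(strip_non_numeric("5 plus 4 equals 9"), c(5L, 4L, 9L))
})

test_that("select_candidate takes the latter mention by default", {
  rep <- list(episode_id = "x", text = paste(
    "CLINICAL HISTORY: GLEASON 3 + 2.",
    "PATHOLOGICAL DIAGNOSIS: GLEASON 3 + 3 = 6 OR 3 + 3."))
  cand <- find_candidates(rep)
  latter <- select_candidate(cand, take_latter = TRUE)
  expect_identical(c(latter$major, latter$minor), c(3L, 3L))
  first <- select_candidate(cand, take_latter = FALSE)
  expect_identical(c(first$major, first$minor), c(3L, 2L))
  expect_null(select_candidate(cand[0, ]))
  single <- select_candidate(cand[1, ])
  expect_identical(single$start, cand$start[1])
})

test_that("components-bearing candidates outrank total-only mentions", {
  rep <- list(episode_id = "x", text = paste(
    "CLINICAL HISTORY: GLEASON 4, 3.",
    "PATHOLOGICAL DIAGNOSIS: GLEASON SCORE 7."))
  sel <- select_candidate(find_candidates(rep), take_latter = TRUE)
  expect_identical(c(sel$major, sel$minor), c(4L, 3L))
})

test_that("compute_total and render_standardized invert parse_standardized", {
  expect_identical(compute_total(3, 4), 7L)
  expect_identical(compute_total(1, 1), 2L)
  expect_identical(compute_total(5, 5), 10L)
  expect_error(compute_total(0, 4), class = "gleason_validation_error")
  expect_error(compute_total(3, 6), class = "gleason_validation_error")
  expect_identical(render_standardized(4, 4), "4 + 4 = 8")
  expect_identical(render_standardized(4, 3), "4 + 3 = 7")
  expect_identical(render_standardized(1, 1), "1 + 1 = 2")
  for (M in 1:5) for (m in 1:5) {
    parsed <- parse_standardized(render_standardized(M, m))
    expect_identical(c(parsed$major, parsed$minor, parsed$total),
                     c(M, m, M + m))
  }
  expect_error(parse_standardized("4+3=7"), class = "gleason_validation_error")
})

test_that("extract_knowledge runs the full pipeline on the worked example", {
  rep <- read_reports(path_example_report(), layout = "csv",
                      text_col = "report_text")
  row <- extract_knowledge(rep[1, ])
  expect_identical(row$episode_id, "ABC1234")
  expect_identical(row$major, 4L)
  expect_identical(row$minor, 3L)
  expect_identical(row$total, 7L)
  expect_identical(row$standardized, "4 + 3 = 7")
  expect_identical(row$risk, "intermediate")
  expect_identical(row$status, "ok")
})

test_that("extract_knowledge statuses cover score-free, incomplete and conflict", {
  empty <- extract_knowledge(list(episode_id = "e", text = ""))
  expect_identical(empty$status, "no_score_found")
  expect_true(is.na(empty$risk))

  total_only <- extract_knowledge(list(episode_id = "t",
                                       text = "gleason score 7"))
  expect_identical(total_only$status, "incomplete")
  expect_identical(total_only$total, 7L)
  expect_true(is.na(total_only$major) && is.na(total_only$minor))
  expect_identical(total_only$risk, "intermediate")
  expect_true(is.na(total_only$standardized))

  conflict <- extract_knowledge(list(episode_id = "c",
                                     text = "gleason 4 + 4 = 7"))
  expect_identical(conflict$status, "conflict")
  # computed total is authoritative over the stated one
  expect_identical(conflict$total, 8L)
  expect_identical(conflict$risk, "high")
  expect_true(is.na(conflict$standardized))
})

test_that("misspelled keywords still drive extraction", {
  for (kw in c("GLEESON", "GLEASEN")) {
    row <- extract_knowledge(list(episode_id = "m",
                                  text = paste(kw, "4, 3")))
    expect_identical(row$standardized, "4 + 3 = 7", label = kw)
  }
})

test_that("grammar rules compile and carry roles for every capture group", {
  gr <- gleason_grammar()
  expect_gte(nrow(gr), 8L)
  for (r in seq_len(nrow(gr))) {
    m <- regexpr(gr$pattern[r], "gleason 4 + 3 = 7", perl = TRUE)
    expect_false(is.null(m)) # pattern compiled
    expect_true(all(gr$roles[[r]] %in% c("major", "minor", "total")))
  }
})
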