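knowledge_row <- function(id, M = NA, m = NA, status = NULL) {
  M <- if (is.na(M)) NA_integer_ else as.integer(M)
  m <- if (is.na(m)) NA_integer_ else as.integer(m)
  total <- if (is.na(M) || is.na(m)) NA_integer_ else M + m
  tibble::tibble(
    episode_id = id, major = M, minor = m, total = total,
    standardized = if (!is.na(total)) render_standardized(M, m) else NA_character_,
    risk = if (!is.na(total)) as.character(classify_risk(total)) else NA_character_,
    status = if (!is.null(status)) status
             else if (!is.na(total)) "ok" else "no_score_found")
}

test_that("confusion counts implement the exact-match rule", {
  truth <- dplyr::bind_rows(
    knowledge_row("a", 4, 3), knowledge_row("b", 3, 3),
    knowledge_row("c", 5, 4), knowledge_row("d"), knowledge_row("e"))
  pred <- dplyr::bind_rows(
    knowledge_row("a", 4, 3),       # exact match -> tp
    knowledge_row("b", 3, 4),       # wrong minor -> fn
    knowledge_row("c"),             # missed -> fn
    knowledge_row("d", 2, 2),       # fabricated -> fp
    knowledge_row("e"))             # both absent -> tn
  cm <- confusion_from_pairs(pred, truth)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(1L, 2L, 1L, 1L))
  expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, nrow(truth))

  expect_error(confusion_from_pairs(pred[1:3, ], truth),
               class = "gleason_validation_error")
})

test_that("tp + fn equals the number of truth-positive reports", {
  set.seed(17)
  for (rep_i in 1:10) {
    n <- 30L
    truth <- dplyr::bind_rows(lapply(1:n, function(i) {
      if (stats::runif(1) < 0.2) knowledge_row(sprintf("r%02d", i))
      else knowledge_row(sprintf("r%02d", i), sample(1:5, 1), sample(1:5, 1))
    }))
    pred <- dplyr::bind_rows(lapply(1:n, function(i) {
      if (stats::runif(1) < 0.3) knowledge_row(sprintf("r%02d", i))
      else knowledge_row(sprintf("r%02d", i), sample(1:5, 1), sample(1:5, 1))
    }))
    cm <- confusion_from_pairs(pred, truth)
    expect_identical(cm$tp + cm$fn,
                     sum(!is.na(truth$major)))
    expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, n)
  }
})

test_that("precision and recall reproduce the published confusion counts", {
  first_output <- structure(list(tp = 984L, tn = 0L, fp = 0L, fn = 16L),
                            class = "confusion_counts")
  expect_identical(precision(first_output), 1)
  expect_identical(recall(first_output), 0.984)
  expect_identical(round(recall(first_output), 2), 0.98)

  validation <- structure(list(tp = 988L, tn = 0L, fp = 0L, fn = 12L),
                          class = "confusion_counts")
  expect_identical(recall(validation), 0.988)

  degenerate <- structure(list(tp = 0L, tn = 5L, fp = 0L, fn = 0L),
                          class = "confusion_counts")
  expect_true(is.na(precision(degenerate)))
  expect_true(is.na(recall(degenerate)))
})

test_that("f_score is the harmonic mean with its boundary behaviour", {
  expect_identical(round(f_score(1.00, 0.984), 2), 0.99)
  expect_identical(f_score(1, 1), 1)
  expect_identical(f_score(0.5, 0.5), 0.5)
  expect_true(is.na(f_score(0, 0)))
  expect_true(is.na(f_score(NA_real_, 1)))
})

test_that("f_score lies between precision and recall and is symmetric", {
  grid <- expand.grid(p = seq(0.05, 1, by = 0.19), r = seq(0.05, 1, by = 0.19))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; r <- grid$r[i]
    f <- f_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
    expect_equal(f, f_score(r, p))
    expect_identical(f == 1, p == 1 && r == 1)
  }
})

test_that("per-class one-vs-rest metrics match a hand-computed oracle", {
  set.seed(23)
  n <- 30
  ids <- sprintf("p%02d", 1:n)
  truth <- dplyr::bind_rows(lapply(1:n, function(i)
    knowledge_row(ids[i], sample(1:5, 1), sample(1:5, 1))))
  pred <- truth
  flip <- sample(n, 8)
  for (i in flip) {
    pred[i, c("major", "minor", "total", "standardized", "risk")] <-
      knowledge_row(ids[i], sample(1:5, 1), sample(1:5, 1))[
        , c("major", "minor", "total", "standardized", "risk")]
  }
  res <- per_class_metrics(pred, truth)
  for (cls in names(res$per_class)) {
    tp <- sum(pred$risk == cls & truth$risk == cls)
    fp <- sum(pred$risk == cls & truth$risk != cls)
    fn <- sum(pred$risk != cls & truth$risk == cls)
    p_oracle <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    r_oracle <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    expect_equal(res$per_class[[cls]]$precision, p_oracle, label = cls)
    expect_equal(res$per_class[[cls]]$recall, r_oracle, label = cls)
  }
  fs <- vapply(res$per_class, `[[`, numeric(1), "f_score")
  expect_equal(res$macro_f, mean(fs[!is.na(fs)]))
})

test_that("macro F averages the published per-class values to 0.99", {
  expect_identical(round(macro_f(c(0.98, 1.00, 1.00)), 2), 0.99)
  expect_identical(macro_f(c(1, 1, 1)), 1)
  expect_true(is.na(macro_f(NA_real_)))
})

test_that("all-correct predictions give perfect class metrics", {
  truth <- dplyr::bind_rows(
    knowledge_row("a", 3, 3), knowledge_row("b", 3, 4),
    knowledge_row("c", 4, 4))
  res <- per_class_metrics(truth, truth)
  expect_identical(res$macro_f, 1)
  expect_identical(res$macro_precision, 1)
  expect_identical(res$macro_recall, 1)
})

test_that("frequency_summary reproduces published high-risk percentages", {
  # study-column counts: 176 of 5+4=9, 175 of 3+3=6, 164 of 4+3=7,
  # 147 of 3+4=7, 142 of 4+4=8, 196 Others none of which reach 8
  study <- make_knowledge_records(
    c("5 + 4 = 9", "3 + 3 = 6", "4 + 3 = 7", "3 + 4 = 7", "4 + 4 = 8",
      "2 + 3 = 5", "3 + 2 = 5", "2 + 2 = 4", "1 + 2 = 3"),
    c(176, 175, 164, 147, 142, 60, 60, 50, 26))
  fs <- frequency_summary(study, top_k = 5)
  expect_identical(fs$total, 1000L)
  expect_identical(fs$entries$score[1:2], c("5 + 4 = 9", "3 + 3 = 6"))
  expect_identical(fs$entries$count,
                   c(176L, 175L, 164L, 147L, 142L))
  expect_identical(fs$others_count, 196L)
  expect_identical(fs$high_risk_count, 318L)
  expect_identical(round(fs$high_risk_percent, 1), 31.8)

  validation <- make_knowledge_records(
    c("3 + 3 = 6", "3 + 4 = 7", "4 + 3 = 7", "4 + 4 = 8", "4 + 5 = 9",
      "2 + 3 = 5", "3 + 2 = 5"),
    c(377, 194, 149, 100, 74, 56, 50))
  fv <- frequency_summary(validation, top_k = 5)
  expect_identical(fv$high_risk_count, 174L)
  expect_identical(round(fv$high_risk_percent, 1), 17.4)
})

test_that("frequency_summary counts and percents are consistent", {
  empty <- frequency_summary(knowledge_row("x")[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(nrow(empty$entries), 0L)

  set.seed(41)
  recs <- dplyr::bind_rows(lapply(1:100, function(i)
    knowledge_row(sprintf("s%03d", i), sample(1:5, 1), sample(1:5, 1))))
  fs <- frequency_summary(recs, top_k = 5)
  expect_identical(sum(fs$entries$count) + fs$others_count, fs$total)
  expect_equal(sum(fs$entries$percent) + fs$others_percent, 100)
  # counting oracle
  tab <- sort(table(recs$standardized), decreasing = TRUE)
  expect_identical(sum(fs$entries$count), sum(head(sort(as.integer(tab), decreasing = TRUE), 5)))
  expect_identical(fs$high_risk_count, sum(recs$total >= 8))
})

test_that("evaluation_report bundles counts and metrics as JSON-ready lists", {
  truth <- dplyr::bind_rows(
    knowledge_row("a", 4, 3), knowledge_row("b", 3, 3), knowledge_row("c", 5, 4))
  pred <- dplyr::bind_rows(
    knowledge_row("a", 4, 3), knowledge_row("b", 3, 3), knowledge_row("c", 4, 4))
  rep <- evaluation_report(pred, truth)
  expect_identical(rep$counts$tp, 2L)
  expect_identical(rep$counts$fn, 1L)
  expect_equal(rep$recall, 2 / 3)
  expect_equal(rep$rounded$recall, 0.67)
  expect_true(all(c("precision", "recall", "f_score") %in% names(rep$macro)))
})
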