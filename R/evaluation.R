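new_confusion <- function(tp, tn, fp, fn) {
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$tp, " TN", x$tn, " FP", x$fp, " FN", x$fn,
      "\n")
  invisible(x)
}

#' Exact-match confusion counts for extracted vs manually coded scores
#'
#' Joins predictions to the gold-standard manual coding on `episode_id` and
#' tallies the exact-match confusion matrix on the (major, minor, total)
#' triple:
#' \itemize{
#'   \item TP: truth has a score and the predicted triple matches it exactly;
#'   \item FN: truth has a score and the prediction is absent or differs;
#'   \item FP: truth has no score but a score was extracted;
#'   \item TN: neither side has a score.
#' }
#'
#' @param predicted Knowledge tibble (from [extract_corpus()]).
#' @param truth Gold-standard tibble with `episode_id`, `major`, `minor`,
#'   `total` (NA where the report truly has no score).
#' @return A `confusion_counts` object (`tp`, `tn`, `fp`, `fn`; they sum to
#'   the number of evaluated reports).
#' @export
confusion_from_pairs <- function(predicted, truth) {
  only_pred <- setdiff(predicted$episode_id, truth$episode_id)
  only_truth <- setdiff(truth$episode_id, predicted$episode_id)
  if (length(only_pred) > 0 || length(only_truth) > 0) {
    abort(paste0("unmatched episode_id(s): ",
                 paste(head(c(only_pred, only_truth), 10), collapse = ", ")),
          class = "gleason_validation_error")
  }
  m <- dplyr::inner_join(predicted, truth, by = "episode_id",
                         suffix = c("_pred", "_true"))
  truth_has <- !is.na(m$major_true) & !is.na(m$minor_true)
  pred_has <- !is.na(m$major_pred) & !is.na(m$minor_pred)
  exact <- truth_has & pred_has &
    m$major_pred == m$major_true & m$minor_pred == m$minor_true &
    m$total_pred == m$total_true
  new_confusion(
    tp = sum(exact),
    fn = sum(truth_has & !exact),
    fp = sum(!truth_has & pred_has),
    tn = sum(!truth_has & !pred_has)
  )
}

#' Precision, recall and F-score from confusion counts
#'
#' Precision is TP/(TP+FP) (positive predictive value), recall is
#' TP/(TP+FN) (sensitivity), and the F-score is their harmonic mean
#' 2PR/(P+R). A zero denominator leaves the metric undefined (`NA`), which
#' is reported as such and never coerced to 0.
#'
#' @param counts A `confusion_counts` object.
#' @return Numeric scalar in `[0, 1]`, or `NA` when undefined.
#' @export
precision <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0L) NA_real_ else counts$tp / d
}

#' @rdname precision
#' @export
recall <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0L) NA_real_ else counts$tp / d
}

#' @rdname precision
#' @param p,r Precision and recall values.
#' @export
f_score <- function(p, r) {
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

metric_set <- function(counts) {
  p <- precision(counts)
  r <- recall(counts)
  structure(list(precision = p, recall = r, f_score = f_score(p, r),
                 counts = counts),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else formatC(v, digits = digits,
                                                            format = "f")
  cat("precision", fmt(x$precision), " recall", fmt(x$recall),
      " F-score", fmt(x$f_score), "\n")
  invisible(x)
}

#' Corpus-level exact-match metrics
#'
#' @inheritParams confusion_from_pairs
#' @return A `metric_set`: precision, recall, F-score plus the underlying
#'   confusion counts.
#' @export
evaluate_extraction <- function(predicted, truth) {
  metric_set(confusion_from_pairs(predicted, truth))
}

#' One-vs-rest risk-category metrics and macro averages
#'
#' Maps both sides to risk categories (low/intermediate/high) via the
#' guideline rule, computes a one-vs-rest confusion matrix and metric set
#' per category, and macro-averages: the macro F-score is the arithmetic
#' mean of the defined per-class F-scores (precision and recall likewise).
#' A category present on neither side is skipped with a message.
#'
#' @inheritParams confusion_from_pairs
#' @return List with `per_class` (named list of `metric_set`),
#'   `macro_precision`, `macro_recall`, `macro_f`, and `class_counts`
#'   (predicted and truth frequencies per category).
#' @export
per_class_metrics <- function(predicted, truth) {
  m <- dplyr::inner_join(predicted, truth, by = "episode_id",
                         suffix = c("_pred", "_true"))
  if (!"risk_true" %in% names(m)) {
    if ("risk" %in% names(truth)) {
      m$risk_true <- truth$risk[match(m$episode_id, truth$episode_id)]
    } else {
      m$risk_true <- as.character(classify_risk(m$total_true))
    }
  }
  if (!"risk_pred" %in% names(m)) {
    m$risk_pred <- as.character(classify_risk(m$total_pred))
  }
  per_class <- list()
  class_counts <- tibble(risk = character(), predicted = integer(),
                         truth = integer())
  for (cls in RISK_LEVELS) {
    pred_is <- !is.na(m$risk_pred) & m$risk_pred == cls
    true_is <- !is.na(m$risk_true) & m$risk_true == cls
    class_counts <- rbind(class_counts,
                          tibble(risk = cls, predicted = sum(pred_is),
                                 truth = sum(true_is)))
    if (!any(pred_is) && !any(true_is)) {
      message("risk category absent from both sides, skipped: ", cls)
      next
    }
    per_class[[cls]] <- metric_set(new_confusion(
      tp = sum(pred_is & true_is),
      fp = sum(pred_is & !true_is),
      fn = sum(!pred_is & true_is),
      tn = sum(!pred_is & !true_is)
    ))
  }
  mean_def <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }
  list(
    per_class = per_class,
    macro_precision = mean_def(vapply(per_class, `[[`, numeric(1), "precision")),
    macro_recall = mean_def(vapply(per_class, `[[`, numeric(1), "recall")),
    macro_f = mean_def(vapply(per_class, `[[`, numeric(1), "f_score")),
    class_counts = class_counts
  )
}

#' Macro-averaged F-score from per-class values
#'
#' Arithmetic mean of the per-class F-scores (each class's F added up, then
#' divided by the number of classes measured).
#'
#' @param f_values Numeric vector of per-class F-scores.
#' @return Numeric scalar.
#' @examples
#' macro_f(c(0.98, 1.00, 1.00))
#' @export
macro_f <- function(f_values) {
  f_values <- f_values[!is.na(f_values)]
  if (length(f_values) == 0L) return(NA_real_)
  mean(f_values)
}

#' Score-frequency and high-risk summary
#'
#' Tabulates the standardized Gleason scores of successfully extracted
#' (`status == "ok"`) records: the `top_k` most frequent scores with their
#' counts and percentages of the full total, the remaining scores pooled as
#' "Others", and the count and percentage of high-risk scores (total >= 8)
#' over all records, including those pooled in Others.
#'
#' @param records Knowledge tibble.
#' @param top_k Number of individually listed scores (default 5).
#' @return List of class `frequency_table`: `entries` (tibble `score`,
#'   `count`, `percent`), `others_count`, `others_percent`, `total`,
#'   `high_risk_count`, `high_risk_percent`.
#' @export
frequency_summary <- function(records, top_k = 5) {
  ok <- records[records$status == "ok", , drop = FALSE]
  total <- nrow(ok)
  if (total == 0L) {
    return(structure(list(
      entries = tibble(score = character(), count = integer(),
                       percent = numeric()),
      others_count = 0L, others_percent = NA_real_, total = 0L,
      high_risk_count = 0L, high_risk_percent = NA_real_
    ), class = "frequency_table"))
  }
  tab <- table(ok$standardized)
  freq <- tibble(score = names(tab), count = as.integer(tab))
  freq <- freq[order(-freq$count, freq$score), , drop = FALSE]
  k <- min(as.integer(top_k), nrow(freq))
  top <- freq[seq_len(k), , drop = FALSE]
  top$percent <- 100 * top$count / total
  others <- sum(freq$count) - sum(top$count)
  high <- sum(ok$total >= 8L)
  structure(list(
    entries = top,
    others_count = as.integer(others),
    others_percent = 100 * others / total,
    total = total,
    high_risk_count = as.integer(high),
    high_risk_percent = 100 * high / total
  ), class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, digits = 1, ...) {
  cat("<frequency_table> n =", x$total, "\n")
  for (i in seq_len(nrow(x$entries))) {
    cat(sprintf("  %-12s %5d  %5.*f%%\n", x$entries$score[i],
                x$entries$count[i], digits, x$entries$percent[i]))
  }
  if (x$total > 0) {
    cat(sprintf("  %-12s %5d  %5.*f%%\n", "Others", x$others_count, digits,
                x$others_percent))
    cat(sprintf("  High-risk (>= 8) %d (%.*f%%)\n", x$high_risk_count, digits,
                x$high_risk_percent))
  }
  invisible(x)
}

#' Frequency table as a tibble
#'
#' @param x A `frequency_table`.
#' @param ... Unused.
#' @return Tibble with the top scores, an Others row and a high-risk row.
#' @method as_tibble frequency_table
#' @export
as_tibble.frequency_table <- function(x, ...) {
  rbind(
    x$entries,
    tibble(score = "Others", count = x$others_count,
           percent = x$others_percent),
    tibble(score = "High-Risk GS >= 8", count = x$high_risk_count,
           percent = x$high_risk_percent)
  )
}

#' Optional chi-square homogeneity check of risk-category frequencies
#'
#' Compares the predicted and manually coded risk-category frequency
#' distributions with Pearson's chi-square test. This comparison is this
#' package's own choice of homogeneity check and is not part of the
#' extraction algorithm or its headline evaluation.
#'
#' @inheritParams confusion_from_pairs
#' @return `htest` object from [stats::chisq.test()].
#' @export
risk_homogeneity_test <- function(predicted, truth) {
  pcm <- per_class_metrics(predicted, truth)
  counts <- pcm$class_counts
  stats::chisq.test(rbind(counts$predicted, counts$truth))
}

#' Full evaluation report
#'
#' Bundles the corpus-level exact-match metrics and the per-risk-class
#' macro metrics into one JSON-serializable list.
#'
#' @inheritParams confusion_from_pairs
#' @param round_digits Display rounding applied to the `rounded` copy of
#'   each metric (full-precision values are always included). Default 2.
#' @return Nested list: `counts`, `precision`, `recall`, `f_score`,
#'   `per_class`, `macro`.
#' @export
evaluation_report <- function(predicted, truth, round_digits = 2) {
  ms <- evaluate_extraction(predicted, truth)
  pcm <- per_class_metrics(predicted, truth)
  rd <- function(v) if (is.na(v)) NULL else round(v, round_digits)
  per_class <- lapply(pcm$per_class, function(m) list(
    precision = m$precision, recall = m$recall, f_score = m$f_score,
    rounded = list(precision = rd(m$precision), recall = rd(m$recall),
                   f_score = rd(m$f_score))
  ))
  list(
    counts = list(tp = ms$counts$tp, tn = ms$counts$tn, fp = ms$counts$fp,
                  fn = ms$counts$fn),
    precision = ms$precision, recall = ms$recall, f_score = ms$f_score,
    rounded = list(precision = rd(ms$precision), recall = rd(ms$recall),
                   f_score = rd(ms$f_score)),
    per_class = per_class,
    macro = list(precision = pcm$macro_precision, recall = pcm$macro_recall,
                 f_score = pcm$macro_f,
                 rounded = list(precision = rd(pcm$macro_precision),
                                recall = rd(pcm$macro_recall),
                                f_score = rd(pcm$macro_f)))
  )
}
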