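# Read a text file as UTF-8, falling back to latin-1 for legacy LIS exports.
read_text_lenient <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    txt <- rawToChar(raw)
    Encoding(txt) <- "latin1"
    txt <- enc2utf8(txt)
  }
  txt
}

#' Read a corpus of narrative reports
#'
#' Reads one narrative report per record from a delimited file (CSV or TSV
#' with RFC-4180 quoting) or from a directory of plain-text files (one
#' report per `.txt` file; the file stem is the episode identifier). Input
#' order is preserved (alphabetical file order for directories) and report
#' text is returned verbatim: no cleaning happens at this layer.
#'
#' @param path File (csv/tsv) or directory (txt_dir) path.
#' @param layout One of `"csv"`, `"tsv"`, `"txt_dir"`.
#' @param id_col,text_col Column names holding the episode identifier and
#'   report text in delimited layouts.
#' @return Tibble with character columns `episode_id`, `text`.
#' @export
read_reports <- function(path, layout = c("csv", "tsv", "txt_dir"),
                         id_col = "episode_id", text_col = "report_text") {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort(paste0("input not found: ", path), class = "gleason_io_error")
  }
  if (layout == "txt_dir") {
    if (!dir.exists(path)) {
      abort(paste0("not a directory: ", path), class = "gleason_io_error")
    }
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    out <- tibble(
      episode_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, read_text_lenient, character(1), USE.NAMES = FALSE)
    )
  } else {
    delim <- if (layout == "csv") "," else "\t"
    tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                             locale = readr::locale(encoding = "UTF-8"),
                             progress = FALSE, show_col_types = FALSE)
    missing_cols <- setdiff(c(id_col, text_col), names(tab))
    if (length(missing_cols) > 0) {
      abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
            class = "gleason_schema_error")
    }
    out <- tibble(
      episode_id = as.character(tab[[id_col]]),
      text = as.character(tab[[text_col]])
    )
  }
  out$text[is.na(out$text)] <- ""
  dup <- unique(out$episode_id[duplicated(out$episode_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate episode_id(s): ", paste(dup, collapse = ", ")),
          class = "gleason_validation_error")
  }
  if (any(is.na(out$episode_id) | !nzchar(out$episode_id))) {
    abort("empty episode_id", class = "gleason_validation_error")
  }
  out
}

validate_knowledge <- function(records) {
  need <- c("episode_id", "major", "minor", "total", "standardized", "risk",
            "status")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("knowledge table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gleason_schema_error")
  }
  bad_status <- setdiff(unique(records$status), KNOWLEDGE_STATUS)
  if (length(bad_status) > 0) {
    abort(paste0("unknown status value(s): ", paste(bad_status, collapse = ", ")),
          class = "gleason_validation_error")
  }
  ok <- records$status == "ok"
  if (any(ok & (is.na(records$major) | is.na(records$minor) |
                is.na(records$total)))) {
    abort("status ok requires major, minor and total",
          class = "gleason_validation_error")
  }
  if (any(ok & records$total != records$major + records$minor)) {
    abort("status ok requires total = major + minor",
          class = "gleason_validation_error")
  }
  invisible(records)
}

#' Write a discovered-knowledge table
#'
#' Writes one CSV row per report with columns `episode_id`, `major`,
#' `minor`, `total`, `standardized`, `risk`, `status`; absent values are
#' written empty. [read_knowledge()] round-trips the file losslessly.
#'
#' @param records Knowledge tibble, e.g. from [extract_corpus()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_knowledge <- function(records, path) {
  validate_knowledge(records)
  readr::write_csv(records[, c("episode_id", "major", "minor", "total",
                               "standardized", "risk", "status")],
                   path, na = "")
  invisible(records)
}

#' Read a discovered-knowledge table written by [write_knowledge()]
#'
#' @param path CSV path.
#' @return Knowledge tibble with typed columns.
#' @export
read_knowledge <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input not found: ", path), class = "gleason_io_error")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(
    episode_id = "c", major = "i", minor = "i", total = "i",
    standardized = "c", risk = "c", status = "c"
  ), na = "", progress = FALSE, show_col_types = FALSE)
  validate_knowledge(tab)
  tab
}

#' Write / read a ground-truth table from the synthetic generator
#'
#' @param truth Truth tibble from [generate_corpus()].
#' @param path CSV path.
#' @return `write_truth`: input invisibly; `read_truth`: truth tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path, na = "")
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input not found: ", path), class = "gleason_io_error")
  }
  readr::read_csv(path, col_types = readr::cols(
    episode_id = "c", major = "i", minor = "i", total = "i", risk = "c",
    format_id = "c", has_history_duplicate = "l"
  ), na = "", progress = FALSE, show_col_types = FALSE)
}
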