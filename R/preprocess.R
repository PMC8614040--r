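#' Normalize narrative report text
#'
#' Lowercases the text and collapses every run of whitespace (spaces, tabs,
#' newlines) to a single space. All characters that carry meaning for score
#' extraction -- digits and the symbols `+ = ( ) / ; , :` -- are preserved
#' verbatim; no characters are deleted. Idempotent.
#'
#' @param text Character vector of raw report text.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_text("GLEASON 4, 3")
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text))
  out <- tolower(text)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

#' Default Gleason spelling-variant map
#'
#' Misspellings of the keyword "gleason" seen in dictated pathology reports
#' (e.g. "gleeson", "gleasen"), each mapped to the canonical form. Shipped as
#' an editable plain-text file (`variant<TAB>canonical`, one entry per line).
#'
#' @param path Optional path to an alternative variant-map file.
#' @return Named character vector: names are variants, values canonical forms.
#' @export
default_variant_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variant_map.tsv", package = "gleasonminer")
  }
  if (!file.exists(path)) {
    abort(paste0("variant map file not found: ", path), class = "gleason_io_error")
  }
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("variant", "canonical"),
                           stringsAsFactors = FALSE)
  setNames(tolower(tab$canonical), tolower(tab$variant))
}

#' Normalize the spelling of a single token
#'
#' Maps known misspelled variants of "gleason" to the canonical spelling;
#' any other token is returned unchanged. Idempotent.
#'
#' @param token Character vector of lowercased tokens.
#' @param variant_map Named character vector as from [default_variant_map()].
#' @return Character vector of normalized tokens.
#' @examples
#' normalize_spelling("gleeson")
#' @export
normalize_spelling <- function(token, variant_map = default_variant_map()) {
  stopifnot(is.character(token))
  hit <- token %in% names(variant_map)
  token[hit] <- unname(variant_map[token[hit]])
  token
}

#' Apply the spelling-variant map across a full text
#'
#' Word-boundary replacement of every variant with its canonical form, used
#' on whole normalized report text before grammar matching.
#'
#' @inheritParams normalize_spelling
#' @param text Normalized (lowercased) text.
#' @return Text with variants canonicalized.
#' @export
apply_variant_map <- function(text, variant_map = default_variant_map()) {
  for (v in names(variant_map)) {
    text <- gsub(paste0("\\b", v, "\\b"), variant_map[[v]], text, perl = TRUE)
  }
  text
}

#' Tokenize normalized text
#'
#' Splits text into words, numbers and the standalone symbols
#' `+ = ( ) / ; , :`. Each symbol becomes its own token; "do not stop"
#' yields exactly three tokens. Source character spans are retained.
#'
#' @param text A single normalized string.
#' @return A tibble with columns `token`, `start`, `end` (1-based,
#'   inclusive character offsets into `text`).
#' @examples
#' tokenize("gleason 4 + 3")$token
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+(?:\\.[0-9]+)?|[+=()/;,:]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tibble(
    token = substring(text, starts, starts + lens - 1L),
    start = starts,
    end = starts + lens - 1L
  )
}

# Tokens that must never be removed as stopwords: score vocabulary,
# numerals and the arithmetic symbols the extractor depends on.
protected_tokens <- function() {
  c("major", "minor", "gleason", "score", "pattern", "+", "=",
    as.character(0:10))
}

#' Default English stoplist
#'
#' A standard English stopword list shipped as a plain-text data file, with
#' the extraction-critical tokens (`major`, `minor`, `gleason`, `score`,
#' `pattern`, numerals, `+`, `=`) excluded so stopword removal can never
#' delete score evidence.
#'
#' @param path Optional path to an alternative stoplist file (one lowercased
#'   word per line, `#` comments allowed).
#' @return Character vector of stopwords.
#' @export
default_stoplist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stoplist.txt", package = "gleasonminer")
  }
  if (!file.exists(path)) {
    abort(paste0("stoplist file not found: ", path), class = "gleason_io_error")
  }
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  words <- trimws(words)
  words[nzchar(words) & !startsWith(words, "#")]
}

#' Remove stopwords from a token sequence
#'
#' @param tokens A token tibble from [tokenize()] or a character vector.
#' @param stoplist Lowercased stopwords; must not contain any protected token
#'   (numerals, `+`, `=`, `major`, `minor`, `gleason`, `score`, `pattern`).
#' @return Tokens with stoplist members removed, order preserved.
#' @export
remove_stopwords <- function(tokens, stoplist = default_stoplist()) {
  bad <- intersect(tolower(stoplist), protected_tokens())
  if (length(bad) > 0) {
    abort(paste0("stoplist contains protected token(s): ",
                 paste(bad, collapse = ", ")),
          class = "gleason_validation_error")
  }
  if (is.character(tokens)) {
    return(tokens[!(tokens %in% stoplist)])
  }
  tokens[!(tokens$token %in% stoplist), , drop = FALSE]
}

# Section headings in the order they appear in routine biopsy reports.
SECTION_HEADINGS <- c(
  clinical_history = "clinical history",
  macroscopy = "macroscopy",
  pathological_diagnosis = "pathological diagnosis"
)

#' Segment a report into its standard sections
#'
#' Splits normalized report text at the first occurrence of each of the
#' headings CLINICAL HISTORY, MACROSCOPY and PATHOLOGICAL DIAGNOSIS
#' (case handled by normalization; an optional trailing colon is part of the
#' heading). Text before the first heading, or the whole text when no heading
#' is present, is labelled `unsectioned`. Sections cover the text exactly:
#' concatenating the section texts in order reproduces the full normalized
#' text.
#'
#' @param report A list or one-row data frame with `episode_id` and `text`
#'   (raw text; it is normalized and spelling-mapped here).
#' @param variant_map Spelling-variant map applied after normalization.
#' @return An object of class `sectioned_report`: list with `episode_id`,
#'   `text` (normalized full text) and `sections`, a tibble with columns
#'   `section`, `start`, `end`, `text`.
#' @export
segment_sections <- function(report, variant_map = default_variant_map()) {
  episode_id <- as.character(report$episode_id)
  norm <- apply_variant_map(normalize_text(as.character(report$text)[1]),
                            variant_map)
  hits <- tibble(section = character(), start = integer())
  for (lab in names(SECTION_HEADINGS)) {
    pat <- paste0("\\b", SECTION_HEADINGS[[lab]], "\\b:?")
    m <- regexpr(pat, norm, perl = TRUE)
    if (m[1] != -1L) {
      hits <- rbind(hits, tibble(section = lab, start = as.integer(m)))
    }
  }
  n <- nchar(norm)
  if (nrow(hits) == 0L) {
    sections <- tibble(section = "unsectioned", start = 1L, end = n,
                       text = norm)
  } else {
    hits <- hits[order(hits$start), , drop = FALSE]
    if (hits$start[1] > 1L) {
      hits <- rbind(tibble(section = "unsectioned", start = 1L), hits)
    }
    ends <- c(hits$start[-1] - 1L, n)
    sections <- tibble(
      section = hits$section,
      start = hits$start,
      end = ends,
      text = substring(norm, hits$start, ends)
    )
  }
  if (n == 0L) {
    sections <- tibble(section = "unsectioned", start = 1L, end = 0L,
                       text = "")
  }
  structure(
    list(episode_id = episode_id, text = norm, sections = sections),
    class = "sectioned_report"
  )
}

#' @export
print.sectioned_report <- function(x, ...) {
  cat("<sectioned_report> episode", x$episode_id, "\n")
  for (i in seq_len(nrow(x$sections))) {
    txt <- x$sections$text[i]
    if (nchar(txt) > 60) txt <- paste0(substr(txt, 1, 57), "...")
    cat(sprintf("  %-24s [%d-%d] %s\n", x$sections$section[i],
                x$sections$start[i], x$sections$end[i], txt))
  }
  invisible(x)
}
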