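#' Light rule-based English stemmer for term-frequency features
#'
#' Strips common inflectional suffixes (plural -s/-es/-ies, -ed, -ing) from
#' alphabetic tokens of four or more characters. Used only on the
#' term-frequency feature path; the score-extraction path never stems, so
#' score-adjacent tokens cannot be corrupted.
#'
#' @param tokens Character vector of lowercased tokens.
#' @return Character vector of stems.
#' @examples
#' stem_tokens(c("biopsies", "showing", "involved", "cores"))
#' @export
stem_tokens <- function(tokens) {
  stopifnot(is.character(tokens))
  out <- tokens
  alpha <- grepl("^[a-z]+$", out) & nchar(out) >= 4L
  out[alpha] <- sub("ies$", "y", out[alpha])
  es <- alpha & grepl("(ss|x|ch|sh)es$", out)
  out[es] <- sub("es$", "", out[es])
  plain_s <- alpha & grepl("[a-z]s$", out) & !grepl("(ss|us|is)$", out)
  out[plain_s] <- sub("s$", "", out[plain_s])
  ing <- alpha & grepl("[a-z]{3}ing$", out)
  out[ing] <- sub("ing$", "", out[ing])
  ed <- alpha & grepl("[a-z]{3}ed$", out)
  out[ed] <- sub("ed$", "", out[ed])
  out
}

#' Generate n-grams from a token sequence
#'
#' Sliding window of width `n` and stride 1 within a single document;
#' windows never cross document boundaries. A document shorter than `n`
#' yields no n-grams. Orders above quadgrams are rejected: by quadgrams the
#' word combinations bearing the score are exhausted.
#'
#' @param tokens Character vector of tokens (or a token tibble from
#'   [tokenize()]).
#' @param n N-gram order, integer in 1-4.
#' @return Character vector of n-grams, tokens joined by single spaces,
#'   in document order; `max(0, length(tokens) - n + 1)` entries.
#' @examples
#' generate_ngrams(c("gleason", "4", "+", "3"), n = 2)
#' @export
generate_ngrams <- function(tokens, n) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  stopifnot(is.character(tokens))
  if (length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1 || n > 4) {
    abort("n-gram order must be an integer in 1-4",
          class = "gleason_validation_error")
  }
  n <- as.integer(n)
  len <- length(tokens)
  if (len < n) return(character(0))
  starts <- seq_len(len - n + 1L)
  vapply(starts, function(s) paste(tokens[s:(s + n - 1L)], collapse = " "),
         character(1))
}

#' Corpus-wide n-gram term frequencies
#'
#' Aggregates n-gram counts over all documents of a corpus (the
#' term-frequency side of a document-term matrix). Deterministic; the total
#' count equals the sum over documents of `max(0, len - n + 1)`.
#'
#' @param corpus List of token character vectors (one per document).
#' @param n N-gram order, 1-4.
#' @return Tibble of class `term_frequency_table` with columns `ngram`,
#'   `count`, sorted by count descending then n-gram text; attribute
#'   `order` = n.
#' @export
term_frequencies <- function(corpus, n) {
  stopifnot(is.list(corpus))
  grams <- unlist(lapply(corpus, generate_ngrams, n = n), use.names = FALSE)
  if (length(grams) == 0L) {
    out <- tibble(ngram = character(), count = integer())
  } else {
    tab <- table(grams)
    out <- tibble(ngram = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$ngram), , drop = FALSE]
  }
  attr(out, "order") <- as.integer(n)
  class(out) <- c("term_frequency_table", class(out))
  out
}

#' Top-k most frequent terms
#'
#' The first `k` entries of the full descending sort of a term-frequency
#' table; ties are broken lexicographically on the joined n-gram text so the
#' ranking is deterministic.
#'
#' @param table A `term_frequency_table` from [term_frequencies()].
#' @param k Number of entries, >= 1; a `k` beyond the table returns the
#'   whole sorted table.
#' @return Tibble `ngram`, `count` with at most `k` rows.
#' @export
top_k_terms <- function(table, k) {
  if (length(k) != 1L || is.na(k) || k < 1) {
    abort("k must be >= 1", class = "gleason_validation_error")
  }
  sorted <- table[order(-table$count, table$ngram), , drop = FALSE]
  head(as_tibble(sorted), as.integer(k))
}

#' Tokenized feature corpus from raw reports
#'
#' Applies the feature-path pre-processing (normalize, spelling map,
#' tokenize, stopword removal, stemming) to each report, yielding the token
#' lists consumed by [term_frequencies()].
#'
#' @param reports Report tibble (`episode_id`, `text`).
#' @param stoplist Stopwords (see [default_stoplist()]).
#' @param stem Apply [stem_tokens()] (default `TRUE`).
#' @param variant_map Spelling-variant map.
#' @return Named list of token character vectors, one per report.
#' @export
feature_corpus <- function(reports, stoplist = default_stoplist(),
                           stem = TRUE, variant_map = default_variant_map()) {
  out <- lapply(seq_len(nrow(reports)), function(i) {
    txt <- apply_variant_map(normalize_text(reports$text[i]), variant_map)
    toks <- tokenize(txt)$token
    toks <- remove_stopwords(toks, stoplist)
    if (stem) toks <- stem_tokens(toks)
    toks
  })
  names(out) <- reports$episode_id
  out
}
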