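#' Extract the digits of a grammar capture, in order
#'
#' Drops every non-numerical character from a captured fragment and returns
#' the remaining digits, left to right, as integers. Used after denominators
#' (`/5`, `/10`) have been stripped by the grammar.
#'
#' @param fragment Character scalar.
#' @return Integer vector (possibly empty).
#' @examples
#' strip_non_numeric("major 4 + minor 3")
#' @export
strip_non_numeric <- function(fragment) {
  stopifnot(is.character(fragment), length(fragment) == 1L)
  digits <- regmatches(fragment, gregexpr("[0-9]", fragment))[[1]]
  as.integer(digits)
}

#' Compute the total Gleason score
#'
#' The total is the sum of the major (most prevalent) and minor (second most
#' prevalent) histological patterns, each graded 1-5.
#'
#' @param major,minor Integer vectors in 1-5.
#' @return Integer vector of totals in 2-10.
#' @examples
#' compute_total(3, 4)
#' @export
compute_total <- function(major, minor) {
  major <- as.integer(major)
  minor <- as.integer(minor)
  bad <- (!is.na(major) & (major < 1L | major > 5L)) |
         (!is.na(minor) & (minor < 1L | minor > 5L))
  if (any(bad)) {
    abort("major and minor patterns must be in 1-5",
          class = "gleason_validation_error")
  }
  major + minor
}

#' Render the standardized Gleason score string
#'
#' @inheritParams compute_total
#' @return Character vector of the form `"M + m = T"` with single spaces.
#' @examples
#' render_standardized(4, 3)
#' @export
render_standardized <- function(major, minor) {
  total <- compute_total(major, minor)
  ifelse(is.na(total), NA_character_,
         sprintf("%d + %d = %d", as.integer(major), as.integer(minor), total))
}

#' Parse a standardized Gleason score string
#'
#' Inverse of [render_standardized()]: `"4 + 3 = 7"` yields major 4,
#' minor 3, total 7.
#'
#' @param x Character vector of `"M + m = T"` strings.
#' @return Tibble with integer columns `major`, `minor`, `total`.
#' @export
parse_standardized <- function(x) {
  m <- regmatches(x, regexec("^([0-9]) \\+ ([0-9]) = ([0-9]{1,2})$", x))
  bad <- vapply(m, length, integer(1)) == 0L & !is.na(x)
  if (any(bad)) {
    abort(paste0("not a standardized score string: ",
                 paste(x[bad], collapse = ", ")),
          class = "gleason_validation_error")
  }
  pick <- function(i) vapply(m, function(g)
    if (length(g) == 4L) as.integer(g[i + 1L]) else NA_integer_, integer(1))
  tibble(major = pick(1), minor = pick(2), total = pick(3))
}

# All matches of one PCRE rule over a text, with capture groups.
match_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  groups <- lapply(seq_along(starts), function(i) {
    g <- character(ncol(cs))
    for (j in seq_len(ncol(cs))) {
      if (cs[i, j] > 0L && cl[i, j] > 0L) {
        g[j] <- substring(text, cs[i, j], cs[i, j] + cl[i, j] - 1L)
      } else {
        g[j] <- NA_character_
      }
    }
    g
  })
  list(start = starts, end = starts + lens - 1L,
       raw = substring(text, starts, starts + lens - 1L), groups = groups)
}

empty_candidates <- function() {
  tibble(
    major = integer(), minor = integer(), stated_total = integer(),
    start = integer(), end = integer(), section = character(),
    format_id = character(), raw = character(), conflict = logical()
  )
}

#' Find every Gleason score mention in a report
#'
#' Runs the extraction grammar over the normalized text of a sectioned
#' report and returns one candidate per surviving match, ordered by span
#' start. Overlapping matches are resolved to the longest match (ties:
#' earliest start, then grammar rule order). Candidates whose major or minor
#' component falls outside 1-5 are discarded (so PSA values, ages and core
#' measurements never parse as scores); a stated total outside 2-10 is
#' dropped from the candidate. A candidate stating a total that differs from
#' the sum of its stated components is flagged as a conflict.
#'
#' @param report A `sectioned_report` from [segment_sections()] (a raw
#'   report list with `episode_id` and `text` is accepted and segmented).
#' @param grammar A grammar from [gleason_grammar()].
#' @return Tibble of candidates: `major`, `minor`, `stated_total`, `start`,
#'   `end`, `section`, `format_id`, `raw`, `conflict`.
#' @examples
#' rep <- list(episode_id = "X1", text = "PATHOLOGICAL DIAGNOSIS: GLEASON 4, 3")
#' find_candidates(segment_sections(rep))
#' @export
find_candidates <- function(report, grammar = gleason_grammar()) {
  if (!inherits(report, "sectioned_report")) {
    report <- segment_sections(report)
  }
  text <- report$text
  if (!nzchar(text)) return(empty_candidates())

  rows <- list()
  for (r in seq_len(nrow(grammar))) {
    hits <- match_all(text, grammar$pattern[r])
    if (is.null(hits)) next
    roles <- grammar$roles[[r]]
    for (i in seq_along(hits$start)) {
      vals <- suppressWarnings(as.integer(hits$groups[[i]]))
      major <- minor <- total <- NA_integer_
      for (j in seq_along(roles)) {
        if (is.na(vals[j])) next
        switch(roles[j],
               major = { major <- vals[j] },
               minor = { minor <- vals[j] },
               total = { total <- vals[j] })
      }
      rows[[length(rows) + 1L]] <- tibble(
        major = major, minor = minor, stated_total = total,
        start = hits$start[i], end = hits$end[i],
        section = NA_character_, format_id = grammar$rule_id[r],
        raw = hits$raw[i], conflict = FALSE, rule_order = r
      )
    }
  }
  if (length(rows) == 0L) return(empty_candidates())
  cand <- dplyr::bind_rows(rows)

  # range guards: components must be 1-5, totals 2-10
  comp_bad <- (!is.na(cand$major) & (cand$major < 1L | cand$major > 5L)) |
              (!is.na(cand$minor) & (cand$minor < 1L | cand$minor > 5L))
  cand <- cand[!comp_bad, , drop = FALSE]
  tot_bad <- !is.na(cand$stated_total) &
             (cand$stated_total < 2L | cand$stated_total > 10L)
  cand$stated_total[tot_bad] <- NA_integer_
  has_pair <- !is.na(cand$major) & !is.na(cand$minor)
  cand <- cand[has_pair | !is.na(cand$stated_total), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_candidates())

  # overlap resolution: longest, then earliest, then rule order
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$rule_order), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(cand$start[i] <= taken_end & cand$end[i] >= taken_start)
    if (!overlaps) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]

  # section label from span start
  sec <- report$sections
  idx <- findInterval(cand$start, sec$start)
  idx[idx < 1L] <- 1L
  cand$section <- sec$section[idx]

  cand$conflict <- !is.na(cand$major) & !is.na(cand$minor) &
    !is.na(cand$stated_total) &
    cand$stated_total != (cand$major + cand$minor)
  cand$rule_order <- NULL
  cand
}

#' Select the reported candidate among all mentions
#'
#' When a report carries more than one Gleason mention (typically a prior
#' score quoted in the clinical history plus the current score in the
#' pathological diagnosis), the extractor reports the latter mention: the
#' last candidate in document order. Candidates carrying both components are
#' preferred over total-only mentions. Setting `take_latter = FALSE`
#' reproduces the first-mention behaviour, which mis-scores exactly the
#' reports whose history quotes a different score.
#'
#' @param candidates Candidate tibble from [find_candidates()], ordered by
#'   span start.
#' @param take_latter Take the last mention (default) or the first.
#' @param prefer_diagnosis If `TRUE`, restrict to candidates in the
#'   pathological-diagnosis section whenever any candidate lies there,
#'   before applying the first/last rule.
#' @return One-row candidate tibble, or `NULL` when there are none.
#' @export
select_candidate <- function(candidates, take_latter = TRUE,
                             prefer_diagnosis = FALSE) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  pool <- candidates
  if (prefer_diagnosis && any(pool$section == "pathological_diagnosis")) {
    pool <- pool[pool$section == "pathological_diagnosis", , drop = FALSE]
  }
  with_pair <- !is.na(pool$major) & !is.na(pool$minor)
  if (any(with_pair)) pool <- pool[with_pair, , drop = FALSE]
  if (take_latter) pool[nrow(pool), , drop = FALSE] else pool[1L, , drop = FALSE]
}

empty_knowledge <- function() {
  tibble(
    episode_id = character(), major = integer(), minor = integer(),
    total = integer(), standardized = character(),
    risk = character(), status = character()
  )
}

#' Extract the discovered-knowledge row from one narrative report
#'
#' Full pipeline for a single report: normalize and spelling-map the text,
#' segment the standard sections, match the extraction grammar, select the
#' reported mention, compute the total from the major and minor patterns,
#' render the standardized score and classify risk. Malformed or score-free
#' reports yield a `status`, never an error:
#' \describe{
#'   \item{ok}{both components found; total = major + minor.}
#'   \item{no_score_found}{no Gleason mention in the text.}
#'   \item{incomplete}{only a total was stated (e.g. "GLEASON SCORE 7");
#'     total and risk are reported, components are absent.}
#'   \item{conflict}{the report stated a total differing from major + minor;
#'     the computed total is authoritative and is reported.}
#' }
#' The standardized string is emitted only for `ok` rows; risk is present
#' whenever a total is.
#'
#' @param report List or one-row data frame with `episode_id` and `text`.
#' @param grammar Grammar from [gleason_grammar()].
#' @param take_latter,prefer_diagnosis Passed to [select_candidate()].
#' @param variant_map Spelling-variant map.
#' @return One-row tibble: `episode_id`, `major`, `minor`, `total`,
#'   `standardized`, `risk`, `status`.
#' @export
extract_knowledge <- function(report, grammar = gleason_grammar(),
                              take_latter = TRUE, prefer_diagnosis = FALSE,
                              variant_map = default_variant_map()) {
  sectioned <- segment_sections(report, variant_map)
  cand <- find_candidates(sectioned, grammar)
  sel <- select_candidate(cand, take_latter = take_latter,
                          prefer_diagnosis = prefer_diagnosis)
  row <- tibble(
    episode_id = sectioned$episode_id,
    major = NA_integer_, minor = NA_integer_, total = NA_integer_,
    standardized = NA_character_, risk = NA_character_,
    status = "no_score_found"
  )
  if (is.null(sel)) return(row)
  if (!is.na(sel$major) && !is.na(sel$minor)) {
    row$major <- sel$major
    row$minor <- sel$minor
    row$total <- compute_total(sel$major, sel$minor)
    if (!is.na(sel$stated_total) && sel$stated_total != row$total) {
      row$status <- "conflict"
    } else {
      row$status <- "ok"
      row$standardized <- render_standardized(sel$major, sel$minor)
    }
  } else {
    row$total <- sel$stated_total
    row$status <- "incomplete"
  }
  row$risk <- as.character(classify_risk(row$total))
  row
}

#' Extract discovered knowledge for a whole corpus
#'
#' @param reports Tibble of reports (`episode_id`, `text`) from
#'   [read_reports()] or [generate_corpus()].
#' @inheritParams extract_knowledge
#' @return Tibble with one discovered-knowledge row per report, input order
#'   preserved.
#' @export
extract_corpus <- function(reports, grammar = gleason_grammar(),
                           take_latter = TRUE, prefer_diagnosis = FALSE,
                           variant_map = default_variant_map()) {
  if (nrow(reports) == 0L) return(empty_knowledge())
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    extract_knowledge(reports[i, , drop = FALSE], grammar = grammar,
                      take_latter = take_latter,
                      prefer_diagnosis = prefer_diagnosis,
                      variant_map = variant_map)
  })
  dplyr::bind_rows(rows)
}

#' Parse a single score-format fragment
#'
#' Convenience wrapper for parsing one reporting-format string (for example
#' `"MAJOR PATTERN: 4/5 MINOR PATTERN: 3/5"`) rather than a whole report.
#' Bare digit pairs such as `"5, 4"` are only valid adjacent to a Gleason
#' keyword; when the fragment itself carries no keyword (gleason, score,
#' major, minor, pattern), a `"gleason:"` context prefix is supplied, which
#' is how such fragments occur in practice.
#'
#' @param x Character scalar, the fragment as reported.
#' @param grammar Grammar from [gleason_grammar()].
#' @param context_keyword Supply the keyword context when absent (default).
#' @return One-row tibble: `major`, `minor`, `total`, `standardized`
#'   (`NA` fields where the fragment does not determine them).
#' @examples
#' parse_score_string("5 PLUS 4 EQUALS 9")
#' @export
parse_score_string <- function(x, grammar = gleason_grammar(),
                               context_keyword = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  norm <- apply_variant_map(normalize_text(x))
  if (context_keyword &&
      !grepl("gleason|score|major|minor|pattern", norm, perl = TRUE)) {
    norm <- paste("gleason:", norm)
  }
  res <- extract_knowledge(list(episode_id = "fragment", text = norm),
                           grammar = grammar, take_latter = TRUE)
  tibble(major = res$major, minor = res$minor, total = res$total,
         standardized = res$standardized)
}
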