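# Report-format templates. Placeholders: {M} major, {m} minor, {T} total,
# {K} the Gleason keyword (subject to misspelling injection). Ten formats
# mirror the reporting styles catalogued from routine practice; three
# auxiliary shapes mirror n-gram output forms.
FORMAT_TEMPLATES <- c(
  f01_keyword_pair        = "{K} {M}, {m}.",
  f02_plus_equals_words   = "{K} {M} PLUS {m} EQUALS {T}.",
  f03_pair_or_pair        = "{K} {M} + {m} = {T} OR {M} + {m}.",
  f04_major_minor_pattern = "MAJOR PATTERN {M}, MINOR PATTERN {m}.",
  f05_pattern_denominator = "MAJOR PATTERN: {M}/5 MINOR PATTERN: {m}/5.",
  f06_major_minor_words   = "MAJOR {M} PLUS MINOR {m} EQUALS {T}.",
  f07_score_paren         = "SCORE {T} (MAJOR {M}; MINOR {m}).",
  f08_total_paren_pair    = "{K} {T} ({M} + {m}).",
  f09_paren_pair_total    = "{K} ({M} + {m}) = {T}.",
  f10_paren_roles         = "{M} (MAJOR) + {m} (MINOR) = {T}/10.",
  aux_major_minor_bare    = "MAJOR {M} MINOR {m}.",
  aux_plus_pair           = "{K} SCORE {M} + {m}.",
  aux_semicolon_pair      = "{K} {M};{m}."
)

# The ten primary reporting formats (excludes the auxiliary n-gram shapes).
PRIMARY_FORMATS <- names(FORMAT_TEMPLATES)[1:10]

MISSPELLINGS <- c("GLEESON", "GLEASEN")

# Default (major, minor) distribution mirroring routine surveillance
# frequencies: five dominant scores, with the residual mass spread
# uniformly over the remaining valid pairs with totals <= 7.
default_score_distribution <- function() {
  top <- c("5,4" = 0.176, "3,3" = 0.175, "4,3" = 0.164, "3,4" = 0.147,
           "4,4" = 0.142)
  pairs <- expand.grid(major = 1:5, minor = 1:5)
  key <- paste(pairs$major, pairs$minor, sep = ",")
  rest <- key[pairs$major + pairs$minor <= 7 & !(key %in% names(top))]
  c(top, setNames(rep((1 - sum(top)) / length(rest), length(rest)), rest))
}

#' Configuration for the synthetic report generator
#'
#' Defines the study conditions the generator emulates: the number of
#' reports, the mix of score-reporting formats, the (major, minor) score
#' distribution, the rate of reports whose clinical history quotes a
#' DIFFERENT prior score (the failure mode that motivates the take-latter
#' selection rule; 16/1000 = 0.016 by default), the keyword misspelling
#' rate and the rate of score-free reports.
#'
#' @param n Number of reports.
#' @param seed RNG seed (integer); the generator is fully deterministic
#'   given the seed.
#' @param format_weights Named probability vector over format ids (see
#'   `gleason_formats()`); default uniform over all shipped formats.
#' @param score_distribution Named probability vector over `"major,minor"`
#'   pairs in 1-5 x 1-5.
#' @param duplicate_history_rate Probability a report also carries a
#'   different score in its clinical history. Default 0.016.
#' @param misspelling_rate Probability the Gleason keyword is emitted as a
#'   misspelled variant. Default 0.05.
#' @param no_score_rate Probability of a score-free report. Default 0.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 1000, seed = 42,
                             format_weights = NULL,
                             score_distribution = default_score_distribution(),
                             duplicate_history_rate = 0.016,
                             misspelling_rate = 0.05,
                             no_score_rate = 0) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    abort("n must be a non-negative integer", class = "gleason_validation_error")
  }
  if (is.null(format_weights)) {
    format_weights <- setNames(
      rep(1 / length(FORMAT_TEMPLATES), length(FORMAT_TEMPLATES)),
      names(FORMAT_TEMPLATES))
  }
  unknown <- setdiff(names(format_weights), names(FORMAT_TEMPLATES))
  if (length(unknown) > 0) {
    abort(paste0("unknown format id(s): ", paste(unknown, collapse = ", ")),
          class = "gleason_validation_error")
  }
  if (abs(sum(format_weights) - 1) > 1e-9) {
    abort("format_weights must sum to 1", class = "gleason_validation_error")
  }
  if (abs(sum(score_distribution) - 1) > 1e-9) {
    abort("score_distribution must sum to 1", class = "gleason_validation_error")
  }
  keys <- strsplit(names(score_distribution), ",")
  ok_keys <- vapply(keys, function(k) {
    length(k) == 2L && all(as.integer(k) >= 1L) && all(as.integer(k) <= 5L)
  }, logical(1))
  if (!all(ok_keys)) {
    abort("score_distribution keys must be 'major,minor' pairs in 1-5",
          class = "gleason_validation_error")
  }
  rates <- c(duplicate_history_rate, misspelling_rate, no_score_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "gleason_validation_error")
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    format_weights = format_weights,
    score_distribution = score_distribution,
    duplicate_history_rate = duplicate_history_rate,
    misspelling_rate = misspelling_rate,
    no_score_rate = no_score_rate
  ), class = "synthetic_config")
}

#' Shipped score-reporting format identifiers
#'
#' @param primary_only Restrict to the ten primary reporting formats,
#'   excluding the auxiliary n-gram shapes.
#' @return Character vector of format ids.
#' @export
gleason_formats <- function(primary_only = FALSE) {
  if (primary_only) PRIMARY_FORMATS else names(FORMAT_TEMPLATES)
}

#' Draw one (major, minor) score pair
#'
#' @param config A `synthetic_config`.
#' @return List with integer `major`, `minor`. Consumes RNG state; wrap in
#'   `set.seed()` or use via [generate_corpus()] for determinism.
#' @export
sample_score <- function(config) {
  key <- sample(names(config$score_distribution), 1L,
                prob = config$score_distribution)
  parts <- as.integer(strsplit(key, ",")[[1]])
  list(major = parts[1], minor = parts[2])
}

fill_template <- function(template, major, minor, keyword) {
  out <- template
  out <- gsub("{M}", major, out, fixed = TRUE)
  out <- gsub("{m}", minor, out, fixed = TRUE)
  out <- gsub("{T}", major + minor, out, fixed = TRUE)
  gsub("{K}", keyword, out, fixed = TRUE)
}

# Number words for core counts, as dictated in macroscopy sections.
CORE_WORDS <- c("SIX", "EIGHT", "TEN", "TWELVE", "FOURTEEN", "SIXTEEN",
                "EIGHTEEN", "TWENTY")

#' Render one synthetic narrative biopsy report
#'
#' Builds an uppercase semi-structured report with the three standard
#' headings. The clinical history carries a randomized age and PSA decoy
#' value (and, for flagged records, a different prior score); the
#' macroscopy carries core counts and millimetre measurements that must
#' never parse as scores; the pathological diagnosis carries the true score
#' rendered in the record's reporting format.
#'
#' @param truth One-row truth tibble (`episode_id`, `major`, `minor`,
#'   `format_id`, `has_history_duplicate`; `major` NA means score-free).
#' @param config A `synthetic_config`.
#' @return List with `episode_id` and `text`. Consumes RNG state.
#' @export
render_report <- function(truth, config) {
  fmt <- truth$format_id
  if (!is.na(fmt) && !(fmt %in% names(FORMAT_TEMPLATES))) {
    abort(paste0("unknown format_id: ", fmt), class = "gleason_validation_error")
  }
  age <- sample(45:90, 1L)
  psa <- sprintf("%.1f", runif(1L, 2, 60))
  n_cores <- sample(CORE_WORDS, 1L)
  mm_long <- sample(10:25, 1L)
  mm_short <- sample(3:9, 1L)

  history <- sprintf(
    "CLINICAL HISTORY: A %d YEAR OLD MALE PATIENT WITH A PSA OF %s UG/L. PROSTATE BIOPSIES HAVE BEEN DONE.",
    age, psa)
  if (isTRUE(truth$has_history_duplicate)) {
    dup_major <- if ("dup_major" %in% names(truth)) truth$dup_major else NA
    dup_minor <- if ("dup_minor" %in% names(truth)) truth$dup_minor else NA
    if (is.na(dup_major) || is.na(dup_minor)) {
      repeat {
        alt <- sample_score(config)
        if (alt$major != truth$major || alt$minor != truth$minor) break
      }
      dup_major <- alt$major
      dup_minor <- alt$minor
    }
    keyword_h <- if (runif(1L) < config$misspelling_rate)
      sample(MISSPELLINGS, 1L) else "GLEASON"
    history <- paste0(
      history,
      sprintf(" PREVIOUS BIOPSY REPORTED A %s SCORE %d + %d.",
              keyword_h, dup_major, dup_minor))
  }
  macroscopy <- sprintf(
    "MACROSCOPY: %s CORES OF TISSUE, THE LONGEST MEASURING %dMM AND THE SHORTEST MEASURING %dMM.",
    n_cores, mm_long, mm_short)
  diagnosis <- "PATHOLOGICAL DIAGNOSIS: PROSTATE CORE BIOPSIES SHOWING AN INVASIVE PROSTATIC ADENOCARCINOMA."
  if (!is.na(truth$major)) {
    keyword <- if (runif(1L) < config$misspelling_rate)
      sample(MISSPELLINGS, 1L) else "GLEASON"
    score_txt <- fill_template(FORMAT_TEMPLATES[[fmt]], truth$major,
                               truth$minor, keyword)
    diagnosis <- paste(diagnosis, score_txt,
                       "PERINEURAL INVASION IS NOT IDENTIFIED.")
  } else {
    diagnosis <- paste(diagnosis,
                       "NO DEFINITE GRADING IS POSSIBLE ON THIS MATERIAL.")
  }
  list(episode_id = truth$episode_id,
       text = paste(history, macroscopy, diagnosis))
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Draws `config$n` reports: a (major, minor) score per report from the
#' configured distribution, a reporting format from the format weights, a
#' misspelled keyword at the misspelling rate, and -- at the duplicate-
#' history rate -- a prior score in the clinical history that always
#' DIFFERS from the diagnosis score. Output is byte-identical across runs
#' with the same config (seeded RNG; the seed is recorded in the result).
#'
#' @param config A `synthetic_config`.
#' @return List with `reports` (tibble `episode_id`, `text`) and `truth`
#'   (tibble `episode_id`, `major`, `minor`, `total`, `risk`, `format_id`,
#'   `has_history_duplicate`); attribute `seed`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  n <- config$n
  if (n == 0L) {
    return(structure(list(reports = tibble(episode_id = character(),
                                           text = character()),
                          truth = tibble(episode_id = character(),
                                         major = integer(), minor = integer(),
                                         total = integer(), risk = character(),
                                         format_id = character(),
                                         has_history_duplicate = logical())),
                     seed = config$seed))
  }
  rows <- vector("list", n)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("SYN%06d", i)
    if (runif(1L) < config$no_score_rate) {
      tr <- tibble(episode_id = id, major = NA_integer_, minor = NA_integer_,
                   total = NA_integer_, risk = NA_character_,
                   format_id = NA_character_, has_history_duplicate = FALSE,
                   dup_major = NA_integer_, dup_minor = NA_integer_)
    } else {
      sc <- sample_score(config)
      fmt <- sample(names(config$format_weights), 1L,
                    prob = config$format_weights)
      dup <- runif(1L) < config$duplicate_history_rate
      dup_major <- dup_minor <- NA_integer_
      if (dup) {
        # a prior score that always differs from the diagnosis score
        repeat {
          alt <- sample_score(config)
          if (alt$major != sc$major || alt$minor != sc$minor) break
        }
        dup_major <- alt$major
        dup_minor <- alt$minor
      }
      tr <- tibble(episode_id = id, major = sc$major, minor = sc$minor,
                   total = sc$major + sc$minor,
                   risk = as.character(classify_risk(sc$major + sc$minor)),
                   format_id = fmt, has_history_duplicate = dup,
                   dup_major = dup_major, dup_minor = dup_minor)
    }
    rows[[i]] <- tr
    rep_i <- render_report(tr, config)
    reports[[i]] <- tibble(episode_id = rep_i$episode_id, text = rep_i$text)
  }
  truth <- dplyr::bind_rows(rows)
  truth$dup_major <- NULL
  truth$dup_minor <- NULL
  structure(list(reports = dplyr::bind_rows(reports), truth = truth),
            seed = config$seed)
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "gleason_io_error")
  }
  # keep the bare key "n" a string (YAML 1.1 would read it as a boolean)
  y <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) x, "bool#yes" = function(x) x))
  args <- list()
  for (key in c("n", "seed", "duplicate_history_rate", "misspelling_rate",
                "no_score_rate")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$format_weights)) {
    args$format_weights <- unlist(y$format_weights)
  }
  if (!is.null(y$score_distribution)) {
    args$score_distribution <- unlist(y$score_distribution)
  }
  do.call(synthetic_config, args)
}
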