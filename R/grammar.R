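#' Load the Gleason extraction grammar
#'
#' The grammar is a versioned, ordered set of Perl-compatible regular
#' expression rules shipped as a plain-text data file. Each rule names the
#' role (major, minor or total) of every capture group. Rules are matched
#' against normalized, spelling-mapped report text; overlapping matches are
#' resolved longest-first, then earliest-start, then by rule order.
#'
#' @param path Optional path to an alternative grammar file (tab-separated:
#'   `rule_id`, `roles`, `pattern`, `description`).
#' @return A tibble of class `gleason_grammar` with columns `rule_id`,
#'   `roles` (list of character vectors), `pattern`, `description`.
#' @export
gleason_grammar <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grammar.tsv", package = "gleasonminer")
  }
  if (!file.exists(path)) {
    abort(paste0("grammar file not found: ", path), class = "gleason_io_error")
  }
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  need <- c("rule_id", "roles", "pattern", "description")
  if (!all(need %in% names(raw))) {
    abort("grammar file must have columns rule_id, roles, pattern, description",
          class = "gleason_schema_error")
  }
  for (p in raw$pattern) {
    ok <- tryCatch({ regexpr(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort(paste0("grammar pattern does not compile: ", p),
                   class = "gleason_validation_error")
  }
  out <- tibble(
    rule_id = raw$rule_id,
    roles = strsplit(raw$roles, "\\s+"),
    pattern = raw$pattern,
    description = raw$description
  )
  class(out) <- c("gleason_grammar", class(out))
  out
}
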