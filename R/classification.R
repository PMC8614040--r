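#' Map a total Gleason score to its guideline risk category
#'
#' Local treatment guidelines stratify prostate-cancer risk by the total
#' Gleason score: low (total <= 6), intermediate (total = 7) and
#' high (total >= 8). The mapping is exhaustive and exclusive over the
#' valid totals 2-10 and monotone in the total.
#'
#' @param total Integer vector of total Gleason scores, each in 2-10
#'   (NA allowed; maps to NA).
#' @return Ordered factor with levels `low < intermediate < high`.
#' @examples
#' classify_risk(c(6, 7, 8))
#' @export
classify_risk <- function(total) {
  total <- as.integer(total)
  bad <- !is.na(total) & (total < 2L | total > 10L)
  if (any(bad)) {
    abort(paste0("total score out of range 2-10: ",
                 paste(unique(total[bad]), collapse = ", ")),
          class = "gleason_validation_error")
  }
  out <- ifelse(is.na(total), NA_character_,
         ifelse(total <= 6L, "low",
         ifelse(total == 7L, "intermediate", "high")))
  factor(out, levels = RISK_LEVELS, ordered = TRUE)
}
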