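#' Classify a taxon as contaminant or not
#'
#' A taxon is called a contaminant when its log-log frequency regression
#' shows the inverse-linear signature strongly enough: adjusted R-squared at
#' or above `r2_threshold` (inclusive) and, by default, a negative slope. A
#' tight positive-slope fit means abundance tracks input mass — real signal,
#' not contamination — so the sign requirement is on unless switched off.
#' The `reason` records the first failing condition in the fixed order
#' insufficient_obs, insufficient_prevalence, slope_nonnegative,
#' r2_below_threshold.
#'
#' @param fit A [fit_taxon()] result (or stub for insufficient observations).
#' @param r2_threshold Adjusted R-squared cutoff (default 0.7).
#' @param require_negative_slope Require slope < 0 (default TRUE).
#' @param insufficient_prevalence Set `TRUE` when the taxon failed the
#'   upstream prevalence filter (recorded as the reason; no classification).
#' @return List with `taxon_id`, `is_contaminant`, `reason` (one of
#'   `"classified"`, `"r2_below_threshold"`, `"slope_nonnegative"`,
#'   `"insufficient_obs"`, `"insufficient_prevalence"`).
#' @export
classify_taxon <- function(fit, r2_threshold = 0.7, require_negative_slope = TRUE,
                           insufficient_prevalence = FALSE) {
  taxon_id <- fit$taxon_id
  if (inherits(fit, "taxon_fit_stub")) {
    return(list(taxon_id = taxon_id, is_contaminant = FALSE,
                reason = "insufficient_obs"))
  }
  stopifnot(inherits(fit, "taxon_fit"))
  if (insufficient_prevalence) {
    return(list(taxon_id = taxon_id, is_contaminant = FALSE,
                reason = "insufficient_prevalence"))
  }
  if (require_negative_slope && fit$slope >= 0) {
    return(list(taxon_id = taxon_id, is_contaminant = FALSE,
                reason = "slope_nonnegative"))
  }
  if (fit$adj_r2 < r2_threshold) {
    return(list(taxon_id = taxon_id, is_contaminant = FALSE,
                reason = "r2_below_threshold"))
  }
  list(taxon_id = taxon_id, is_contaminant = TRUE, reason = "classified")
}
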