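#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the published workflow where it states a value (adjusted R-squared
#' threshold 0.7, 25 pg spike, the +/-2 studentized-residual band) and
#' conservative conventions where it is silent (documented per argument).
#'
#' @param r2_threshold Adjusted R-squared classification cutoff, inclusive
#'   (default 0.7).
#' @param require_negative_slope Demand a negative slope for a contaminant
#'   call (default TRUE); a tight positive-slope fit is mass-tracking signal.
#' @param min_prevalence Minimum fraction of samples with nonzero counts for
#'   a taxon to be fitted (default 0.25).
#' @param min_obs Minimum observations per fit (default 6).
#' @param pseudocount Optional pseudocount added before rpm; `NULL` (default)
#'   excludes zero-count samples from a taxon's fit instead.
#' @param flag_threshold Studentized-residual outlier cutoff (default 2).
#' @param one_sided Flag high-side outliers only (default TRUE).
#' @param outlier_exclusion Exclude flagged samples from a contaminant's
#'   mass summary and refit iteratively (default TRUE).
#' @param max_iter Maximum flag/refit rounds (default 3).
#' @param spike_mass_pg Spiked mass per sample, picograms (default 25).
#' @param min_ercc_reads Minimum spike reads for mass inference (default 100).
#' @param mass_mode `"auto"`, `"given"` or `"inferred"` (default `"auto"`).
#' @return A named list of class `contam_config`.
#' @export
contam_config <- function(r2_threshold = 0.7,
                          require_negative_slope = TRUE,
                          min_prevalence = 0.25,
                          min_obs = 6,
                          pseudocount = NULL,
                          flag_threshold = 2,
                          one_sided = TRUE,
                          outlier_exclusion = TRUE,
                          max_iter = 3,
                          spike_mass_pg = 25,
                          min_ercc_reads = 100,
                          mass_mode = c("auto", "given", "inferred")) {
  mass_mode <- match.arg(mass_mode)
  stopifnot(r2_threshold <= 1, min_prevalence >= 0, min_prevalence <= 1,
            min_obs >= 4, flag_threshold > 0, max_iter >= 1,
            spike_mass_pg > 0, min_ercc_reads >= 1)
  if (!is.null(pseudocount)) stopifnot(is.numeric(pseudocount), pseudocount > 0)
  structure(
    list(r2_threshold = r2_threshold,
         require_negative_slope = require_negative_slope,
         min_prevalence = min_prevalence,
         min_obs = min_obs,
         pseudocount = pseudocount,
         flag_threshold = flag_threshold,
         one_sided = one_sided,
         outlier_exclusion = outlier_exclusion,
         max_iter = max_iter,
         spike_mass_pg = spike_mass_pg,
         min_ercc_reads = min_ercc_reads,
         mass_mode = mass_mode),
    class = "contam_config"
  )
}
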