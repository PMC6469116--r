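#' End-to-end contamination analysis
#'
#' Convenience wrapper running the full workflow: sample-mass estimation
#' (from metadata, the spike-in, or both per `config$mass_mode`), per-taxon
#' log-log regression and classification, outlier detection on classified
#' contaminants, and mass quantification.
#'
#' @param table A [count_table()] or a path readable by [load_counts()].
#' @param metadata Optional metadata data.frame (or path for
#'   [load_metadata()]); required for `mass_mode = "given"`.
#' @param mix An [ercc_mix()]; defaults to the bundled reference with the
#'   configured spike mass.
#' @param config A [contam_config()].
#' @param spike_prefix,transpose Passed to [load_counts()] when `table` is a
#'   path.
#' @return A `contaminant_report` (see [build_report()]).
#' @examples
#' sim <- simulate_scenario(dilution_config(seed = 1))
#' rep <- analyze_contamination(sim$table, sim$metadata)
#' @export
analyze_contamination <- function(table, metadata = NULL,
                                  mix = NULL, config = contam_config(),
                                  spike_prefix = "ERCC-", transpose = FALSE) {
  if (is.character(table)) {
    table <- load_counts(table, spike_prefix = spike_prefix,
                         transpose = transpose)
  }
  if (is.character(metadata)) metadata <- load_metadata(metadata)
  if (is.null(mix)) {
    mix <- load_ercc_reference(spike_mass_pg = config$spike_mass_pg)
  }
  sm <- estimate_sample_mass(table, mix, meta = metadata,
                             mode = config$mass_mode,
                             min_ercc_reads = config$min_ercc_reads)
  build_report(table, mix, sm, config)
}
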