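#' Reads-per-million normalization
#'
#' `rpm[t, s] = counts[t, s] / total_reads[s] * 1e6`, where the denominator
#' sums every row of the sample — spike-in and non-spike alike. Columns of
#' the result therefore sum to 1e6 and are invariant to uniform rescaling of
#' a sample's counts.
#'
#' @param table A [count_table()].
#' @param pseudocount Optional constant added to every cell before
#'   normalization (the denominator is left at the raw total so that zero
#'   cells map to a small positive rpm). `NULL` (default) disables it.
#' @return Numeric matrix, same dimnames as the counts.
#' @export
rpm <- function(table, pseudocount = NULL) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  if (!is.null(pseudocount)) {
    stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount > 0)
    m <- m + pseudocount
  }
  sweep(m, 2, sample_totals(table), "/") * 1e6
}

#' Estimate per-sample input mass
#'
#' In `"given"` mode, masses come from the metadata. In `"inferred"` mode the
#' spike-in anchors the estimate: with a known spiked mass and read output
#' proportional to mass, `mass[s] = spike_mass_pg * nonspike_reads[s] /
#' ercc_reads[s]`, where `nonspike_reads` counts every non-spike row (host
#' plus microbes — the host dominates total input). `"auto"` uses the
#' metadata mass where present and infers the rest.
#'
#' @param table A [count_table()].
#' @param mix An [ercc_mix()]; its `spike_mass_pg` enters the inference.
#' @param meta Optional metadata data.frame from [load_metadata()].
#' @param mode One of `"auto"`, `"given"`, `"inferred"`.
#' @param min_ercc_reads Minimum spike reads required for inference
#'   (default 100); below it the ratio is too unstable to report.
#' @return data.frame with columns `sample_id`, `mass_pg`, `source`
#'   (`"given"` or `"inferred"`), `ercc_reads`, `nonspike_reads`, in input
#'   sample order.
#' @export
estimate_sample_mass <- function(table, mix, meta = NULL,
                                 mode = c("auto", "given", "inferred"),
                                 min_ercc_reads = 100) {
  stopifnot(inherits(table, "count_table"), inherits(mix, "ercc_mix"))
  mode <- match.arg(mode)
  samples <- colnames(table$counts)
  ercc <- spike_totals(table)
  nonspike <- sample_totals(table) - ercc

  given <- rep(NA_real_, length(samples))
  if (!is.null(meta)) {
    idx <- match(samples, meta$sample_id)
    given <- meta$input_mass_pg[idx]
  }

  use_given <- switch(mode,
    given = rep(TRUE, length(samples)),
    inferred = rep(FALSE, length(samples)),
    auto = !is.na(given)
  )
  if (mode == "given" && any(is.na(given))) {
    stop("mass_mode 'given' but no input_mass_pg for sample(s): ",
         paste(samples[is.na(given)], collapse = ", "), call. = FALSE)
  }
  need_infer <- !use_given
  if (any(need_infer & ercc < min_ercc_reads)) {
    bad <- samples[need_infer & ercc < min_ercc_reads]
    stop(sprintf("cannot infer input mass (spike reads < %g) for sample(s): %s",
                 min_ercc_reads, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  mass <- ifelse(use_given, given, mix$spike_mass_pg * nonspike / ercc)
  if (any(!is.finite(mass) | mass <= 0)) {
    stop("non-positive estimated mass for sample(s): ",
         paste(samples[!is.finite(mass) | mass <= 0], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    sample_id = samples,
    mass_pg = as.numeric(mass),
    source = ifelse(use_given, "given", "inferred"),
    ercc_reads = as.numeric(ercc),
    nonspike_reads = as.numeric(nonspike),
    stringsAsFactors = FALSE
  )
}

#' Quantify a taxon's mass per sample from the spike-in ratio
#'
#' Solves the mass-ratio identity `taxon mass / spiked mass = taxon reads /
#' spike reads` per sample and converts to attograms (1 pg = 1e6 ag). The
#' identity is unchanged when rpm values replace raw counts (the per-sample
#' total cancels), and is linear in the taxon's counts.
#'
#' @param table A [count_table()].
#' @param taxon_id A non-spike taxon present in the table.
#' @param mix An [ercc_mix()].
#' @param include_samples Sample IDs over which to report mass and compute
#'   the mean/SD summary (default all samples). SD uses the n-1 denominator.
#' @return An object of class `mass_quant`: list with `taxon_id`,
#'   `per_sample` (data.frame `sample_id`, `mass_ag`), `mean_mass_ag`,
#'   `sd_mass_ag`.
#' @export
quantify_taxon_mass <- function(table, taxon_id, mix, include_samples = NULL) {
  stopifnot(inherits(table, "count_table"), inherits(mix, "ercc_mix"))
  if (!taxon_id %in% rownames(table$counts)) {
    stop("taxon not found in count table: ", taxon_id, call. = FALSE)
  }
  if (table$is_spike[[taxon_id]]) {
    stop("taxon is a spike-in row: ", taxon_id, call. = FALSE)
  }
  samples <- colnames(table$counts)
  if (is.null(include_samples)) include_samples <- samples
  include_samples <- as.character(include_samples)
  if (length(include_samples) == 0L) {
    stop("empty include_samples set", call. = FALSE)
  }
  missing_s <- setdiff(include_samples, samples)
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "), call. = FALSE)
  }
  ercc <- spike_totals(table)[include_samples]
  if (any(ercc == 0)) {
    stop("zero spike reads in sample(s): ",
         paste(include_samples[ercc == 0], collapse = ", "), call. = FALSE)
  }
  k <- table$counts[taxon_id, include_samples]
  mass_ag <- mix$spike_mass_pg * 1e6 * k / ercc
  structure(
    list(
      taxon_id = taxon_id,
      per_sample = data.frame(sample_id = include_samples,
                              mass_ag = as.numeric(mass_ag),
                              stringsAsFactors = FALSE),
      mean_mass_ag = mean(mass_ag),
      sd_mass_ag = if (length(mass_ag) > 1L) stats::sd(mass_ag) else NA_real_
    ),
    class = "mass_quant"
  )
}

#' @export
print.mass_quant <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g ag over %d samples\n", x$taxon_id,
              x$mean_mass_ag, x$sd_mass_ag, nrow(x$per_sample)))
  invisible(x)
}
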