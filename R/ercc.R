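#' Construct an ERCC spike-in mix
#'
#' An `ercc_mix` models the spike-in panel added at known mass to every
#' library: the transcript identities, their relative concentrations, and the
#' total spiked mass. Only within-mix concentration ratios matter to the
#' method; absolute units are arbitrary.
#'
#' @param transcripts data.frame with columns `transcript_id` (unique
#'   character), `length_nt` (positive integer, nucleotides) and
#'   `concentration` (positive numeric, arbitrary molar units).
#' @param spike_mass_pg Total mass of the mix added per sample, picograms.
#'   Defaults to 25 pg.
#' @return An object of class `ercc_mix`.
#' @seealso [load_ercc_reference()], [mass_fractions()]
#' @export
ercc_mix <- function(transcripts, spike_mass_pg = 25) {
  if (!is.data.frame(transcripts)) {
    stop("`transcripts` must be a data.frame", call. = FALSE)
  }
  req <- c("transcript_id", "length_nt", "concentration")
  missing_cols <- setdiff(req, names(transcripts))
  if (length(missing_cols)) {
    stop("ERCC reference is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  id <- as.character(transcripts$transcript_id)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate transcript_id in ERCC reference: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  len <- transcripts$length_nt
  conc <- transcripts$concentration
  if (!is.numeric(len) || anyNA(len) || any(len <= 0) || any(len != round(len))) {
    bad <- which(!is.finite(len) | len <= 0 | len != round(len))
    stop("length_nt must be a positive integer; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(conc) || anyNA(conc) || any(conc <= 0)) {
    bad <- which(!is.finite(conc) | conc <= 0)
    stop("concentration must be positive; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(spike_mass_pg) || length(spike_mass_pg) != 1L ||
      !is.finite(spike_mass_pg) || spike_mass_pg <= 0) {
    stop("`spike_mass_pg` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      transcripts = data.frame(
        transcript_id = id,
        length_nt = as.integer(len),
        concentration = as.numeric(conc),
        stringsAsFactors = FALSE
      ),
      spike_mass_pg = as.numeric(spike_mass_pg)
    ),
    class = "ercc_mix"
  )
}

#' Load an ERCC spike-in reference sheet
#'
#' Reads a tab-separated reference with columns `transcript_id`, `length_nt`
#' and `concentration` (header required, `#` comment lines permitted). The
#' bundled default describes a synthetic 92-transcript mix with
#' concentrations log-spaced over six decades; it stands in for a commercial
#' concentration sheet, which the method never needs because only within-mix
#' ratios enter any computation.
#'
#' @param path Path to a reference TSV, or `"bundled"` (default) for the
#'   synthetic 92-transcript sheet shipped with the package.
#' @param spike_mass_pg Total spiked mass per sample in picograms (default 25).
#' @return An [ercc_mix()] object.
#' @examples
#' mix <- load_ercc_reference()
#' nrow(mix$transcripts)  # 92
#' @export
load_ercc_reference <- function(path = "bundled", spike_mass_pg = 25) {
  if (identical(path, "bundled")) {
    path <- system.file("extdata", "ercc92_synthetic.tsv",
                        package = "spikecontam", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("ERCC reference not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(df) == 0L) stop("ERCC reference has no data rows: ", path, call. = FALSE)
  ercc_mix(df, spike_mass_pg = spike_mass_pg)
}

#' Mass fractions of an ERCC mix
#'
#' The fraction of the total spiked mass carried by each transcript,
#' `concentration * length_nt` normalized over the mix. Invariant to
#' rescaling all concentrations by a positive constant; fractions sum to 1.
#'
#' @param mix An [ercc_mix()] object.
#' @return Named numeric vector (names = transcript IDs, order as in the mix).
#' @export
mass_fractions <- function(mix) {
  stopifnot(inherits(mix, "ercc_mix"))
  w <- mix$transcripts$concentration * mix$transcripts$length_nt
  stats::setNames(w / sum(w), mix$transcripts$transcript_id)
}

#' @export
print.ercc_mix <- function(x, ...) {
  cat(sprintf("ERCC spike-in mix: %d transcripts, %g pg total spiked mass\n",
              nrow(x$transcripts), x$spike_mass_pg))
  rng <- range(x$transcripts$concentration)
  cat(sprintf("  concentration range: %.3g-%.3g (arbitrary units)\n", rng[1], rng[2]))
  invisible(x)
}
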