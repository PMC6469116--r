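#' Run the contaminant analysis over a count table
#'
#' For every non-spike taxon passing the prevalence filter, fits the log-log
#' frequency regression, classifies it (adjusted R-squared threshold plus
#' negative slope), and — for classified contaminants — detects outlier
#' samples by externally studentized residuals and quantifies the
#' contaminant's mass per sample from the spike-in ratio. Zero-count samples
#' are excluded from a taxon's fit unless a pseudocount is configured;
#' p-values for the slope are Benjamini-Hochberg adjusted across all fitted
#' taxa (reported, not used for classification). Flagged outlier samples are
#' excluded from a contaminant's mean +/- SD mass summary when
#' `outlier_exclusion` is on; per-sample totals are summed over all samples
#' so totals remain exactly additive.
#'
#' @param table A [count_table()].
#' @param mix An [ercc_mix()].
#' @param sample_masses data.frame from [estimate_sample_mass()].
#' @param config A [contam_config()].
#' @return An object of class `contaminant_report`: list with `fits`
#'   (per-taxon data.frame incl. classification), `masses` (list of
#'   [quantify_taxon_mass()] results for contaminants), `mass_matrix`
#'   (contaminant x all-samples attogram matrix), `outliers` (per
#'   contaminant-sample calls), `totals` (`per_sample`, `mean_ag`, `sd_ag`),
#'   `sample_masses`, `config`.
#' @export
build_report <- function(table, mix, sample_masses, config = contam_config()) {
  stopifnot(inherits(table, "count_table"), inherits(mix, "ercc_mix"),
            is.data.frame(sample_masses), inherits(config, "contam_config"))
  samples <- colnames(table$counts)
  mi <- match(samples, sample_masses$sample_id)
  if (anyNA(mi)) {
    stop("sample_masses missing sample(s): ",
         paste(samples[is.na(mi)], collapse = ", "), call. = FALSE)
  }
  x_all <- log10(sample_masses$mass_pg[mi])
  rpm_mat <- rpm(table, pseudocount = config$pseudocount)
  taxa <- rownames(table$counts)[!table$is_spike]

  fits <- vector("list", length(taxa))
  calls <- vector("list", length(taxa))
  rows <- vector("list", length(taxa))
  for (i in seq_along(taxa)) {
    t_id <- taxa[i]
    k <- table$counts[t_id, ]
    use <- if (is.null(config$pseudocount)) k > 0 else rep(TRUE, length(k))
    n_use <- sum(use)
    prevalence <- mean(k > 0)
    if (n_use < config$min_obs) {
      fit <- structure(list(taxon_id = t_id, n_obs = n_use,
                            reason = "insufficient_obs"),
                       class = "taxon_fit_stub")
      call <- classify_taxon(fit)
    } else if (prevalence < config$min_prevalence) {
      fit <- NULL
      call <- list(taxon_id = t_id, is_contaminant = FALSE,
                   reason = "insufficient_prevalence")
    } else {
      fit <- fit_taxon(x_all[use], log10(rpm_mat[t_id, use]),
                       sample_ids = samples[use], min_obs = config$min_obs,
                       taxon_id = t_id)
      call <- classify_taxon(fit, r2_threshold = config$r2_threshold,
                             require_negative_slope = config$require_negative_slope)
    }
    fitted_ok <- inherits(fit, "taxon_fit")
    fits[[i]] <- fit
    calls[[i]] <- call
    rows[[i]] <- data.frame(
      taxon_id = t_id,
      n_obs = if (fitted_ok) fit$n_obs else n_use,
      slope = if (fitted_ok) fit$slope else NA_real_,
      intercept = if (fitted_ok) fit$intercept else NA_real_,
      adj_r2 = if (fitted_ok) fit$adj_r2 else NA_real_,
      p_slope = if (fitted_ok) fit$p_slope else NA_real_,
      is_contaminant = call$is_contaminant,
      classification = call$reason,
      stringsAsFactors = FALSE
    )
  }
  fits_df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(taxon_id = character(), n_obs = integer(),
               slope = numeric(), intercept = numeric(),
               adj_r2 = numeric(), p_slope = numeric(),
               is_contaminant = logical(), classification = character(),
               stringsAsFactors = FALSE)
  }
  fits_df$p_adj <- NA_real_
  fitted_idx <- !is.na(fits_df$p_slope)
  fits_df$p_adj[fitted_idx] <- stats::p.adjust(fits_df$p_slope[fitted_idx],
                                               method = "BH")
  if (!any(fitted_idx)) {
    warning("no taxa passed the prevalence/observation filters; empty report",
            call. = FALSE)
  }

  contam_ids <- fits_df$taxon_id[fits_df$is_contaminant]
  masses <- list()
  outlier_rows <- list()
  mass_matrix <- matrix(0, nrow = 0, ncol = length(samples),
                        dimnames = list(NULL, samples))
  for (t_id in contam_ids) {
    fit <- fits[[match(t_id, taxa)]]
    xs <- fit$x; ys <- fit$y; ids <- fit$included_samples
    if (config$outlier_exclusion) {
      it <- iterate_refit(xs, ys, ids,
                          flag_threshold = config$flag_threshold,
                          one_sided = config$one_sided,
                          max_iter = config$max_iter,
                          min_obs = config$min_obs,
                          table = table, taxon_id = t_id, mix = mix)
      ocalls <- it$outliers
      include <- setdiff(ids, ocalls$sample_id[ocalls$is_outlier])
    } else {
      ocalls <- flag_outliers(fit, config$flag_threshold, config$one_sided,
                              table = table, taxon_id = t_id, mix = mix)
      include <- ids
    }
    outlier_rows[[t_id]] <- ocalls
    if (length(include) == 0L) include <- ids  # all flagged: fall back
    masses[[t_id]] <- quantify_taxon_mass(table, t_id, mix,
                                          include_samples = include)
    full <- quantify_taxon_mass(table, t_id, mix)  # all samples, for totals
    mass_matrix <- rbind(mass_matrix,
                         stats::setNames(full$per_sample$mass_ag,
                                         full$per_sample$sample_id)[samples])
    rownames(mass_matrix)[nrow(mass_matrix)] <- t_id
  }
  outliers <- if (length(outlier_rows)) {
    do.call(rbind, c(outlier_rows, list(make.row.names = FALSE)))
  } else {
    flag_outliers_empty()
  }
  total_per_sample <- colSums(mass_matrix)
  totals <- list(
    per_sample = data.frame(sample_id = samples,
                            total_mass_ag = as.numeric(total_per_sample),
                            stringsAsFactors = FALSE),
    mean_ag = mean(total_per_sample),
    sd_ag = if (length(total_per_sample) > 1L) stats::sd(total_per_sample) else NA_real_
  )
  structure(
    list(fits = fits_df, calls = calls, masses = masses,
         mass_matrix = mass_matrix, outliers = outliers, totals = totals,
         sample_masses = sample_masses[mi, , drop = FALSE], config = config),
    class = "contaminant_report"
  )
}

# internal: zero-row outlier-call frame with the canonical columns
flag_outliers_empty <- function() {
  data.frame(sample_id = character(), taxon_id = character(),
             studentized_residual = numeric(), p_value = numeric(),
             p_bonferroni = numeric(), is_outlier = logical(),
             observed_reads = numeric(), expected_reads = numeric(),
             excess_reads = numeric(), excess_mass_ag = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.contaminant_report <- function(x, ...) {
  n_fit <- sum(!is.na(x$fits$p_slope))
  n_con <- sum(x$fits$is_contaminant)
  cat(sprintf("contaminant_report: %d taxa examined, %d fitted, %d classified as contaminants\n",
              nrow(x$fits), n_fit, n_con))
  if (n_con > 0) {
    for (m in x$masses) {
      cat(sprintf("  %-32s %8.4g +/- %.4g ag\n", m$taxon_id, m$mean_mass_ag,
                  m$sd_mass_ag))
    }
    cat(sprintf("  total contaminant mass: %.4g +/- %.4g ag per sample\n",
                x$totals$mean_ag, x$totals$sd_ag))
    n_flag <- sum(x$outliers$is_outlier)
    cat(sprintf("  %d outlier sample-taxon pair(s) flagged\n", n_flag))
  }
  invisible(x)
}

#' Write analysis result tables
#'
#' Writes five files into `outdir` (created if needed): `taxa_fits.tsv`
#' (per-taxon regression and classification), `contaminant_mass.tsv`
#' (contaminant x sample attogram masses plus mean and SD), `outliers.tsv`
#' (per contaminant-sample studentized-residual calls), `sample_mass.tsv`
#' (per-sample mass and its source) and `run_info.json` (configuration, seed
#' when known, package version). All tab-delimited, UTF-8, LF endings;
#' numbers at 6 significant digits; column order follows input sample order.
#' Reruns with identical inputs produce byte-identical files.
#'
#' @param report A [build_report()] result.
#' @param outdir Output directory.
#' @param seed Optional integer recorded in `run_info.json`.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, outdir, seed = NULL) {
  stopifnot(inherits(report, "contaminant_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  fmt <- function(v) {
    ifelse(is.na(v), "NA",
           vapply(v, function(z) format(signif(z, 6), trim = TRUE,
                                        scientific = FALSE), character(1)))
  }
  paths <- character()

  f <- report$fits
  lines <- c(
    paste(c("taxon_id", "slope", "intercept", "adj_r2", "p_slope", "p_adj",
            "n_obs", "classification"), collapse = "\t"),
    if (nrow(f)) vapply(seq_len(nrow(f)), function(i) {
      paste(c(f$taxon_id[i], fmt(f$slope[i]), fmt(f$intercept[i]),
              fmt(f$adj_r2[i]), fmt(f$p_slope[i]), fmt(f$p_adj[i]),
              f$n_obs[i],
              if (f$is_contaminant[i]) "contaminant" else f$classification[i]),
            collapse = "\t")
    }, character(1))
  )
  paths <- c(paths, write_lines_lf(lines, file.path(outdir, "taxa_fits.tsv")))

  mm <- report$mass_matrix
  lines <- c(
    paste(c("taxon_id", colnames(mm), "mean_ag", "sd_ag"), collapse = "\t"),
    if (nrow(mm)) vapply(seq_len(nrow(mm)), function(i) {
      m <- report$masses[[rownames(mm)[i]]]
      paste(c(rownames(mm)[i], fmt(mm[i, ]), fmt(m$mean_mass_ag),
              fmt(m$sd_mass_ag)), collapse = "\t")
    }, character(1))
  )
  paths <- c(paths, write_lines_lf(lines, file.path(outdir, "contaminant_mass.tsv")))

  o <- report$outliers
  lines <- c(
    paste(c("sample_id", "taxon_id", "studentized_residual", "p_value",
            "is_outlier"), collapse = "\t"),
    if (nrow(o)) vapply(seq_len(nrow(o)), function(i) {
      paste(c(o$sample_id[i], o$taxon_id[i], fmt(o$studentized_residual[i]),
              fmt(o$p_value[i]), tolower(o$is_outlier[i])), collapse = "\t")
    }, character(1))
  )
  paths <- c(paths, write_lines_lf(lines, file.path(outdir, "outliers.tsv")))

  s <- report$sample_masses
  lines <- c(
    paste(c("sample_id", "source", "mass_pg"), collapse = "\t"),
    vapply(seq_len(nrow(s)), function(i) {
      paste(c(s$sample_id[i], s$source[i], fmt(s$mass_pg[i])), collapse = "\t")
    }, character(1))
  )
  paths <- c(paths, write_lines_lf(lines, file.path(outdir, "sample_mass.tsv")))

  cfg <- report$config
  cfg_out <- cfg[!vapply(cfg, is.null, logical(1))]
  info <- list(package = "spikecontam",
               version = as.character(utils::packageVersion("spikecontam")),
               config = cfg_out)
  if (!is.null(seed)) info$seed <- seed
  jsonlite::write_json(info, file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, file.path(outdir, "run_info.json"))
  invisible(paths)
}
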