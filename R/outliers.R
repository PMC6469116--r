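#' Flag samples carrying more of a taxon than contamination predicts
#'
#' For every observation in a taxon's frequency regression, computes the
#' externally studentized residual and its two-sided p-value (t, n-3 df,
#' Bonferroni-adjusted copy included), and flags observations beyond
#' `flag_threshold`. Flagging is one-sided high by default: an excess above
#' the contamination expectation is the biologically interesting direction
#' (true presence on top of background), while a deficit is mere depletion.
#'
#' When the count context (`table`, `taxon_id`, `mix`) is supplied, each call
#' also carries the observed reads, the regression-predicted reads
#' (back-transformed rpm prediction times total reads / 1e6), the excess
#' reads `max(observed - expected, 0)`, and the excess mass in attograms via
#' the spike-in ratio — the separation of a sample's signal into expected
#' contamination and excess.
#'
#' @param fit A [fit_taxon()] result.
#' @param flag_threshold Studentized-residual cutoff (default 2).
#' @param one_sided Flag only the high side (default TRUE); otherwise
#'   `|t| > flag_threshold`.
#' @param table,taxon_id,mix Optional count context (a [count_table()], the
#'   fitted taxon and an [ercc_mix()]) to fill the read/mass columns.
#' @return data.frame with one row per included sample: `sample_id`,
#'   `taxon_id`, `studentized_residual`, `p_value`, `p_bonferroni`,
#'   `is_outlier`, `observed_reads`, `expected_reads`, `excess_reads`,
#'   `excess_mass_ag` (the last four NA without count context).
#' @export
flag_outliers <- function(fit, flag_threshold = 2, one_sided = TRUE,
                          table = NULL, taxon_id = NULL, mix = NULL) {
  stopifnot(inherits(fit, "taxon_fit"))
  t_i <- studentized_residuals(fit)
  n <- fit$n_obs
  p <- 2 * stats::pt(-abs(t_i), df = n - 3)
  flagged <- if (one_sided) t_i > flag_threshold else abs(t_i) > flag_threshold
  if (is.null(taxon_id)) {
    taxon_id <- if (is.null(fit$taxon_id)) NA_character_ else fit$taxon_id
  }
  out <- data.frame(
    sample_id = fit$included_samples,
    taxon_id = taxon_id,
    studentized_residual = t_i,
    p_value = p,
    p_bonferroni = pmin(1, p * n),
    is_outlier = flagged,
    observed_reads = NA_real_,
    expected_reads = NA_real_,
    excess_reads = NA_real_,
    excess_mass_ag = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(table) && !is.null(mix) && !is.null(out$taxon_id[1]) &&
      !anyNA(out$taxon_id)) {
    stopifnot(inherits(table, "count_table"), inherits(mix, "ercc_mix"))
    tid <- out$taxon_id[1]
    s <- fit$included_samples
    totals <- sample_totals(table)[s]
    ercc <- spike_totals(table)[s]
    out$observed_reads <- as.numeric(table$counts[tid, s])
    out$expected_reads <- 10^fit$fitted * totals / 1e6
    out$excess_reads <- pmax(out$observed_reads - out$expected_reads, 0)
    out$excess_mass_ag <- mix$spike_mass_pg * 1e6 * out$excess_reads / ercc
  }
  out
}

#' Iteratively refit a taxon's regression excluding flagged outliers
#'
#' Alternates outlier flagging and refitting on the unflagged observations
#' until no new observation is flagged or `max_iter` is reached. A sample
#' truly carrying a taxon drags the single-pass regression towards itself;
#' one or two rounds of exclusion restore the contamination baseline, after
#' which all samples are scored against the final fit. If exclusion would
#' leave fewer than `min_obs` observations, iteration stops with a warning
#' and the last valid fit is returned.
#'
#' @param log_mass,log_rpm,sample_ids Regression inputs as in [fit_taxon()].
#' @param flag_threshold,one_sided Flagging rule as in [flag_outliers()].
#' @param max_iter Maximum refit rounds (default 3).
#' @param min_obs Minimum observations per fit (default 6).
#' @param table,taxon_id,mix Optional count context passed to
#'   [flag_outliers()].
#' @return List with `fit` (final [fit_taxon()] on unflagged observations),
#'   `outliers` (calls for every original observation scored against the
#'   final fit), `excluded` (flagged sample IDs) and `n_iter`.
#' @export
iterate_refit <- function(log_mass, log_rpm, sample_ids = NULL,
                          flag_threshold = 2, one_sided = TRUE, max_iter = 3,
                          min_obs = 6, table = NULL, taxon_id = NULL,
                          mix = NULL) {
  stopifnot(max_iter >= 1)
  n <- length(log_mass)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  keep <- rep(TRUE, n)
  fit <- fit_taxon(log_mass, log_rpm, sample_ids, min_obs = min_obs,
                   taxon_id = taxon_id)
  if (inherits(fit, "taxon_fit_stub")) {
    stop("too few observations for outlier iteration", call. = FALSE)
  }
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    calls <- flag_outliers(fit, flag_threshold, one_sided)
    newly <- calls$sample_id[calls$is_outlier]
    if (length(newly) == 0L || n_iter >= max_iter) break
    keep_next <- keep & !(sample_ids %in% c(sample_ids[!keep], newly))
    if (sum(keep_next) < min_obs) {
      warning("outlier exclusion would leave fewer than min_obs observations; stopping",
              call. = FALSE)
      break
    }
    keep <- keep_next
    fit <- fit_taxon(log_mass[keep], log_rpm[keep], sample_ids[keep],
                     min_obs = min_obs, taxon_id = taxon_id)
  }
  # score every original observation against the final fit
  scored <- score_against_fit(fit, log_mass, log_rpm, sample_ids,
                              flag_threshold, one_sided, table, taxon_id, mix)
  list(fit = fit, outliers = scored,
       excluded = sample_ids[!keep |
                             sample_ids %in% scored$sample_id[scored$is_outlier]],
       n_iter = n_iter)
}

# internal: studentized residuals of arbitrary points wrt a fit.
# Points inside the fit use the exact deletion identity; points excluded from
# the fit are scored as predictions (se of a new observation, full df).
score_against_fit <- function(fit, log_mass, log_rpm, sample_ids,
                              flag_threshold, one_sided,
                              table = NULL, taxon_id = NULL, mix = NULL) {
  inside <- sample_ids %in% fit$included_samples
  calls_in <- flag_outliers(fit, flag_threshold, one_sided, table, taxon_id, mix)
  if (all(inside)) return(calls_in[match(sample_ids, calls_in$sample_id), ,
                                   drop = FALSE])
  x <- fit$x; n <- fit$n_obs
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  x0 <- log_mass[!inside]; y0 <- log_rpm[!inside]
  pred <- fit$intercept + fit$slope * x0
  se_pred <- fit$residual_se * sqrt(1 + 1 / n + (x0 - xbar)^2 / sxx)
  t0 <- (y0 - pred) / se_pred
  p0 <- 2 * stats::pt(-abs(t0), df = n - 2)
  calls_out <- data.frame(
    sample_id = sample_ids[!inside],
    taxon_id = if (is.null(taxon_id)) fit$taxon_id else taxon_id,
    studentized_residual = t0,
    p_value = p0,
    p_bonferroni = pmin(1, p0 * length(sample_ids)),
    is_outlier = if (one_sided) t0 > flag_threshold else abs(t0) > flag_threshold,
    observed_reads = NA_real_,
    expected_reads = NA_real_,
    excess_reads = NA_real_,
    excess_mass_ag = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(table) && !is.null(mix) && !is.null(taxon_id)) {
    s <- calls_out$sample_id
    totals <- sample_totals(table)[s]
    ercc <- spike_totals(table)[s]
    calls_out$observed_reads <- as.numeric(table$counts[taxon_id, s])
    calls_out$expected_reads <- 10^pred * totals / 1e6
    calls_out$excess_reads <- pmax(calls_out$observed_reads - calls_out$expected_reads, 0)
    calls_out$excess_mass_ag <- mix$spike_mass_pg * 1e6 * calls_out$excess_reads / ercc
  }
  all_calls <- rbind(calls_in, calls_out)
  all_calls[match(sample_ids, all_calls$sample_id), , drop = FALSE]
}
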