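#' Fit one taxon's log-log frequency regression
#'
#' Ordinary least squares of `log10(rpm)` on `log10(input mass in pg)` with
#' an intercept — the frequency signature at the heart of the method: a taxon
#' introduced at fixed absolute mass dilutes as sample mass grows, so its
#' relative abundance falls inverse-linearly on the log-log scale. The fit is
#' computed in closed form (simple-regression normal equations), together
#' with the diagnostics the rest of the pipeline needs: adjusted R-squared,
#' the two-sided p-value for slope = 0 (t, n-2 df), per-observation residuals
#' and hat-matrix leverages, and the residual standard error.
#'
#' @param log_mass Numeric vector, log10 of input mass in pg.
#' @param log_rpm Numeric vector, log10 of reads-per-million; same length.
#' @param sample_ids Optional IDs per observation (defaults to indices).
#' @param min_obs Minimum observations for a fit (default 6). With fewer, a
#'   stub of class `taxon_fit_stub` (reason `"insufficient_obs"`) is returned
#'   instead of an error so callers can record the classification reason.
#' @param taxon_id Optional label carried into the result.
#' @return An object of class `taxon_fit` (or `taxon_fit_stub`).
#' @examples
#' f <- fit_taxon(0:3, 3 - (0:3))
#' c(f$slope, f$intercept, f$adj_r2)  # -1, 3, 1
#' @export
fit_taxon <- function(log_mass, log_rpm, sample_ids = NULL, min_obs = 6,
                      taxon_id = NA_character_) {
  if (length(log_mass) != length(log_rpm)) {
    stop("log_mass and log_rpm must have equal length", call. = FALSE)
  }
  n <- length(log_mass)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  if (is.null(taxon_id)) taxon_id <- NA_character_
  if (n < min_obs) {
    return(structure(list(taxon_id = taxon_id, n_obs = n,
                          reason = "insufficient_obs"),
                     class = "taxon_fit_stub"))
  }
  if (any(!is.finite(log_mass)) || any(!is.finite(log_rpm))) {
    stop("non-finite values in regression inputs", call. = FALSE)
  }
  x <- as.numeric(log_mass); y <- as.numeric(log_rpm)
  xbar <- mean(x); ybar <- mean(y)
  dx <- x - xbar
  sxx <- sum(dx^2)
  if (sxx <= .Machine$double.eps * n * max(1, xbar^2)) {
    stop("degenerate design: no variance in log input mass", call. = FALSE)
  }
  slope <- sum(dx * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * x
  e <- y - fitted
  sse <- sum(e^2)
  syy <- sum((y - ybar)^2)
  r2 <- if (syy > 0) 1 - sse / syy else 0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  residual_se <- sqrt(sse / (n - 2))
  se_slope <- residual_se / sqrt(sxx)
  p_slope <- if (se_slope > 0) {
    2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  } else if (abs(slope) > 0) 0 else 1
  h <- 1 / n + dx^2 / sxx
  structure(
    list(
      taxon_id = taxon_id,
      n_obs = n,
      slope = slope,
      intercept = intercept,
      r2 = r2,
      adj_r2 = adj_r2,
      p_slope = p_slope,
      residuals = e,
      leverages = h,
      fitted = fitted,
      residual_se = residual_se,
      se_slope = se_slope,
      x = x,
      y = y,
      included_samples = as.character(sample_ids)
    ),
    class = "taxon_fit"
  )
}

#' Externally studentized residuals of a taxon fit
#'
#' Each residual divided by its leave-one-out standard error:
#' `t_i = e_i / (s_(i) * sqrt(1 - h_ii))`, with `s_(i)` the residual standard
#' error of the regression refit without observation i, obtained through the
#' standard deletion identity `s_(i)^2 = (SSE - e_i^2 / (1 - h_ii)) / (n - 3)`.
#' Under Gaussian errors each `t_i` follows a t distribution with n-3 df, so
#' values beyond about +/-2 mark observations the regression cannot explain.
#' Leverages within 1e-12 of 1 yield a signed infinite sentinel with a
#' warning.
#'
#' @param fit A [fit_taxon()] result.
#' @return Numeric vector, one value per included observation.
#' @export
studentized_residuals <- function(fit) {
  stopifnot(inherits(fit, "taxon_fit"))
  e <- fit$residuals; h <- fit$leverages; n <- fit$n_obs
  if (n < 4) stop("externally studentized residuals need n >= 4", call. = FALSE)
  out <- numeric(n)
  degen <- h >= 1 - 1e-12
  if (any(degen)) {
    warning("degenerate leverage (h ~ 1) for observation(s) ",
            paste(which(degen), collapse = ", "), call. = FALSE)
  }
  sse <- sum(e^2)
  s2i <- pmax((sse - e^2 / pmax(1 - h, 1e-12)) / (n - 3), 0)
  denom <- sqrt(s2i * (1 - h))
  zero <- denom == 0
  out[!zero & !degen] <- e[!zero & !degen] / denom[!zero & !degen]
  out[zero & e == 0] <- 0
  out[zero & e != 0] <- sign(e[zero & e != 0]) * Inf
  out[degen] <- sign(e[degen]) * Inf
  out
}

#' @export
print.taxon_fit <- function(x, ...) {
  cat(sprintf("taxon_fit%s: n=%d slope=%.4g intercept=%.4g adj_r2=%.4g p=%.3g\n",
              if (is.na(x$taxon_id)) "" else paste0(" [", x$taxon_id, "]"),
              x$n_obs, x$slope, x$intercept, x$adj_r2, x$p_slope))
  invisible(x)
}
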