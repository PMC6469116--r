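# shared fixtures: all built in code, nothing read from disk except tempfiles

# minimal spike-in mix with equal transcripts
tiny_mix <- function(n = 3, spike_mass_pg = 25) {
  ercc_mix(data.frame(
    transcript_id = sprintf("ERCC-%05d", seq_len(n)),
    length_nt = rep(1000L, n),
    concentration = rep(1, n)
  ), spike_mass_pg = spike_mass_pg)
}

# small count matrix with one spike row
tiny_counts <- function() {
  m <- matrix(c(1000, 2000,
                9000, 8000,
                  10,    0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("ERCC-00001", "host", "taxon_x"),
                              c("A", "B")))
  m
}

write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

# a scenario in which contaminants are comfortably detectable: host-dominant
# masses well above the spike, contaminant masses of ~0.1-0.5 pg
detectable_dilution <- function(seed = 7, depth_mean = 2e5, ...) {
  args <- list(
    n_masses = 12, replicates = 3,
    mass_min_pg = 100, mass_max_pg = 10000, mass_spacing = "log",
    spike_mass_pg = 25, depth_mean = depth_mean, depth_cv = 0.1,
    contaminant_panel = data.frame(taxon_id = c("con_A", "con_B"),
                                   mass_ag = c(5e5, 1e5),
                                   stringsAsFactors = FALSE),
    community_panel = data.frame(taxon_id = "comm_X", proportion = 1e-3,
                                 stringsAsFactors = FALSE),
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

# literal leave-one-out refits: the independent oracle for externally
# studentized residuals
loo_studentized <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    f <- stats::lm(y[-i] ~ x[-i])
    pred <- sum(coef(f) * c(1, x[i]))
    xbar <- mean(x[-i]); sxx <- sum((x[-i] - xbar)^2)
    s <- summary(f)$sigma
    se <- s * sqrt(1 + 1 / (n - 1) + (x[i] - xbar)^2 / sxx)
    (y[i] - pred) / se
  }, numeric(1))
}
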