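#' Scenario configuration for the synthetic count-table generator
#'
#' Describes one simulated batch: the input-mass design, the spike-in, the
#' panel of fixed-mass contaminants (reagent background, attograms per
#' library regardless of input), the panel of community taxa (true sample
#' constituents at a fixed proportion of input mass), an optional infected
#' sample carrying excess mass of one contaminant taxon, sequencing depth,
#' and overdispersion.
#'
#' @param n_masses Number of distinct input masses (or libraries when
#'   `replicates = 1`).
#' @param replicates Libraries per mass.
#' @param mass_min_pg,mass_max_pg Mass range, picograms (for `"log"` /
#'   `"linear"` spacing).
#' @param mass_spacing `"log"`, `"linear"`, or `"lognormal"` (random masses;
#'   see `mass_median_pg`, `mass_cv`).
#' @param mass_median_pg,mass_cv Median (pg) and coefficient of variation of
#'   lognormal input masses; used only when `mass_spacing = "lognormal"`.
#' @param spike_mass_pg Spiked mass per library, picograms (default 25).
#' @param depth_mean Mean library depth in reads (default 5e5).
#' @param depth_cv Coefficient of variation of the lognormal depth draw
#'   (default 0.1).
#' @param contaminant_panel data.frame with `taxon_id`, `mass_ag`: fixed mass
#'   per library of each contaminant.
#' @param community_panel Optional data.frame with `taxon_id`, `proportion`:
#'   each taxon's fixed proportion of the input mass (proportions in (0,1),
#'   summing to at most 1; the host carries the remainder).
#' @param infected Optional list `(sample_index, taxon_id, extra_mass_ag)`:
#'   one library carries that much extra mass of a contaminant taxon.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default) is
#'   pure multinomial sampling, larger values scale down the Dirichlet
#'   concentration (`alpha = expected_fractions / overdispersion`).
#' @param seed Integer seed; all draws come from one generator in documented
#'   order (per library: depth, then composition when overdispersed, then
#'   counts).
#' @return A list of class `scenario_config`.
#' @seealso [dilution_config()], [serum_config()], [simulate_scenario()]
#' @export
scenario_config <- function(n_masses, replicates = 1,
                            mass_min_pg = NULL, mass_max_pg = NULL,
                            mass_spacing = c("log", "linear", "lognormal"),
                            mass_median_pg = NULL, mass_cv = NULL,
                            spike_mass_pg = 25,
                            depth_mean = 5e5, depth_cv = 0.1,
                            contaminant_panel = NULL,
                            community_panel = NULL,
                            infected = NULL,
                            overdispersion = 0,
                            seed = 1) {
  mass_spacing <- match.arg(mass_spacing)
  stopifnot(n_masses >= 1, replicates >= 1, n_masses * replicates >= 2,
            depth_mean > 0, depth_cv >= 0, overdispersion >= 0,
            spike_mass_pg > 0)
  if (mass_spacing == "lognormal") {
    stopifnot(!is.null(mass_median_pg), mass_median_pg > 0,
              !is.null(mass_cv), mass_cv > 0)
  } else {
    stopifnot(!is.null(mass_min_pg), !is.null(mass_max_pg),
              mass_min_pg > 0, mass_min_pg < mass_max_pg)
  }
  if (!is.null(contaminant_panel)) {
    stopifnot(is.data.frame(contaminant_panel),
              all(c("taxon_id", "mass_ag") %in% names(contaminant_panel)),
              all(contaminant_panel$mass_ag > 0),
              !anyDuplicated(contaminant_panel$taxon_id))
  }
  if (!is.null(community_panel)) {
    stopifnot(is.data.frame(community_panel),
              all(c("taxon_id", "proportion") %in% names(community_panel)),
              all(community_panel$proportion > 0),
              all(community_panel$proportion < 1),
              sum(community_panel$proportion) <= 1,
              !anyDuplicated(community_panel$taxon_id))
  }
  if (!is.null(infected)) {
    stopifnot(is.list(infected),
              all(c("sample_index", "taxon_id", "extra_mass_ag") %in% names(infected)),
              infected$extra_mass_ag > 0)
  }
  structure(
    list(n_masses = as.integer(n_masses), replicates = as.integer(replicates),
         mass_min_pg = mass_min_pg, mass_max_pg = mass_max_pg,
         mass_spacing = mass_spacing, mass_median_pg = mass_median_pg,
         mass_cv = mass_cv, spike_mass_pg = spike_mass_pg,
         depth_mean = depth_mean, depth_cv = depth_cv,
         contaminant_panel = contaminant_panel,
         community_panel = community_panel, infected = infected,
         overdispersion = overdispersion, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Default contaminant panel
#'
#' The five named reagent contaminants of the reference dilution experiment
#' at their reported mean per-sample masses, plus a ten-taxon minor tail
#' (geometric decay) bringing the panel total to 9.1 ag. The tail is a
#' modeling device: published results name only the top five taxa but report
#' the 9.1 ag batch total, so the remaining 4.05 ag is spread over unnamed
#' minor contaminants.
#'
#' @return data.frame with `taxon_id`, `mass_ag` (15 rows summing to 9.1).
#' @export
default_contaminant_panel <- function() {
  named <- data.frame(
    taxon_id = c("Escherichia_coli", "Saccharomyces_cerevisiae",
                 "Stenotrophomonas_maltophilia", "cloning_vector",
                 "Achromobacter_xylosoxidans"),
    mass_ag = c(2.59, 1.02, 0.61, 0.43, 0.40),
    stringsAsFactors = FALSE
  )
  w <- 0.85^(0:9)
  tail <- data.frame(
    taxon_id = sprintf("minor_contaminant_%02d", 1:10),
    mass_ag = 4.05 * w / sum(w),
    stringsAsFactors = FALSE
  )
  rbind(named, tail)
}

#' Default dilution-series scenario
#'
#' Emulates the reference spike-in dilution experiment: 32 log-spaced input
#' masses from 1 pg to 2500 pg, each in triplicate (96 libraries), 25 pg
#' spike, host RNA at the full input mass, and the
#' [default_contaminant_panel()] (9.1 ag total). Depth is lognormal with
#' mean 5e5 reads and CV 0.1 — a desk-scale depth at which a full scenario
#' simulates in well under a second.
#'
#' @param seed Integer seed (default 1).
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
dilution_config <- function(seed = 1, ...) {
  args <- list(n_masses = 32, replicates = 3,
               mass_min_pg = 1, mass_max_pg = 2500, mass_spacing = "log",
               spike_mass_pg = 25, depth_mean = 5e5, depth_cv = 0.1,
               contaminant_panel = default_contaminant_panel(),
               overdispersion = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

#' Default serum-batch scenario
#'
#' Emulates a clinical batch: 97 libraries with lognormally distributed
#' input masses (median 100 pg, CV 0.5), 25 pg spike, the same contaminant
#' panel as the dilution scenario, and one infected sample (index 42)
#' carrying an extra 50 ag of Escherichia coli on top of its contamination
#' background.
#'
#' @param seed Integer seed (default 1).
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
serum_config <- function(seed = 1, ...) {
  args <- list(n_masses = 97, replicates = 1,
               mass_spacing = "lognormal", mass_median_pg = 100, mass_cv = 0.5,
               spike_mass_pg = 25, depth_mean = 5e5, depth_cv = 0.1,
               contaminant_panel = default_contaminant_panel(),
               infected = list(sample_index = 42,
                               taxon_id = "Escherichia_coli",
                               extra_mass_ag = 50),
               overdispersion = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

#' Simulate a count table from a scenario
#'
#' Each library is a mass pool: host at the input mass, community taxa at
#' their proportions of input mass, contaminants at their fixed attogram
#' masses (plus the infected sample's excess), and the spike split over the
#' ERCC transcripts by [mass_fractions()]. Reads are allocated proportional
#' to component mass — the same assumption the mass-ratio estimator makes —
#' by a multinomial draw at a lognormal depth (Dirichlet-multinomial when
#' `overdispersion > 0`). Counts per library sum exactly to the drawn depth;
#' expected fractions sum exactly to 1. The same seed reproduces the output
#' byte-for-byte; the caller's RNG state is left untouched.
#'
#' @param config A [scenario_config()].
#' @param mix An [ercc_mix()] providing the spike transcripts (default the
#'   bundled 92-transcript sheet); its total mass is taken from
#'   `config$spike_mass_pg`.
#' @return A list of class `contam_sim`: `table` ([count_table()], ERCC rows
#'   first, then host, contaminants, community), `metadata` (data.frame
#'   `sample_id`, `input_mass_pg`, `group`, `is_control`), and `truth`
#'   (seed plus per-sample input mass, depth, injected taxon masses in ag,
#'   and expected read fractions).
#' @export
simulate_scenario <- function(config, mix = load_ercc_reference()) {
  stopifnot(inherits(config, "scenario_config"), inherits(mix, "ercc_mix"))
  mix <- ercc_mix(mix$transcripts, spike_mass_pg = config$spike_mass_pg)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_lib <- config$n_masses * config$replicates
  if (config$mass_spacing == "lognormal") {
    sdlog <- sqrt(log(1 + config$mass_cv^2))
    masses <- stats::rlnorm(n_lib, meanlog = log(config$mass_median_pg),
                            sdlog = sdlog)
    sample_ids <- sprintf("S%02d", seq_len(n_lib))
    groups <- rep(NA_character_, n_lib)
  } else {
    base <- if (config$mass_spacing == "log") {
      10^seq(log10(config$mass_min_pg), log10(config$mass_max_pg),
             length.out = config$n_masses)
    } else {
      seq(config$mass_min_pg, config$mass_max_pg,
          length.out = config$n_masses)
    }
    masses <- rep(base, each = config$replicates)
    rep_id <- rep(seq_len(config$replicates), times = config$n_masses)
    sample_ids <- sprintf("M%02d_r%d",
                          rep(seq_len(config$n_masses), each = config$replicates),
                          rep_id)
    groups <- sprintf("mass_%02d", rep(seq_len(config$n_masses),
                                       each = config$replicates))
  }
  if (!is.null(config$infected) &&
      (config$infected$sample_index < 1 ||
       config$infected$sample_index > n_lib)) {
    stop("infected sample_index out of range 1..", n_lib, call. = FALSE)
  }

  ercc_ids <- mix$transcripts$transcript_id
  ercc_mass_ag <- config$spike_mass_pg * 1e6 * mass_fractions(mix)
  contam <- config$contaminant_panel
  community <- config$community_panel
  taxa <- c(ercc_ids, "host",
            if (!is.null(contam)) contam$taxon_id,
            if (!is.null(community)) community$taxon_id)
  if (!is.null(config$infected) &&
      !config$infected$taxon_id %in% taxa) {
    stop("infected taxon not in the contaminant panel: ",
         config$infected$taxon_id, call. = FALSE)
  }

  counts <- matrix(0, nrow = length(taxa), ncol = n_lib,
                   dimnames = list(taxa, sample_ids))
  depths <- numeric(n_lib)
  truth_samples <- vector("list", n_lib)
  sdlog_d <- sqrt(log(1 + config$depth_cv^2))
  for (j in seq_len(n_lib)) {
    m_pg <- masses[j]
    host_ag <- m_pg * 1e6
    comm_ag <- if (!is.null(community)) community$proportion * host_ag else numeric(0)
    host_ag <- host_ag - sum(comm_ag)  # community taxa are part of the input mass
    con_ag <- if (!is.null(contam)) contam$mass_ag else numeric(0)
    names(con_ag) <- if (!is.null(contam)) contam$taxon_id
    if (!is.null(config$infected) && j == config$infected$sample_index) {
      con_ag[config$infected$taxon_id] <-
        con_ag[config$infected$taxon_id] + config$infected$extra_mass_ag
    }
    pool <- c(ercc_mass_ag, host = host_ag, con_ag,
              if (!is.null(community)) stats::setNames(comm_ag, community$taxon_id))
    frac <- pool / sum(pool)
    depth <- if (config$depth_cv > 0) {
      max(1, round(stats::rlnorm(1, meanlog = log(config$depth_mean) - sdlog_d^2 / 2,
                                 sdlog = sdlog_d)))
    } else {
      round(config$depth_mean)
    }
    p <- if (config$overdispersion > 0) {
      g <- stats::rgamma(length(frac), shape = frac / config$overdispersion,
                         rate = 1)
      if (sum(g) == 0) frac else g / sum(g)
    } else {
      frac
    }
    counts[, j] <- stats::rmultinom(1, size = depth, prob = p)[, 1]
    depths[j] <- depth
    injected <- c(host = unname(host_ag), con_ag,
                  if (!is.null(community)) stats::setNames(comm_ag, community$taxon_id))
    truth_samples[[j]] <- list(
      input_mass_pg = m_pg,
      depth = depth,
      injected_mass_ag = as.list(injected),
      expected_fractions = as.list(frac)
    )
  }
  names(truth_samples) <- sample_ids
  metadata <- data.frame(sample_id = sample_ids, input_mass_pg = masses,
                         group = groups, is_control = FALSE,
                         stringsAsFactors = FALSE)
  structure(
    list(table = count_table(counts, spike_prefix = "ERCC-"),
         metadata = metadata,
         truth = list(seed = config$seed, scenario = config$mass_spacing,
                      spike_mass_pg = config$spike_mass_pg,
                      infected = config$infected,
                      per_sample = truth_samples)),
    class = "contam_sim"
  )
}

#' Write a simulated scenario to disk
#'
#' Writes `counts.tsv`, `metadata.tsv` and `truth.json` into `outdir`.
#'
#' @param sim A [simulate_scenario()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_scenario <- function(sim, outdir) {
  stopifnot(inherits(sim, "contam_sim"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p1 <- write_counts(sim$table, file.path(outdir, "counts.tsv"))
  md <- sim$metadata
  lines <- c(
    paste(c("sample_id", "input_mass_pg", "group", "is_control"),
          collapse = "\t"),
    vapply(seq_len(nrow(md)), function(i) {
      paste(c(md$sample_id[i],
              format(md$input_mass_pg[i], digits = 10, trim = TRUE,
                     scientific = FALSE),
              ifelse(is.na(md$group[i]), "NA", md$group[i]),
              tolower(md$is_control[i])), collapse = "\t")
    }, character(1))
  )
  p2 <- write_lines_lf(lines, file.path(outdir, "metadata.tsv"))
  p3 <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth, p3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(p1, p2, p3))
}

#' @export
print.contam_sim <- function(x, ...) {
  cat(sprintf("contam_sim (seed %d): %d samples, %d taxa rows\n",
              x$truth$seed, ncol(x$table$counts), nrow(x$table$counts)))
  invisible(x)
}
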