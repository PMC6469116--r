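test_that("fixed-mass contaminants are classified and mass-quantified; mass-tracking taxa are not", {
  sim <- simulate_scenario(detectable_dilution(seed = 7))
  rep <- analyze_contamination(sim$table, sim$metadata)
  f <- rep$fits
  expect_true(all(f$is_contaminant[f$taxon_id %in% c("con_A", "con_B")]))
  expect_false(any(f$is_contaminant[f$taxon_id %in% c("host", "comm_X")]))
  # slopes near -1 in the host-dominant regime
  expect_equal(unname(f$slope[f$taxon_id == "con_A"]), -1, tolerance = 0.15)
  expect_equal(unname(f$slope[f$taxon_id == "con_B"]), -1, tolerance = 0.15)
  # recovered masses near the injected truths
  expect_equal(rep$masses[["con_A"]]$mean_mass_ag, 5e5, tolerance = 0.25)
  expect_equal(rep$masses[["con_B"]]$mean_mass_ag, 1e5, tolerance = 0.25)
  # BH-adjusted p present for every fitted taxon
  expect_true(all(!is.na(f$p_adj[!is.na(f$p_slope)])))
})

test_that("per-sample totals are exactly additive over contaminant taxa", {
  sim <- simulate_scenario(detectable_dilution(seed = 8))
  mix <- load_ercc_reference()
  rep <- analyze_contamination(sim$table, sim$metadata)
  contams <- rownames(rep$mass_matrix)
  manual <- Reduce(`+`, lapply(contams, function(t) {
    quantify_taxon_mass(sim$table, t, mix)$per_sample$mass_ag
  }))
  expect_equal(rep$totals$per_sample$total_mass_ag, manual)
  expect_equal(rep$totals$mean_ag, mean(manual))
})

test_that("classification is invariant to sample relabeling and reordering", {
  sim <- simulate_scenario(detectable_dilution(seed = 10))
  rep1 <- analyze_contamination(sim$table, sim$metadata)

  set.seed(1)
  perm <- sample(ncol(sim$table$counts))
  m <- sim$table$counts[, perm]
  colnames(m) <- sprintf("x%02d", seq_len(ncol(m)))
  md <- sim$metadata[perm, ]
  md$sample_id <- colnames(m)
  rep2 <- analyze_contamination(count_table(m), md)
  cols <- c("taxon_id", "slope", "adj_r2", "is_contaminant", "classification")
  expect_equal(rep2$fits[cols], rep1$fits[cols], tolerance = 1e-12)
})

test_that("a batch with no contamination signature yields an empty classification", {
  # host + spike only: host tracks mass, nothing has the inverse signature
  cfg <- detectable_dilution(seed = 11, contaminant_panel = NULL,
                             community_panel = NULL)
  sim <- simulate_scenario(cfg)
  rep <- analyze_contamination(sim$table, sim$metadata)
  expect_equal(sum(rep$fits$is_contaminant), 0)
  expect_equal(nrow(rep$mass_matrix), 0)
  expect_equal(rep$totals$mean_ag, 0)

  out <- file.path(tempdir(), "empty_report")
  write_report(rep, out)
  cm <- readLines(file.path(out, "contaminant_mass.tsv"))
  expect_length(cm, 1)  # header only
})

test_that("result files are written with stable layout and are reproducible", {
  sim <- simulate_scenario(detectable_dilution(seed = 12))
  rep <- analyze_contamination(sim$table, sim$metadata)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_report(rep, d1, seed = 12)
  write_report(rep, d2, seed = 12)
  files <- c("taxa_fits.tsv", "contaminant_mass.tsv", "outliers.tsv",
             "sample_mass.tsv", "run_info.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # contaminant_mass.tsv: one column per sample, in input order, plus summary
  header <- strsplit(readLines(file.path(d1, "contaminant_mass.tsv"), n = 1),
                     "\t")[[1]]
  expect_identical(header,
                   c("taxon_id", colnames(sim$table$counts), "mean_ag", "sd_ag"))
  info <- jsonlite::read_json(file.path(d1, "run_info.json"))
  expect_equal(info$seed, 12)
  expect_equal(info$config$r2_threshold, 0.7)
})

test_that("pseudocount mode keeps zero-count samples in the fit", {
  sim <- simulate_scenario(detectable_dilution(seed = 13))
  n_zero <- sum(sim$table$counts["con_B", ] == 0)
  rep0 <- analyze_contamination(sim$table, sim$metadata)
  repc <- analyze_contamination(sim$table, sim$metadata,
                                config = contam_config(pseudocount = 0.5))
  n_all <- ncol(sim$table$counts)
  expect_equal(repc$fits$n_obs[repc$fits$taxon_id == "con_B"], n_all)
  expect_lte(rep0$fits$n_obs[rep0$fits$taxon_id == "con_B"], n_all - n_zero)
})
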