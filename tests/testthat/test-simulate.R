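test_that("default dilution scenario matches its stated design", {
  cfg <- dilution_config()
  sim <- simulate_scenario(cfg)
  expect_equal(ncol(sim$table$counts), 96)
  masses <- sim$metadata$input_mass_pg
  expect_equal(range(masses), c(1, 2500))
  expect_equal(sum(sim$table$is_spike), 92)
  expect_equal(cfg$spike_mass_pg, 25)
  expect_equal(sum(default_contaminant_panel()$mass_ag), 9.1,
               tolerance = 1e-12)
})

test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_scenario(dilution_config(seed = 4))
  expect_identical(.Random.seed, before)
  s2 <- simulate_scenario(dilution_config(seed = 4))
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_scenario(dilution_config(seed = 5))
  expect_false(identical(s1$table$counts, s3$table$counts))

  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_scenario(s1, d1); write_scenario(s2, d2)
  for (f in c("counts.tsv", "metadata.tsv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("expected fractions follow component mass over pool mass", {
  sim <- simulate_scenario(dilution_config(seed = 1))
  top <- sim$truth$per_sample[["M32_r1"]]
  expect_equal(top$input_mass_pg, 2500)
  # closed-form oracle, all in attograms
  pool <- 2500e6 + 25e6 + 9.1
  expect_equal(top$expected_fractions[["Escherichia_coli"]], 2.59 / pool,
               tolerance = 1e-12)
  for (s in sample(names(sim$truth$per_sample), 5)) {
    fr <- unlist(sim$truth$per_sample[[s]]$expected_fractions)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_equal(sum(sim$table$counts[, s]), sim$truth$per_sample[[s]]$depth)
  }
  # equal masses, no contaminants: spike takes exactly half the pool
  eq <- scenario_config(n_masses = 2, replicates = 1, mass_min_pg = 25,
                        mass_max_pg = 25.0000001, mass_spacing = "log",
                        spike_mass_pg = 25, seed = 1)
  sim_eq <- simulate_scenario(eq)
  fr <- unlist(sim_eq$truth$per_sample[[1]]$expected_fractions)
  expect_equal(sum(fr[startsWith(names(fr), "ERCC-")]), 0.5, tolerance = 1e-8)
})

test_that("serum scenario has 97 libraries and a single infected sample", {
  sim <- simulate_scenario(serum_config(seed = 2))
  expect_equal(ncol(sim$table$counts), 97)
  expect_true(all(sim$metadata$input_mass_pg > 0))
  inf <- sim$truth$infected
  expect_equal(inf$sample_index, 42)
  expect_equal(inf$taxon_id, "Escherichia_coli")
  base <- default_contaminant_panel()
  excess <- vapply(sim$truth$per_sample, function(p) {
    p$injected_mass_ag[["Escherichia_coli"]] -
      base$mass_ag[base$taxon_id == "Escherichia_coli"]
  }, numeric(1))
  expect_equal(sum(excess > 0), 1)
  expect_equal(unname(excess[42]), 50)
})

test_that("config validation catches impossible scenarios", {
  expect_error(simulate_scenario(
    serum_config(infected = list(sample_index = 200,
                                 taxon_id = "Escherichia_coli",
                                 extra_mass_ag = 50))),
    "out of range")
  expect_error(simulate_scenario(
    serum_config(infected = list(sample_index = 1, taxon_id = "nope",
                                 extra_mass_ag = 50))),
    "not in the contaminant panel")
  expect_error(scenario_config(n_masses = 1, replicates = 1,
                               mass_min_pg = 1, mass_max_pg = 10))
  expect_error(scenario_config(n_masses = 4, mass_min_pg = 10, mass_max_pg = 1))
  expect_error(scenario_config(n_masses = 4, mass_min_pg = 1, mass_max_pg = 10,
                               community_panel = data.frame(taxon_id = "a",
                                                            proportion = 1.2)))
})

test_that("overdispersion produces valid, seed-stable, noisier tables", {
  cfg <- detectable_dilution(seed = 9, overdispersion = 0.05)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$table$counts, s2$table$counts)
  depths <- vapply(s1$truth$per_sample, `[[`, numeric(1), "depth")
  expect_equal(unname(colSums(s1$table$counts)), unname(depths))
})

test_that("expected-value rpm slope approaches -1 when host mass dominates", {
  cfg <- scenario_config(n_masses = 10, replicates = 1, mass_min_pg = 1e5,
                         mass_max_pg = 1e7, mass_spacing = "log",
                         contaminant_panel = data.frame(taxon_id = "con",
                                                        mass_ag = 2.59),
                         seed = 1)
  sim <- simulate_scenario(cfg)
  x <- log10(vapply(sim$truth$per_sample, `[[`, numeric(1), "input_mass_pg"))
  y <- log10(vapply(sim$truth$per_sample, function(p) {
    p$expected_fractions[["con"]] * 1e6
  }, numeric(1)))
  f <- fit_taxon(x, y)
  expect_equal(f$slope, -1, tolerance = 1e-3)
})

test_that("mass recovery error shrinks with depth for a detectable contaminant", {
  med_err <- vapply(c(1e4, 1e5, 1e6), function(d) {
    errs <- vapply(1:3, function(s) {
      sim <- simulate_scenario(detectable_dilution(seed = s, depth_mean = d))
      q <- quantify_taxon_mass(sim$table, "con_A", load_ercc_reference())
      abs(q$per_sample$mass_ag - 5e5) / 5e5
    }, numeric(36))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})
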