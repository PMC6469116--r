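test_that("rpm normalizes against the all-row sample total", {
  m <- matrix(c(999000, 1000), nrow = 2,
              dimnames = list(c("host", "ERCC-00001"), "s1"))
  ct <- count_table(m)
  expect_equal(unname(rpm(ct)["ERCC-00001", "s1"]), 1000)

  sim <- simulate_scenario(detectable_dilution(seed = 2))
  r <- rpm(sim$table)
  expect_equal(unname(colSums(r)), rep(1e6, ncol(r)), tolerance = 1e-9)

  # uniform rescaling of a sample leaves its rpm column unchanged
  m2 <- sim$table$counts
  m2[, 1] <- m2[, 1] * 2
  expect_equal(rpm(count_table(m2))[, 1], r[, 1], tolerance = 1e-12)
})

test_that("sample mass inference follows the spike-in read ratio", {
  m <- matrix(c(1000, 1000,
                1000, 10000),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("ERCC-00001", "host"), c("A", "B")))
  ct <- count_table(m)
  est <- estimate_sample_mass(ct, tiny_mix(), mode = "inferred")
  expect_equal(est$mass_pg, c(25, 250))  # ratio 1 and ratio 10
  expect_equal(est$source, c("inferred", "inferred"))
  expect_equal(est$ercc_reads, c(1000, 1000))

  meta <- data.frame(sample_id = c("A", "B"), input_mass_pg = c(40, NA))
  given <- estimate_sample_mass(ct, tiny_mix(), meta, mode = "auto")
  expect_equal(given$mass_pg, c(40, 250))
  expect_equal(given$source, c("given", "inferred"))

  expect_error(estimate_sample_mass(ct, tiny_mix(), meta, mode = "given"),
               "B")
  low <- count_table(matrix(c(10, 5000), nrow = 2,
                            dimnames = list(c("ERCC-00001", "host"), "A")))
  expect_error(estimate_sample_mass(low, tiny_mix(), mode = "inferred"),
               "spike reads.*A")
})

test_that("inferred masses recover simulated truth within 5% at deep coverage", {
  cfg <- scenario_config(n_masses = 8, replicates = 3, mass_min_pg = 1,
                         mass_max_pg = 2500, mass_spacing = "log",
                         depth_mean = 1e6, depth_cv = 0.1,
                         contaminant_panel = default_contaminant_panel(),
                         seed = 1)
  sim <- simulate_scenario(cfg)
  est <- estimate_sample_mass(sim$table, load_ercc_reference(),
                              mode = "inferred")
  truth <- vapply(sim$truth$per_sample, `[[`, numeric(1), "input_mass_pg")
  rel_err <- abs(est$mass_pg - truth) / truth
  expect_lt(max(rel_err), 0.05)
})

test_that("taxon mass quantification solves the spike-in ratio equation", {
  m <- matrix(c(1e6, 1e6,
                  10, 1e6,
                 1e6, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("ERCC-00001", "taxon_a", "taxon_b"),
                              c("s1", "s2")))
  ct <- count_table(m)
  mix <- tiny_mix()
  qa <- quantify_taxon_mass(ct, "taxon_a", mix)
  # counts 10 vs 1e6 spike reads at 25 pg -> 250 ag; equal counts -> 2.5e7 ag
  expect_equal(qa$per_sample$mass_ag, c(250, 2.5e7))
  qb <- quantify_taxon_mass(ct, "taxon_b", mix)
  expect_equal(qb$per_sample$mass_ag, c(2.5e7, 0))
  expect_equal(qb$mean_mass_ag, 1.25e7)
  expect_equal(qb$sd_mass_ag, stats::sd(c(2.5e7, 0)))

  expect_error(quantify_taxon_mass(ct, "nope", mix), "not found")
  expect_error(quantify_taxon_mass(ct, "ERCC-00001", mix), "spike-in")
  expect_error(quantify_taxon_mass(ct, "taxon_a", mix,
                                   include_samples = character(0)), "empty")
  expect_error(quantify_taxon_mass(ct, "taxon_a", mix,
                                   include_samples = "zz"), "unknown")
})

test_that("mass estimates are linear in counts and identical under rpm", {
  sim <- simulate_scenario(detectable_dilution(seed = 5))
  ct <- sim$table
  mix <- load_ercc_reference()
  q1 <- quantify_taxon_mass(ct, "con_A", mix)

  m2 <- ct$counts
  m2["con_A", ] <- m2["con_A", ] * 2
  q2 <- quantify_taxon_mass(count_table(m2), "con_A", mix)
  expect_equal(q2$per_sample$mass_ag, 2 * q1$per_sample$mass_ag,
               tolerance = 1e-12)

  # the per-sample total cancels: rpm in place of raw counts gives the same mass
  r <- rpm(ct)
  ercc_rpm <- colSums(r[ct$is_spike, , drop = FALSE])
  mass_rpm <- mix$spike_mass_pg * 1e6 * r["con_A", ] / ercc_rpm
  expect_equal(unname(mass_rpm), q1$per_sample$mass_ag, tolerance = 1e-12)
})
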