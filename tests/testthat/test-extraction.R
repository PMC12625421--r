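test_that("partition coefficient follows logP with an optional similarity factor", {
  cbd <- cannabinoid_properties("CBD")
  expect_equal(partition_coefficient(cbd), 10^6.3, tolerance = 1e-12)
  expect_equal(partition_coefficient(cbd, similarity = 0.5), 0.5 * 10^6.3)
  hypo <- solute_properties("hypothetical", 1, logP = 0)
  expect_equal(partition_coefficient(hypo), 1)
  no_logp <- solute_properties("x", 1)
  expect_error(partition_coefficient(no_logp), "supply a partition")
})

test_that("bundled solute records carry the reported constants", {
  thc <- cannabinoid_properties("THC")
  expect_equal(thc$water_solubility_mg_L, 2.8)  # 0.0028 mg/mL
  cbd <- cannabinoid_properties("CBD")
  expect_equal(cbd$water_solubility_mg_L, 12.6)
  expect_equal(cbd$pKa, 9.1)
  expect_equal(unname(cbd$solubility_in["DMSO"]), 60)
})

test_that("roasting limits: no kinetics means no transfer; fast kinetics empties the husk", {
  exp0 <- extraction_experiment(k_per_min = 0)
  r0 <- roast_extract(exp0)
  expect_equal(r0$thc_in_oil, 0)
  expect_equal(r0$thc_in_residue, r0$initial_thc_mg)

  expfast <- extraction_experiment(k_per_min = 1e6)
  rfast <- roast_extract(expfast, K = Inf)
  pools <- seed_thc_pools(5)
  # all husk THC has left the seed interior (oil phase = free + surface film)
  expect_equal(rfast$thc_residue_internal, pools$kernel_thc_mg,
               tolerance = 1e-12)
  expect_equal(rfast$thc_in_oil + rfast$thc_residue_surface,
               pools$husk_thc_mg, tolerance = 1e-12)
})

test_that("oil bookkeeping: absorption capacity, recovery, and the no-free-oil flag", {
  for (frac in c(0.10, 0.20, 0.30, 0.40)) {
    r <- roast_extract(extraction_experiment(oil_fraction = frac))
    oil_in <- frac * 5
    expect_equal(r$oil_recovered + r$oil_absorbed, oil_in, tolerance = 1e-12)
    retained <- r$oil_absorbed / oil_in
    expect_gte(retained, 0.05)
    expect_lte(retained, 0.25)
  }
  # capacity set so oil only separates above a 20% oil fraction
  r10 <- roast_extract(extraction_experiment(oil_fraction = 0.10,
                                             oil_absorption_g_per_g = 0.2))
  expect_true("no_free_oil" %in% r10$flags)
  expect_equal(r10$thc_in_oil, 0)
  r30 <- roast_extract(extraction_experiment(oil_fraction = 0.30,
                                             oil_absorption_g_per_g = 0.2))
  expect_false("no_free_oil" %in% r30$flags)
  expect_warning(extraction_experiment(oil_fraction = 0.05), "10-40%")
})

test_that("recovered-oil THC barely changes between 10% and 40% oil once oil separates", {
  lo <- roast_extract(extraction_experiment(oil_fraction = 0.10))
  hi <- roast_extract(extraction_experiment(oil_fraction = 0.40))
  expect_gt(lo$oil_recovered, 0)
  expect_equal(lo$thc_in_oil, hi$thc_in_oil,
               tolerance = 0.10 * hi$thc_in_oil)
})

test_that("wash transfer is capped by aqueous solubility; reuse removes no more than fresh", {
  exp <- extraction_experiment()
  roast <- roast_extract(exp)
  w1 <- wash_cycle(roast)
  cap <- 2.8 * (20 / 1000)  # 2.8 mg/L in 20 mL
  expect_lte(w1$water_dissolved_mg, cap + 1e-12)
  expect_lte(w1$water_dissolved_mg / (20 / 1000), 2.8 + 1e-12)

  # already-saturated reused water takes up nothing
  sat <- w1
  w_sat <- wash_cycle(sat, reuse = TRUE)
  if (w1$water_dissolved_mg >= cap - 1e-12) {
    expect_equal(w_sat$thc_in_water, w1$thc_in_water, tolerance = 1e-12)
  }

  state_fresh <- roast
  state_reuse <- roast
  for (i in 1:4) {
    state_fresh <- wash_cycle(state_fresh, reuse = FALSE)
    state_reuse <- wash_cycle(state_reuse, reuse = TRUE)
  }
  expect_lte(state_reuse$thc_in_water, state_fresh$thc_in_water + 1e-12)
})

test_that("aliquot of the final wash scales by the volume fraction", {
  w <- wash_cycle(roast_extract(extraction_experiment()))
  al <- wash_aliquot(w, final_volume_mL = 20, aliquot_mL = 1)
  expect_equal(al$aliquot_fraction, 1 / 20)
  expect_equal(al$aliquot_thc_mg, w$water_dissolved_mg / 20)
})

test_that("protocol composition: zero washes equals the roast stage; zero-THC seed stays zero", {
  exp <- extraction_experiment(wash_cycles = 0)
  p <- run_protocol(exp)
  r <- roast_extract(exp)
  expect_equal(p$final$thc_in_residue, r$thc_in_residue)
  expect_equal(p$final$residue_concentration, r$residue_concentration)
  expect_length(p$stages, 1L)

  blank <- list(f_H = 0.10, rho_ratio = 1.5, C_H = 0, C_C = 0)
  pb <- run_protocol(extraction_experiment(), blank)
  expect_equal(pb$final$thc_in_oil, 0)
  expect_equal(pb$final$thc_in_water, 0)
  expect_equal(pb$final$thc_in_residue, 0)
})

test_that("THC mass is conserved across random protocols", {
  set.seed(21)
  for (i in 1:300) {
    exp <- suppressWarnings(extraction_experiment(
      seed_mass_g = runif(1, 1, 50),
      oil_fraction = runif(1, 0.05, 0.5),
      duration_min = runif(1, 0, 120),
      wash_water_ratio = runif(1, 1, 8),
      wash_cycles = sample(0:6, 1),
      reuse_water = sample(c(TRUE, FALSE), 1),
      k_per_min = runif(1, 0, 1),
      oil_absorption_g_per_g = runif(1, 0, 0.3),
      oil_phase_split = runif(1),
      wash_efficiency = runif(1)))
    p <- run_protocol(exp)
    expect_lt(p$mass_balance_error, 1e-9)
    f <- p$final
    expect_equal(f$oil_recovered + f$oil_absorbed,
                 exp$oil_fraction * exp$seed_mass_g, tolerance = 1e-12)
    if (f$water_volume_mL > 0) {
      expect_lte(f$water_dissolved_mg / (f$water_volume_mL / 1000),
                 2.8 + 1e-9)
    }
  }
})

test_that("residue concentration is monotone non-increasing in k, K and wash cycles", {
  res_k <- vapply(c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                  function(k) run_protocol(
                    extraction_experiment(k_per_min = k))$final$residue_concentration,
                  numeric(1))
  expect_true(all(diff(res_k) <= 1e-12))

  res_K <- vapply(10^c(-2, 0, 2, 4, 6),
                  function(K) run_protocol(extraction_experiment(),
                                           K = K)$final$residue_concentration,
                  numeric(1))
  expect_true(all(diff(res_K) <= 1e-12))

  res_w <- vapply(0:6, function(w) run_protocol(
    extraction_experiment(wash_cycles = w))$final$residue_concentration,
    numeric(1))
  expect_true(all(diff(res_w) <= 1e-12))
})

test_that("shipped defaults land the residue in the compliant range", {
  p <- run_protocol(extraction_experiment())
  expect_lte(p$final$residue_concentration, 5)
  expect_gte(p$final$residue_concentration, 1.5)
})
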