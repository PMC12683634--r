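# Reference kinetics/thermodynamics: Eyring-Polanyi conversions, the
# mole-fraction autoprotolysis equilibrium, pKa routes and the assembled
# bulk-water protolysis profile.

test_that("Eyring-Polanyi conversion reproduces the experimental anchors", {
  expect_equal(rate_to_barrier(2.56e-7, 310.15), 27.55, tolerance = 0.05 / 27.55)
  expect_equal(rate_to_barrier(1.3e11, 298.15), 2.33, tolerance = 0.05 / 2.33)
  ## prefactor identity: k = kB*T/h gives a zero barrier
  for (T in c(250, 298.15, 400))
    expect_equal(rate_to_barrier(2.083661912e10 * T, T), 0, tolerance = 1e-10)
  expect_error(rate_to_barrier(-1, 300), "positive")
  expect_error(rate_to_barrier(1, -300), "positive")
})

test_that("rate <-> barrier conversions are exact inverses over 24 decades", {
  expect_equal(barrier_to_rate(0, 300), 2.083661912e10 * 300)
  expect_equal(barrier_to_rate(27.55, 310.15), 2.6e-7, tolerance = 0.01)
  for (k in 10^seq(-10, 14, by = 2)) {
    for (T in c(280, 310.15)) {
      expect_equal(barrier_to_rate(rate_to_barrier(k, T), T), k,
                   tolerance = 1e-9)
    }
  }
})

test_that("half-life matches the printed value and scales inversely", {
  expect_equal(half_life(2.56e-7), 752, tolerance = 1 / 752)
  expect_equal(half_life(log(2)) * 3600, 1)
  expect_equal(half_life(2e-7), 2 * half_life(4e-7))
  expect_error(half_life(0), "positive")
})

test_that("mole-fraction Keq and its free energy match the pH-7 reference", {
  keq <- autoprotolysis_keq(1e-7)
  expect_equal(keq, 3.25e-18, tolerance = 0.01)
  expect_equal(free_energy_from_keq(keq, 298.15), 23.88, tolerance = 0.05 / 23.88)
  ## printed-rounding route
  expect_equal(free_energy_from_keq(3.25e-18, 298.15), 23.88,
               tolerance = 0.05 / 23.88)
  ## unit ion mole fraction
  expect_equal(autoprotolysis_keq(55.345, 55.345), 1)
  expect_equal(free_energy_from_keq(1, 321), 0)
  ## quadratic scaling in the ion concentration
  expect_equal(autoprotolysis_keq(1e-6), 100 * keq)
  expect_error(autoprotolysis_keq(0), "positive")
  expect_error(free_energy_from_keq(-1), "positive")
})

test_that("free energy from Keq is monotone decreasing in ion concentration", {
  conc <- 10^seq(-9, -3, by = 0.5)
  dg <- free_energy_from_keq(autoprotolysis_keq(conc))
  expect_true(all(diff(dg) < 0))
})

test_that("pKa route and Henderson-Hasselbalch penalties match printed values", {
  ## effective temperature at which kB*T*ln10 equals the printed 1.38 prefactor
  t_eff <- 1.38 / (0.0019872041 * log(10))
  expect_equal(pka_reaction_free_energy(15.7 + 1.7, t_eff), 24.0,
               tolerance = 0.05 / 24)
  expect_equal(pka_reaction_free_energy(14, t_eff), 19.32,
               tolerance = 0.05 / 19.32)
  expect_equal(pka_reaction_free_energy(0, 321), 0)
  ## the two routes agree within 0.2 kcal/mol at 25 C
  expect_equal(free_energy_from_keq(autoprotolysis_keq(1e-7), 298.15),
               pka_reaction_free_energy(15.7 + 1.7, 298.15),
               tolerance = 0.2 / 23.9)
  expect_equal(protonation_penalty(15.7, 7.4, 310.15), 11.79,
               tolerance = 0.02 / 11.79)
  expect_equal(protonation_penalty(8.11, 7.4, 310.15), 1.01,
               tolerance = 0.02 / 1.01)
  expect_equal(protonation_penalty(7.4, 7.4, 310.15), 0)
  ## negative when the pH exceeds the pKa
  expect_lt(protonation_penalty(6, 7.4), 0)
})

test_that("barrier composition is additive and permutation-invariant", {
  expect_equal(compose_barrier(18.13, 11.79), 29.92)
  expect_equal(compose_barrier(29.92, 1.01), 30.93)
  expect_equal(compose_barrier(5), 5)
  set.seed(4)
  for (rep in 1:20) {
    pen <- rnorm(5)
    expect_equal(compose_barrier(10, pen), compose_barrier(10, sample(pen)))
  }
  expect_error(compose_barrier(Inf, 1), "finite")
})

test_that("the assembled protolysis profile satisfies its identities", {
  p <- assemble_protolysis_profile(23.88, 2.33, 0.59)
  expect_equal(p$forward_barrier, 26.21)
  expect_equal(p$reaction_free_energy, 23.88)
  expect_equal(p$grotthuss_ts - p$reactant_level, p$forward_barrier)
  expect_equal(p$product_plateau - p$reactant_level, p$reaction_free_energy)
  expect_equal(p$first_ts - p$ion_pair_level, 0.59)
  ## flat profile degenerate case
  p0 <- assemble_protolysis_profile(0, 0, 0)
  expect_true(all(unlist(p0[c("reactant_level", "first_ts", "ion_pair_level",
                              "grotthuss_ts", "product_plateau")]) == 0))
  ## identity over random inputs
  set.seed(11)
  for (rep in 1:25) {
    dg0 <- rnorm(1, 10, 8); rev <- abs(rnorm(1, 3, 2)); fs <- abs(rnorm(1))
    pp <- assemble_protolysis_profile(dg0, rev, fs)
    expect_equal(pp$forward_barrier - pp$reaction_free_energy, rev)
  }
  expect_error(assemble_protolysis_profile(1, -0.1, 0), "reverse_barrier")
})

test_that("profile TSV serialization round-trips", {
  p <- assemble_protolysis_profile(23.88, 2.33, 0.59)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(df$state_label,
               c("reactant", "first_ts", "ion_pair", "grotthuss_ts",
                 "product_plateau"))
  expect_equal(df$free_energy_kcal_mol,
               as.data.frame(p)$free_energy_kcal_mol, tolerance = 1e-6)
})
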