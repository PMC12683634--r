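# Charged-solvation corrections and the counterion thermodynamic cycles.

test_that("Born correction follows the closed form and its symmetries", {
  expect_equal(born_correction(30, 80, 0, -1), -(166 / 30) * (79 / 80),
               tolerance = 1e-12)
  expect_equal(born_correction(25, 80, 0.3, 0.3), 0)
  expect_equal(born_correction(25, 1, 0, -1), 0)
  ## odd under exchange of the end-state charges
  set.seed(2)
  for (rep in 1:10) {
    qa <- rnorm(1); qb <- rnorm(1); R <- runif(1, 10, 50)
    expect_equal(born_correction(R, 80, qa, qb),
                 -born_correction(R, 80, qb, qa))
  }
  expect_error(born_correction(-5, 80, 0, 1), "radius")
})

test_that("Ewald self-energy correction follows Eq-form and limits", {
  xi <- -2.8374
  expect_equal(ewald_charge_correction(40, 80, 0, -1),
               332.0636 * xi / (2 * 40 * 80), tolerance = 1e-12)
  expect_equal(ewald_charge_correction(40, 80, 1, -1), 0)
  expect_equal(ewald_charge_correction(1e9, 80, 0, -1), 0, tolerance = 1e-8)
  expect_equal(ewald_charge_correction(40, 80, 0, -1),
               -ewald_charge_correction(40, 80, -1, 0))
  expect_error(ewald_charge_correction(0, 80, 0, 1), "box_length")
})

test_that("counterion cycle algebra isolates the single-ion free energies", {
  s <- solve_ion_cycle(-205.93, -34.51, 0.05, 0.08)
  expect_equal(s$dg_hydroxide, -120.22)
  expect_equal(s$dg_sodium, -85.71)
  expect_equal(s$u_hydroxide, sqrt(0.05^2 + 0.08^2) / 2)
  z <- solve_ion_cycle(0, 0)
  expect_equal(c(z$dg_hydroxide, z$dg_sodium), c(0, 0))
  ## recombination returns the original legs exactly
  set.seed(8)
  for (rep in 1:20) {
    g9 <- rnorm(1, -200, 30); g10 <- rnorm(1, -30, 10)
    s <- solve_ion_cycle(g9, g10)
    expect_equal(s$dg_hydroxide + s$dg_sodium, g9, tolerance = 1e-12)
    expect_equal(s$dg_hydroxide - s$dg_sodium, g10, tolerance = 1e-12)
  }
})

test_that("interface correction reproduces the experiment-comparable values", {
  expect_equal(apply_interface_correction(-120.22, -1), -101.22)
  expect_equal(apply_interface_correction(-85.68, +1), -104.68)
  expect_equal(apply_interface_correction(3.7, 0), 3.7)
  ## the constant cancels over an anion/cation pair
  set.seed(3)
  for (rep in 1:10) {
    a <- rnorm(1, -120, 10); c <- rnorm(1, -90, 10)
    expect_equal(apply_interface_correction(a, -1) +
                   apply_interface_correction(c, +1), a + c)
  }
  expect_error(apply_interface_correction(0, 2), "charge")
})

test_that("the packaged hydration table yields the published transfer ledger", {
  tab <- hydration_cycles()
  expect_s3_class(tab, "cycle_table")
  rep <- transfer_gap(tab)
  expect_equal(rep$dg_hydroxide_water, -120.22)
  expect_equal(rep$water_transfer, -2.9, tolerance = 0.05 / 2.9)
  ## the two route estimates (route-labeled; 7.7 from the counterion
  ## cycles, 6.3 from the direct charging leg)
  expect_equal(rep$hydroxide_transfer_counterion_cycles, 7.7, tolerance = 0.05 / 7.7)
  expect_equal(rep$hydroxide_transfer_direct_leg, 6.3, tolerance = 0.05 / 6.3)
  expect_equal(rep$total_gap, 9.9, tolerance = 0.05 / 9.9)
  ## direct vs cycle-derived sodium leg both surfaced
  expect_equal(rep$dg_sodium_direct_water, -85.68)
  expect_equal(rep$dg_sodium_cycle_water, -85.71)
  expect_equal(rep$dg_hydroxide_water_interface_corrected, -101.22)
  expect_equal(rep$dg_sodium_water_interface_corrected, -104.68)
})

test_that("cycle tables are validated on read and errors name missing legs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("environment\tleg\tvalue\tuncertainty",
               "water\tdG9\t-205.93\t0.05"), path)
  tab <- read_cycle_table(path)
  expect_error(transfer_gap(tab), "dG10")
  writeLines(c("environment\tleg\tvalue", "water\tdG9\t-205.93"), path)
  expect_error(read_cycle_table(path), "uncertainty")
})

test_that("pathway budget adds the formation and transfer costs", {
  expect_equal(pathway_budget(9.9, 23.88), 33.78)
  expect_equal(pathway_budget(0, 23.88), 23.88)
  for (gap in c(0, 2, 9.9))
    expect_gte(pathway_budget(gap, 23.88), 23.88)
})
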