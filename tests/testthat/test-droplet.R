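# Droplet construction and the Langevin sampler: geometry audits,
# determinism, integrator quality, temperature control, confinement.

test_that("a two-water droplet is just the reactive dimer", {
  d <- build_droplet(2, 6, seed = 1)
  expect_equal(nrow(d$frame$coords), 6)
  doo <- sqrt(sum((d$frame$coords[1, ] - d$frame$coords[4, ])^2))
  expect_gte(doo, 2.5); expect_lte(doo, 3.5)
})

test_that("packed droplets pass the post-hoc geometric audit", {
  d <- build_droplet(50, 10, seed = 21)
  o <- d$frame$coords[seq(1, 150, by = 3), ]
  expect_true(all(sqrt(rowSums(o^2)) <= 10))
  dm <- as.matrix(dist(o)); diag(dm) <- Inf
  expect_gt(min(dm), 2.4)
})

test_that("droplet construction is deterministic and leaves the RNG alone", {
  d1 <- build_droplet(12, 7, seed = 33)
  d2 <- build_droplet(12, 7, seed = 33)
  expect_identical(d1$frame$coords, d2$frame$coords)
  d3 <- build_droplet(12, 7, seed = 34)
  expect_false(identical(d1$frame$coords, d3$frame$coords))
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(build_droplet(5, 6, seed = 1))
  expect_identical(runif(1), before)
})

test_that("impossible packings fail with a clear error", {
  expect_error(build_droplet(60, 4, seed = 1), "packing failed")
})

test_that("windows are bit-reproducible for a fixed seed", {
  d <- build_droplet(6, 6, seed = 2)
  cfg <- sampler_config(n_steps = 300, equil_steps = 100, seed = 9)
  w1 <- run_window(d$topology, d$frame, 0.8, cfg)
  w2 <- run_window(d$topology, d$frame, 0.8, cfg)
  expect_identical(w1$eps1, w2$eps1)
  expect_identical(w1$final_frame$coords, w2$final_frame$coords)
  cfg$seed <- 10L
  w3 <- run_window(d$topology, d$frame, 0.8, cfg)
  expect_false(identical(w1$eps1, w3$eps1))
})

test_that("without friction the integrator conserves energy on the dimer", {
  d <- build_droplet(2, 6, seed = 4)
  ## relax first, then measure drift of V(lambda=1) + kinetic energy
  cfg <- sampler_config(n_steps = 2000, equil_steps = 0, stride = 1,
                        friction = 1, timestep = 0.5, seed = 3)
  relaxed <- equilibrate_frame(d$topology, d$frame, 1, cfg, steps = 2000)
  cfg0 <- sampler_config(n_steps = 4000, equil_steps = 0, stride = 20,
                         friction = 0, timestep = 0.5, seed = 3,
                         frame_stride = 0)
  w <- run_window(d$topology, relaxed, 1, cfg0)
  total_energy <- function(frame) {
    ke <- sum(0.5 * d$topology$atoms$mass * rowSums(frame$velocities^2)) /
      4.184e-4
    diabatic_energy(d$topology, frame, "reactant") + ke
  }
  drift <- abs(total_energy(w$final_frame) - total_energy(relaxed))
  expect_lt(drift / 2, 0.05)   # kcal/mol per ps over the 2 ps window
})

test_that("long-window kinetic temperature converges to the target", {
  d <- build_droplet(15, 7, seed = 6)
  cfg <- sampler_config(n_steps = 8000, equil_steps = 2000, stride = 50,
                        friction = 2, seed = 12)
  w <- run_window(d$topology, d$frame, 1, cfg)
  expect_lt(abs(w$mean_temperature - 300) / 300, 0.05)
})

test_that("confinement keeps every oxygen near the droplet", {
  d <- build_droplet(12, 6.5, seed = 8)
  cfg <- sampler_config(n_steps = 3000, equil_steps = 0, stride = 100,
                        frame_stride = 100, seed = 5)
  w <- run_window(d$topology, d$frame, 1, cfg)
  for (fr in w$frames) {
    o <- fr[seq(1, nrow(fr), by = 3), ]
    expect_lt(max(sqrt(rowSums(o^2))), 6.5 + 2)
  }
})

test_that("schedules chain frames and cover the lambda grid exactly", {
  d <- build_droplet(4, 6, seed = 10)
  cfg <- sampler_config(n_steps = 100, equil_steps = 20, stride = 10, seed = 2)
  start <- equilibrate_frame(d$topology, d$frame, 0.5, cfg, steps = 1000)
  lams <- seq(0, 1, by = 0.02)
  wins <- run_schedule(d$topology, start, lams, cfg, ts_lambda = 0.5)
  expect_length(wins, 51)
  expect_equal(sort(vapply(wins, `[[`, numeric(1), "lambda")), sort(lams))
  expect_equal(vapply(wins, `[[`, integer(1), "window_index"), 1:51)
  ## single-window schedule delegates to run_window
  one <- run_schedule(d$topology, start, 0.4, cfg)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1L
  direct <- run_window(d$topology, start, 0.4, cfg1)
  expect_identical(one[[1]]$eps1, direct$eps1)
  ## replica runs with distinct seeds differ in data, not metadata
  cfgB <- cfg; cfgB$seed <- 900L
  winsB <- run_schedule(d$topology, start, seq(0, 1, 0.25), cfg)
  winsC <- run_schedule(d$topology, start, seq(0, 1, 0.25), cfgB)
  expect_equal(vapply(winsB, `[[`, numeric(1), "lambda"),
               vapply(winsC, `[[`, numeric(1), "lambda"))
  expect_false(identical(winsB[[2]]$eps1, winsC[[2]]$eps1))
})

test_that("frozen solvent leaves non-dimer atoms exactly in place", {
  d <- build_droplet(8, 6, seed = 14)
  cfg <- sampler_config(n_steps = 200, equil_steps = 50, seed = 4,
                        frozen_solvent = TRUE)
  w <- run_window(d$topology, d$frame, 0.7, cfg)
  moved <- w$final_frame$coords - d$frame$coords
  expect_equal(max(abs(moved[-(1:6), ])), 0)
  expect_gt(max(abs(moved[1:6, ])), 0)
})

test_that("divergent dynamics raise an error naming the step", {
  d <- build_droplet(3, 6, seed = 5)
  bad <- d$frame
  cfg <- sampler_config(n_steps = 50, equil_steps = 0, seed = 1,
                        max_energy = 1e-3)
  expect_error(run_window(d$topology, bad, 1, cfg), "step")
})

test_that("mirrored windows on a symmetric synthetic topology mirror the gap", {
  ## at lambda = 1 vs lambda = 0 on the exactly symmetric Marcus model the
  ## sampled gap distributions are mirror images (construction symmetry)
  m <- marcus_model(10, 2, 0, 0, 300)
  w <- sample_marcus_records(m, c(1, 0), 5000, seed = 19)
  g1 <- w[[1]]$eps1 - w[[1]]$eps2
  g0 <- w[[2]]$eps1 - w[[2]]$eps2
  ks <- suppressWarnings(ks.test(g1, -g0))
  expect_gt(ks$p.value, 0.01)
})
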