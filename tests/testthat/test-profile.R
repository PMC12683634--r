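# FEP/US profile assembly on the gap coordinate and stationary-point logic.

marcus_windows <- function(curv, disp, dg0, n = 3000, seed = 42,
                           lams = seq(1, 0, by = -0.05)) {
  m <- marcus_model(curv, disp, dg0, 0, 300)
  sample_marcus_records(m, lams, n, seed)
}

test_that("us_profile reproduces the exact coupled-surface energetics", {
  settings <- list(c(10, 2, 0, 0), c(10, 2, 5, 0), c(10, 2, 5, 3))
  for (s in settings) {
    m <- marcus_model(s[1], s[2], s[3], 0, 300)
    ref <- marcus_reference(m, h_ij = s[4])
    w <- marcus_windows(s[1], s[2], s[3], n = 3000, seed = 42)
    p <- us_profile(w, h_ij = s[4], alpha = 0, temperature = 300,
                    bin_width = 0.5, min_count = 10)
    ps <- profile_summary(p)
    expect_equal(unname(ps["barrier"]), ref$barrier, tolerance = 0.3 / ref$barrier)
    expect_equal(unname(ps["reaction_free_energy"]), ref$reaction_free_energy,
                 tolerance = 0.1)
  }
})

test_that("profiles are anchored with the reactant minimum at exactly zero", {
  w <- marcus_windows(10, 2, 4)
  p <- us_profile(w, h_ij = 2, alpha = 0, temperature = 300, bin_width = 1)
  st <- attr(p, "stationary")
  expect_identical(st$reactant_minimum$energy, 0)
  expect_equal(min(p$free_energy[p$gap <= st$transition_state$gap]), 0)
})

test_that("symmetric uncoupled diabats give a symmetric profile", {
  w <- marcus_windows(10, 2, 0, n = 4000, seed = 17)
  p <- us_profile(w, h_ij = 0, alpha = 0, temperature = 300, bin_width = 2)
  neg <- p[p$gap < 0, ]
  mirrored <- approx(-neg$gap, neg$free_energy,
                     xout = p$gap[p$gap > 0], rule = 1)
  ok <- is.finite(mirrored$y)
  expect_lt(max(abs(mirrored$y - p$free_energy[p$gap > 0][ok])), 0.5)
})

test_that("doubling the sample size changes the profile within noise", {
  w1 <- marcus_windows(10, 2, 4, n = 2000, seed = 5)
  w2 <- marcus_windows(10, 2, 4, n = 4000, seed = 5)
  p1 <- profile_summary(us_profile(w1, 2, 0, 300, bin_width = 1))
  p2 <- profile_summary(us_profile(w2, 2, 0, 300, bin_width = 1))
  expect_lt(abs(p1["barrier"] - p2["barrier"]), 0.25)
  expect_lt(abs(p1["reaction_free_energy"] - p2["reaction_free_energy"]), 0.25)
})

test_that("zwanzig and bar increment estimators agree on well-overlapped windows", {
  w <- marcus_windows(10, 2, 4, n = 3000, seed = 9)
  pb <- profile_summary(us_profile(w, 2, 0, 300, bin_width = 1, estimator = "bar"))
  pz <- profile_summary(us_profile(w, 2, 0, 300, bin_width = 1, estimator = "zwanzig"))
  expect_equal(unname(pb["barrier"]), unname(pz["barrier"]), tolerance = 0.02)
})

test_that("a single parabola yields one minimum and no transition state", {
  g <- seq(-10, 10, by = 1)
  p <- locate_stationary_points(make_profile(g, 0.3 * g^2))
  st <- attr(p, "stationary")
  expect_false(st$has_feature)
  expect_equal(st$reactant_minimum$gap, 0)
  expect_true(is.na(st$barrier))
})

test_that("double-well extrema are recovered bin-exactly", {
  ## quartic double well with known analytic extrema at x = -2, 0, +2
  g <- seq(-4, 4, by = 0.25)
  G <- 0.5 * (g^2 - 4)^2 / 4
  p <- locate_stationary_points(make_profile(g, G))
  st <- attr(p, "stationary")
  expect_true(st$has_feature)
  expect_equal(st$transition_state$gap, 0)
  expect_equal(abs(st$reactant_minimum$gap), 2)
  expect_equal(abs(st$product_feature$gap), 2)
  expect_equal(st$barrier, G[g == 0] - G[g == 2])
})

test_that("an ascending profile with a flat shoulder is identified as the TS", {
  ## steep rise, flat shoulder around x = 5, then rise again
  g <- seq(0, 10, by = 0.5)
  G <- 2 * g - 5 * sin(pi * (g - 5) / 10)   # slope minimum at g = 5
  slope_oracle <- (G[3:length(G)] - G[1:(length(G) - 2)]) / (2 * 0.5)
  i_oracle <- which.min(slope_oracle) + 1
  p <- locate_stationary_points(make_profile(g, G))
  st <- attr(p, "stationary")
  expect_true(st$has_feature)
  expect_equal(st$transition_state$kind, "shoulder")
  expect_equal(st$transition_state$gap, g[i_oracle])
  expect_equal(st$product_feature$kind, "shoulder")
})

test_that("monotone convex profiles report no interior feature", {
  g <- seq(0, 10, by = 0.5)
  p <- locate_stationary_points(make_profile(g, 0.4 * g^2 + g))
  expect_false(attr(p, "stationary")$has_feature)
  expect_error(locate_stationary_points(make_profile(1:4, 1:4)), "5")
})

test_that("noise bumps below the prominence threshold are not barriers", {
  g <- seq(0, 20, by = 1)
  G <- g
  G[10] <- G[10] + 0.3   # sub-prominence blip on a monotone climb
  p <- locate_stationary_points(make_profile(g, G))
  st <- attr(p, "stationary")
  expect_true(is.null(st$transition_state) || st$transition_state$kind != "maximum")
})

test_that("interpolated crossing free energy matches the profile", {
  p <- make_profile(seq(-5, 5, by = 1), abs(seq(-5, 5, by = 1)) + 2)
  expect_equal(profile_at_gap(p, 0), 2)
  expect_equal(profile_at_gap(p, 0.5), 2.5)
  expect_equal(profile_at_gap(p, 100), 7)   # clamped to the range edge
})
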