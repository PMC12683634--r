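# Independent R oracles used to cross-check the compiled engine and the
# estimator stack.  These re-derive every energy term directly from the
# topology tables with plain R arithmetic (no shared code with the engine).

KB <- 0.0019872041
KE <- 332.0636

## term-by-term diabatic energy, summed by hand from the topology tables
oracle_diabatic_energy <- function(topology, coords, state) {
  a <- topology$atoms
  n <- nrow(a)
  q <- a[[paste0("q_", state)]]
  sa <- a[[paste0("sqrt_a_", state)]]
  sb <- a[[paste0("sqrt_b_", state)]]
  dist_ij <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))

  b <- topology$bonds
  b <- b[b$state %in% c("both", state), , drop = FALSE]
  e_bond <- 0
  for (r in seq_len(nrow(b))) {
    rr <- dist_ij(b$i[r], b$j[r])
    e_bond <- e_bond + b$d_e[r] * (1 - exp(-b$beta[r] * (rr - b$r0[r])))^2
  }

  g <- topology$angles
  g <- g[g$state %in% c("both", state), , drop = FALSE]
  e_ang <- 0
  for (r in seq_len(nrow(g))) {
    v1 <- coords[g$i[r], ] - coords[g$j[r], ]
    v2 <- coords[g$k[r], ] - coords[g$j[r], ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    e_ang <- e_ang + g$force_constant[r] * (th - g$theta0[r] * pi / 180)^2
  }

  ## exclusions: 1-2 and 1-3 over this state's bond graph
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  excluded <- function(i, j) {
    if (j %in% adj[[i]]) return(TRUE)
    any(vapply(adj[[i]], function(m) j %in% adj[[m]], logical(1)))
  }
  bu <- topology$buckingham
  is_reactive <- function(i, j) {
    any((bu$i == i & bu$j == j) | (bu$i == j & bu$j == i))
  }
  e_nb <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excluded(i, j)) next
    rr <- dist_ij(i, j)
    e_nb <- e_nb + KE * q[i] * q[j] / rr
    if (is_reactive(i, j)) {
      e_nb <- e_nb + 2 / rr^12           # core guard replacing the LJ term
    } else {
      e_nb <- e_nb + (sa[i] * sa[j]) / rr^12 - (sb[i] * sb[j]) / rr^6
    }
  }
  e_buck <- 0
  for (r in seq_len(nrow(bu))) {
    rr <- dist_ij(bu$i[r], bu$j[r])
    e_buck <- e_buck + bu$c[r] * exp(-bu$beta[r] * rr)
  }

  re <- topology$restraints
  e_res <- 0
  for (r in seq_len(nrow(re))) {
    rr <- dist_ij(re$i[r], re$j[r])
    ex <- if (rr < re$lower[r]) rr - re$lower[r]
          else if (rr > re$upper[r]) rr - re$upper[r] else 0
    e_res <- e_res + re$force_constant[r] * ex^2
  }
  pr <- topology$posres
  for (r in seq_len(nrow(pr))) {
    dv <- coords[pr$atom[r], ] - c(pr$x[r], pr$y[r], pr$z[r])
    e_res <- e_res + pr$force_constant[r] * sum(dv^2)
  }
  cf <- topology$confinement
  if (cf$force_constant > 0) {
    for (i in cf$atoms) {
      rr <- sqrt(sum((coords[i, ] - cf$center)^2))
      if (rr > cf$radius) e_res <- e_res + cf$force_constant * (rr - cf$radius)^2
    }
  }
  e_bond + e_ang + e_nb + e_buck + e_res
}

## lowest eigenvalue of the 2x2 EVB matrix via the generic eigensolver
oracle_ground_state <- function(e1, e2s, h) {
  min(eigen(matrix(c(e1, h, h, e2s), 2, 2), symmetric = TRUE)$values)
}

## tiny convenience: a synthetic binned profile object
make_profile <- function(gap, G, count = 1000L) {
  p <- data.frame(gap = gap, free_energy = G, count = count)
  class(p) <- c("fe_profile", "data.frame")
  attr(p, "temperature") <- 300
  p
}
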