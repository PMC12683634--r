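# EVB free-energy profiles: staged FEP along lambda combined with umbrella
# sampling (reweighting to the coupled ground-state surface, binned on the
# energy-gap coordinate), and stationary-point / shoulder identification.

#' EVB free-energy profile along the energy-gap coordinate (FEP/US)
#'
#' Combines the lambda-staged free-energy increments with an
#' umbrella-sampling reweighting of each window's samples from its mapping
#' potential to the coupled adiabatic ground state, binned on the gap
#' coordinate \eqn{\Delta\epsilon = \epsilon_1 - (\epsilon_2 + \alpha)}:
#' \deqn{\Delta G(\Delta\epsilon_b) = \Delta G_{FEP}(\lambda_w) - k_B T \ln
#'   \langle \delta_{b}\; e^{-(E_g - V_\lambda)/k_B T} \rangle_w,}
#' averaged over the windows contributing to bin b with count weights.
#' Adjacent-window increments are estimated with BAR (default) or one-sided
#' exponential averaging.  The profile is anchored so the reactant minimum
#' is exactly 0.  Because the sampling potential does not involve
#' \code{h_ij} or \code{alpha}, re-analysis of the same windows under new
#' coupling parameters is exact.
#'
#' @param windows list of \code{"traj_window"} objects (engine- or
#'   generator-produced) spanning the gap range.
#' @param h_ij off-diagonal coupling, kcal/mol.
#' @param alpha gas-phase shift added to the product diabat, kcal/mol.
#' @param temperature absolute temperature in K; default 300.
#' @param bin_width gap bin width in kcal/mol; default 5.
#' @param min_count minimum samples for a window to contribute to a bin and
#'   for a bin to be reported; default 10.
#' @param estimator adjacent-window increment estimator, "bar" or
#'   "zwanzig".
#' @return a \code{"fe_profile"} data frame (gap, free_energy, count) with
#'   the stationary-point annotation of [locate_stationary_points()]
#'   attached.
#' @export
us_profile <- function(windows, h_ij, alpha, temperature = 300,
                       bin_width = 5, min_count = 10,
                       estimator = c("bar", "zwanzig")) {
  estimator <- match.arg(estimator)
  stopifnot(length(windows) >= 1, is.finite(h_ij), is.finite(alpha),
            bin_width > 0)
  kT <- kBT(temperature)
  lam <- vapply(windows, `[[`, numeric(1), "lambda")
  windows <- windows[order(lam, decreasing = TRUE)]
  lam <- sort(lam, decreasing = TRUE)
  W <- length(windows)

  ## shifted product diabat and mapping potential per window
  e1 <- lapply(windows, `[[`, "eps1")
  e2s <- lapply(windows, function(w) w$eps2 + alpha)
  vmap <- lapply(seq_len(W), function(w)
    mapping_potential(e1[[w]], e2s[[w]], lam[w]))

  ## staged free energy along lambda (reactant window anchored at 0)
  dg_fep <- numeric(W)
  for (w in seq_len(W)[-1]) {
    v_prev_here <- mapping_potential(e1[[w - 1]], e2s[[w - 1]], lam[w])
    v_here_prev <- mapping_potential(e1[[w]], e2s[[w]], lam[w - 1])
    inc <- if (estimator == "bar") {
      bar_estimate(v_prev_here - vmap[[w - 1]],   # forward work on w-1
                   v_here_prev - vmap[[w]],       # reverse work on w
                   temperature)$dg
    } else {
      zwanzig_increment(vmap[[w - 1]], v_prev_here, temperature)$dg
    }
    dg_fep[w] <- dg_fep[w - 1] + inc
  }

  gap <- lapply(seq_len(W), function(w) energy_gap(e1[[w]], e2s[[w]]))
  eg <- lapply(seq_len(W), function(w)
    adiabatic_ground_state(e1[[w]], e2s[[w]], h_ij))

  rng <- range(unlist(gap))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width + bin_width,
               by = bin_width)
  nb <- length(edges) - 1
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  num <- rep(0, nb)   # count-weighted sum of per-window bin free energies
  cnt <- rep(0L, nb)
  for (w in seq_len(W)) {
    b <- findInterval(gap[[w]], edges, rightmost.closed = TRUE)
    x <- -(eg[[w]] - vmap[[w]]) / kT
    nw <- length(x)
    for (bb in unique(b)) {
      sel <- which(b == bb)
      if (length(sel) < min_count) next
      dgb <- dg_fep[w] - kT * (.logsumexp(x[sel]) - log(nw))
      num[bb] <- num[bb] + length(sel) * dgb
      cnt[bb] <- cnt[bb] + length(sel)
    }
  }
  fe <- ifelse(cnt >= min_count, num / pmax(cnt, 1L), NA_real_)
  keep <- !is.na(fe)
  prof <- data.frame(gap = centers[keep], free_energy = fe[keep],
                     count = cnt[keep])
  class(prof) <- c("fe_profile", "data.frame")
  attr(prof, "temperature") <- temperature
  attr(prof, "h_ij") <- h_ij
  attr(prof, "alpha") <- alpha
  attr(prof, "bin_width") <- bin_width
  prof <- locate_stationary_points(prof)
  st <- attr(prof, "stationary")
  if (!is.null(st$reactant_minimum)) {
    shift <- st$reactant_minimum$energy
    prof$free_energy <- prof$free_energy - shift
    prof <- locate_stationary_points(prof)
  }
  prof
}

#' Locate stationary points on a binned free-energy profile
#'
#' Identifies the reactant minimum, the transition state and the product
#' feature on a gap-coordinate profile.  The transition state is the
#' highest interior local maximum when one exists; otherwise, on a profile
#' that only ascends toward the products, the interior point of minimal
#' positive slope on the ascending branch (a shoulder) is identified as the
#' transition state - the treatment used when an environment shows no
#' distinct product minimum.  A profile with no interior feature yields
#' \code{has_feature = FALSE} rather than an error.
#'
#' @param profile a \code{"fe_profile"} (>= 5 populated bins).
#' @param prominence minimum height (kcal/mol) by which an interior maximum
#'   must rise above the lowest point on each side to count as a transition
#'   state; filters bin-level statistical noise.  Default 0.5.
#' @return the profile with attribute \code{stationary}: a list with
#'   \code{reactant_minimum}, \code{transition_state}, \code{product_feature}
#'   (each gap/energy/kind), \code{barrier}, \code{reaction_free_energy},
#'   \code{has_feature}.
#' @export
locate_stationary_points <- function(profile, prominence = 0.5) {
  stopifnot(inherits(profile, "fe_profile"))
  g <- profile$gap
  G <- profile$free_energy
  n <- length(G)
  if (n < 5) stop("need at least 5 populated bins")
  pt <- function(i, kind = "minimum")
    list(gap = g[i], energy = G[i], kind = kind, index = i)
  st <- list(reactant_minimum = NULL, transition_state = NULL,
             product_feature = NULL, barrier = NA_real_,
             reaction_free_energy = NA_real_, has_feature = FALSE)

  interior <- 2:(n - 1)
  imax <- interior[G[interior] > G[interior - 1] & G[interior] > G[interior + 1]]
  if (length(imax)) {
    ## discard maxima that do not rise by >= prominence above both sides
    keep <- vapply(imax, function(i) {
      G[i] >= min(G[1:(i - 1)]) + prominence &&
        G[i] >= min(G[(i + 1):n]) + prominence
    }, logical(1))
    imax <- imax[keep]
  }
  if (length(imax)) {
    its <- imax[which.max(G[imax])]
    ir <- which.min(G[1:(its - 1)])
    right <- (its + 1):n
    rmin <- interior[G[interior] < G[interior - 1] & G[interior] < G[interior + 1]]
    rmin <- rmin[rmin > its]
    if (length(rmin)) {
      ip <- rmin[which.min(G[rmin])]
      st$product_feature <- pt(ip, "minimum")
    } else {
      ip <- right[which.min(G[right])]
      st$product_feature <- pt(ip, if (ip == n) "minimum" else "shoulder")
    }
    st$reactant_minimum <- pt(ir)
    st$transition_state <- pt(its, "maximum")
    st$has_feature <- TRUE
  } else {
    ir <- which.min(G)
    st$reactant_minimum <- pt(ir)
    ## ascending product branch: look for a slope local minimum (shoulder)
    if (ir <= n - 3) {
      idx <- (ir + 1):(n - 1)
      slope <- (G[idx + 1] - G[idx - 1]) / (g[idx + 1] - g[idx - 1])
      k <- seq_along(idx)
      kin <- k[k > 1 & k < length(k)]
      is_smin <- kin[slope[kin] < slope[kin - 1] & slope[kin] < slope[kin + 1] &
                       slope[kin] > 0]
      if (length(is_smin)) {
        ish <- idx[is_smin[which.min(slope[is_smin])]]
        st$transition_state <- pt(ish, "shoulder")
        st$product_feature <- pt(ish, "shoulder")
        st$has_feature <- TRUE
      }
    }
  }
  if (st$has_feature) {
    st$barrier <- st$transition_state$energy - st$reactant_minimum$energy
    st$reaction_free_energy <-
      st$product_feature$energy - st$reactant_minimum$energy
  }
  attr(profile, "stationary") <- st
  profile
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf("EVB free-energy profile: %d bins over gap [%.1f, %.1f] kcal/mol\n",
              nrow(x), min(x$gap), max(x$gap)))
  st <- attr(x, "stationary")
  if (!is.null(st) && isTRUE(st$has_feature)) {
    cat(sprintf("  barrier      %.2f kcal/mol (TS at gap %.1f, %s)\n",
                st$barrier, st$transition_state$gap, st$transition_state$kind))
    cat(sprintf("  reaction dG0 %.2f kcal/mol (product %s)\n",
                st$reaction_free_energy, st$product_feature$kind))
  } else {
    cat("  no interior stationary feature\n")
  }
  invisible(x)
}

#' Interpolated profile free energy at a given gap value
#'
#' Linear interpolation of the binned profile; the free energy at the
#' diabatic crossing (gap = 0) is a robust transition-state proxy when an
#' environment yields a monotone (featureless) profile.  Outside the
#' sampled range the nearest bin value is returned.
#'
#' @param profile a \code{"fe_profile"}.
#' @param gap gap-coordinate value(s), kcal/mol; default 0.
#' @return interpolated free energy in kcal/mol.
#' @export
profile_at_gap <- function(profile, gap = 0) {
  stopifnot(inherits(profile, "fe_profile"))
  stats::approx(profile$gap, profile$free_energy, xout = gap, rule = 2)$y
}

#' Barrier and reaction free energy of an annotated profile
#'
#' @param profile a \code{"fe_profile"} processed by
#'   [locate_stationary_points()].
#' @return named numeric: barrier, reaction_free_energy (kcal/mol).
#' @export
profile_summary <- function(profile) {
  st <- attr(profile, "stationary")
  if (is.null(st)) {
    profile <- locate_stationary_points(profile)
    st <- attr(profile, "stationary")
  }
  c(barrier = st$barrier, reaction_free_energy = st$reaction_free_energy)
}
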