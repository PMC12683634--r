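# Calibration of the two EVB coupling parameters (H_ij, alpha) against
# reference barrier / reaction free-energy targets.

#' Calibrate EVB coupling and gas-phase shift against reference energetics
#'
#' Adjusts the off-diagonal coupling \code{h_ij} (which chiefly lowers the
#' barrier at the diabatic crossing) and the gas-phase shift \code{alpha}
#' (which chiefly moves the reaction free energy) so that the FEP/US
#' profile computed from the sampled windows reproduces the target
#' \eqn{(\Delta G^\ddagger, \Delta G_0)}.  Because the sampling (mapping)
#' potential is independent of both parameters, re-analysis of the stored
#' energy records under trial parameters is exact reweighting; the search
#' is a damped Newton iteration with a finite-difference Jacobian on that
#' deterministic objective.  If a \code{resample} function is supplied,
#' fresh sampling rounds (up to \code{max_rounds}) re-check convergence on
#' independent trajectories.
#'
#' @param windows list of \code{"traj_window"} objects, or a function
#'   \code{function(round)} returning such a list (round 1 supplies the
#'   initial windows).
#' @param targets numeric: target \code{c(barrier, reaction_free_energy)}
#'   in kcal/mol.
#' @param init numeric: initial \code{c(h_ij, alpha)}; or \code{"auto"} to
#'   place the diabatic crossing at the window nearest lambda = 0.5 and
#'   start the coupling at one tenth of the target barrier (at least 5).
#' @param temperature absolute temperature in K; default 300.
#' @param tolerance convergence tolerance on both achieved values,
#'   kcal/mol; default 0.1.
#' @param max_iter Newton iterations per sampling round; default 40.
#' @param max_rounds sampling rounds when \code{windows} is a function;
#'   default 10.
#' @param bin_width,min_count,estimator passed to [us_profile()].
#' @return a \code{"calibration_result"} list: h_ij, alpha,
#'   achieved_barrier, achieved_reaction_free_energy, iterations, rounds,
#'   converged, profile.
#' @export
calibrate_evb <- function(windows, targets, init = "auto", temperature = 300,
                          tolerance = 0.1, max_iter = 40, max_rounds = 10,
                          bin_width = 2, min_count = 5, estimator = "bar") {
  stopifnot(length(targets) == 2, all(is.finite(targets)))
  provider <- NULL
  if (is.function(windows)) {
    provider <- windows
    windows <- provider(1)
  }
  stopifnot(length(windows) >= 2)

  measure <- function(w, h, a) {
    p <- us_profile(w, h_ij = h, alpha = a, temperature = temperature,
                    bin_width = bin_width, min_count = min_count,
                    estimator = estimator)
    s <- profile_summary(p)
    list(f = unname(s - targets), summary = s, profile = p,
         ok = all(is.finite(s)))
  }

  if (identical(init, "auto")) {
    lam <- vapply(windows, `[[`, numeric(1), "lambda")
    wts <- windows[[which.min(abs(lam - 0.5))]]
    a0 <- mean(wts$eps1 - wts$eps2)
    h0 <- max(5, 0.1 * abs(targets[1]))
    init <- c(h0, a0)
  }
  h <- init[1]; a <- init[2]

  total_iter <- 0L
  rounds <- 1L
  converged <- FALSE
  m <- measure(windows, h, a)

  repeat {
    iter <- 0L
    while (iter < max_iter) {
      if (m$ok && max(abs(m$f)) < tolerance) { converged <- TRUE; break }
      iter <- iter + 1L; total_iter <- total_iter + 1L
      if (!m$ok) {
        ## no identifiable feature: strengthen the coupling mildly and retry
        h <- max(h * 0.8, 1)
        m <- measure(windows, h, a)
        next
      }
      dh <- max(0.5, 0.02 * abs(h))
      da <- max(0.5, 0.02 * abs(a))
      mh <- measure(windows, h + dh, a)
      ma <- measure(windows, h, a + da)
      if (!mh$ok || !ma$ok) { h <- max(h * 0.9, 1); m <- measure(windows, h, a); next }
      J <- cbind((mh$f - m$f) / dh, (ma$f - m$f) / da)
      step <- tryCatch(-solve(J, m$f), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step)))
        step <- -c(m$f[1] / -1, m$f[2] / 1)   # fallback: unit sensitivities
      ## damping: clamp the step sizes
      step[1] <- max(min(step[1], 0.5 * abs(h) + 5), -(0.5 * abs(h) + 5))
      step[2] <- max(min(step[2], 25), -25)
      h_new <- max(h + step[1], 0)
      a_new <- a + step[2]
      m_new <- measure(windows, h_new, a_new)
      ## backtrack if the residual grew badly
      tries <- 0L
      while ((!m_new$ok ||
              (m$ok && sum(m_new$f^2) > 4 * sum(m$f^2))) && tries < 4) {
        step <- step / 2
        h_new <- max(h + step[1], 0)
        a_new <- a + step[2]
        m_new <- measure(windows, h_new, a_new)
        tries <- tries + 1L
      }
      h <- h_new; a <- a_new; m <- m_new
    }
    if (!converged || is.null(provider) || rounds >= max_rounds) break
    ## fresh sampling round: verify on independent windows
    rounds <- rounds + 1L
    windows <- provider(rounds)
    m <- measure(windows, h, a)
    if (m$ok && max(abs(m$f)) < tolerance) break
    converged <- FALSE
  }

  out <- list(h_ij = h, alpha = a,
              achieved_barrier = unname(m$summary["barrier"]),
              achieved_reaction_free_energy =
                unname(m$summary["reaction_free_energy"]),
              iterations = total_iter, rounds = rounds,
              converged = converged, profile = m$profile,
              targets = c(barrier = targets[1],
                          reaction_free_energy = targets[2]))
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("EVB calibration result\n")
  cat(sprintf("  H_ij  = %.3f kcal/mol\n  alpha = %.3f kcal/mol\n",
              x$h_ij, x$alpha))
  cat(sprintf("  achieved barrier %.3f (target %.3f)\n",
              x$achieved_barrier, x$targets["barrier"]))
  cat(sprintf("  achieved dG0     %.3f (target %.3f)\n",
              x$achieved_reaction_free_energy,
              x$targets["reaction_free_energy"]))
  cat(sprintf("  converged: %s after %d iterations, %d sampling round(s)\n",
              x$converged, x$iterations, x$rounds))
  invisible(x)
}
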