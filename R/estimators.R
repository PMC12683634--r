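# Two-state free-energy estimators: exponential averaging (Zwanzig) and the
# Bennett acceptance ratio (BAR), with asymptotic standard errors.

#' Free-energy increment by exponential averaging (Zwanzig)
#'
#' One-sided free-energy perturbation between potentials i and j from
#' samples of state i:
#' \deqn{\Delta G_{i\to j} = -k_B T \ln \langle e^{-(V_j - V_i)/k_B T}\rangle_i.}
#' The exponential average is evaluated with a max-shift (log-sum-exp), and
#' the standard error comes from the delta method on the sample variance of
#' the exponentiated work.
#'
#' @param u_i potential energies of the sampled state evaluated on its own
#'   samples (kcal/mol).
#' @param u_j potential energies of the target state evaluated on the same
#'   samples (kcal/mol); same length as \code{u_i}.
#' @param temperature absolute temperature in K.
#' @return a \code{"fe_estimate"} list: \code{dg} (kcal/mol), \code{se},
#'   \code{n}.
#' @examples
#' x <- rnorm(1000)
#' zwanzig_increment(x^2, x^2 + 1.5, 300)$dg   # constant shift -> exactly 1.5
#' @export
zwanzig_increment <- function(u_i, u_j, temperature) {
  if (length(u_i) == 0) stop("empty sample")
  if (length(u_i) != length(u_j)) stop("'u_i' and 'u_j' must have equal length")
  kT <- kBT(temperature)
  w <- (u_j - u_i) / kT
  n <- length(w)
  dg <- -kT * .logmeanexp(-w)
  ## delta method on y = exp(-w - shift)
  y <- exp(-(w - min(w)))
  se <- kT * stats::sd(y) / (mean(y) * sqrt(n))
  structure(list(dg = dg, se = se, n = n), class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("free-energy estimate: %.4f +- %.4f kcal/mol (n = %s)\n",
              x$dg, x$se, paste(x$n, collapse = "/")))
  if (!is.null(x$overlap) && !x$overlap)
    cat("  warning: forward and reverse work distributions do not overlap\n")
  invisible(x)
}

#' Bennett acceptance ratio (BAR) free-energy estimate
#'
#' Minimum-variance two-state estimator from forward work samples
#' (\eqn{W_F = V_1 - V_0} on samples of state 0) and reverse work samples
#' (\eqn{W_R = V_0 - V_1} on samples of state 1).  Solves the
#' self-consistent Bennett equation
#' \deqn{\sum_F f(\beta(M + W_F - \Delta G)) =
#'       \sum_R f(\beta(-M + W_R + \Delta G))}
#' with \eqn{f} the Fermi function and \eqn{M = k_B T \ln(n_F/n_R)}, and
#' reports the standard asymptotic variance.  If the forward and negated
#' reverse work distributions do not overlap, the estimate is still
#' returned with \code{overlap = FALSE}.
#'
#' @param work_forward forward work samples, kcal/mol.
#' @param work_reverse reverse work samples, kcal/mol.
#' @param temperature absolute temperature in K.
#' @return a \code{"fe_estimate"} list: \code{dg}, \code{se}, \code{n}
#'   (c(forward, reverse)), \code{overlap} flag.
#' @examples
#' ha <- sample_harmonic_alchemy(100, 400, 300, 2000, seed = 1)
#' bar_estimate(ha$work_forward, ha$work_reverse, 300)
#' @export
bar_estimate <- function(work_forward, work_reverse, temperature) {
  nf <- length(work_forward); nr <- length(work_reverse)
  if (nf == 0 || nr == 0) stop("both work directions must be non-empty")
  kT <- kBT(temperature)
  beta <- 1 / kT
  M <- kT * log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(pmin(x, 700)))
  g <- function(dg) {
    sum(fermi(beta * (M + work_forward - dg))) -
      sum(fermi(beta * (-M + work_reverse + dg)))
  }
  ## g is monotone increasing in dg; bracket and expand as needed
  lo <- min(c(work_forward, -work_reverse)) - 1
  hi <- max(c(work_forward, -work_reverse)) + 1
  for (k in 1:60) {
    if (g(lo) <= 0) break
    lo <- lo - 2^k
  }
  for (k in 1:60) {
    if (g(hi) >= 0) break
    hi <- hi + 2^k
  }
  dg <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  ## asymptotic variance from the Fermi weights at the solution
  fF <- fermi(beta * (M + work_forward - dg))
  fR <- fermi(beta * (-M + work_reverse + dg))
  vf <- (mean(fF^2) / mean(fF)^2 - 1) / nf
  vr <- (mean(fR^2) / mean(fR)^2 - 1) / nr
  se <- kT * sqrt(max(vf + vr, 0))
  overlap <- min(work_forward) <= max(-work_reverse) + 1e-12 &&
    min(-work_reverse) <= max(work_forward) + 1e-12
  if (!overlap)
    warning("forward and reverse work distributions do not overlap; ",
            "BAR estimate is unreliable")
  structure(list(dg = dg, se = se, n = c(forward = nf, reverse = nr),
                 overlap = overlap),
            class = "fe_estimate")
}
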