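# Two-parabola (Marcus-type) diabatic model with exact Boltzmann sampling:
# the closed-form oracle used to validate the EVB free-energy machinery
# independently of the dynamics engine.

#' Construct a Marcus-type two-parabola diabatic model
#'
#' Two equal-curvature diabats on an abstract 1-D coordinate x:
#' \deqn{\epsilon_1(x) = c\,x^2, \qquad
#'       \epsilon_2(x) = c\,(x - d)^2 + \Delta G_0,}
#' with reorganization energy \eqn{\lambda_M = c\,d^2} and electronic
#' coupling H mixing the states.  Because the curvatures are equal, the
#' energy gap \eqn{\epsilon_1 - \epsilon_2} is linear in x, so the free
#' energy along the gap coordinate equals the adiabatic potential up to an
#' additive constant - which makes every downstream estimator checkable
#' against a grid search on the exact surface.
#'
#' @param curvature parabola curvature c in kcal/mol per coordinate-unit^2
#'   (> 0).
#' @param displacement separation d of the two minima (coordinate units).
#' @param reaction_free_energy diabatic offset \eqn{\Delta G_0} in kcal/mol.
#' @param coupling electronic coupling H in kcal/mol (>= 0).
#' @param temperature absolute temperature in K.
#' @return a \code{"marcus_model"} list, with \code{reorganization} added.
#' @examples
#' m <- marcus_model(10, 2, 5, 3, 300)
#' m$reorganization   # c d^2 = 40
#' @export
marcus_model <- function(curvature, displacement, reaction_free_energy = 0,
                         coupling = 0, temperature = 300) {
  stopifnot(curvature > 0, displacement != 0, coupling >= 0, temperature > 0)
  m <- list(curvature = curvature, displacement = displacement,
            reaction_free_energy = reaction_free_energy, coupling = coupling,
            temperature = temperature,
            reorganization = curvature * displacement^2)
  class(m) <- "marcus_model"
  m
}

.marcus_diabats <- function(model, x, alpha = 0) {
  e1 <- model$curvature * x^2
  e2 <- model$curvature * (x - model$displacement)^2 +
    model$reaction_free_energy + alpha
  list(e1 = e1, e2 = e2)
}

#' Exact barrier and reaction free energy of the coupled Marcus surface
#'
#' Grid search on the adiabatic ground state of the two-parabola model,
#' \eqn{E_g = (\epsilon_1+\epsilon_2)/2 -
#' \sqrt{((\epsilon_1-\epsilon_2)/2)^2 + H^2}}: locates the reactant
#' minimum, the interior maximum between the wells, and the product
#' minimum.  For H = 0 this reduces to the Marcus closed form
#' \eqn{\Delta G^\ddagger = (\lambda_M + \Delta G_0)^2 / 4\lambda_M}.
#'
#' @param model a \code{"marcus_model"}.
#' @param h_ij coupling used on the surface; defaults to the model's.
#' @param alpha extra constant shift added to the product diabat (kcal/mol);
#'   default 0.
#' @param n_grid number of grid points; default 20001.
#' @return list with \code{barrier}, \code{reaction_free_energy} (both
#'   kcal/mol, relative to the reactant minimum), \code{has_barrier}, and
#'   the stationary-point coordinates \code{x_reactant}, \code{x_ts},
#'   \code{x_product}.
#' @examples
#' marcus_reference(marcus_model(10, 2, 0, 0))$barrier   # lambda/4 = 10
#' @export
marcus_reference <- function(model, h_ij = model$coupling, alpha = 0,
                             n_grid = 20001) {
  stopifnot(inherits(model, "marcus_model"))
  d <- model$displacement
  x <- seq(min(0, d) - abs(d), max(0, d) + abs(d), length.out = n_grid)
  eps <- .marcus_diabats(model, x, alpha)
  eg <- adiabatic_ground_state(eps$e1, eps$e2, h_ij)
  ## interior local minima/maxima
  n <- length(eg)
  interior <- 2:(n - 1)
  is_min <- eg[interior] < eg[interior - 1] & eg[interior] < eg[interior + 1]
  mins <- interior[is_min]
  if (length(mins) < 2) {
    i0 <- if (length(mins)) mins[1] else which.min(eg)
    return(list(barrier = NA_real_, reaction_free_energy = NA_real_,
                has_barrier = FALSE, x_reactant = x[i0], x_ts = NA_real_,
                x_product = NA_real_))
  }
  ## reactant = minimum closer to x = 0; product = minimum closer to x = d
  i_r <- mins[which.min(abs(x[mins] - 0))]
  i_p <- mins[which.min(abs(x[mins] - d))]
  lo <- min(i_r, i_p); hi <- max(i_r, i_p)
  i_ts <- lo + which.max(eg[lo:hi]) - 1
  list(barrier = eg[i_ts] - eg[i_r],
       reaction_free_energy = eg[i_p] - eg[i_r],
       has_barrier = TRUE,
       x_reactant = x[i_r], x_ts = x[i_ts], x_product = x[i_p])
}

#' Exact Boltzmann sampling of Marcus-model energy records per lambda window
#'
#' The mapping potential \eqn{V_\lambda = \lambda\epsilon_1 +
#' (1-\lambda)\epsilon_2} of the two-parabola model is itself a parabola, so
#' each window's Boltzmann distribution is an exact Gaussian with mean
#' \eqn{(1-\lambda) d} and variance \eqn{k_B T / 2c}.  Samples are drawn
#' directly (no dynamics) and emitted as per-frame diabatic energy records,
#' interchangeable with engine-produced windows downstream.
#'
#' @param model a \code{"marcus_model"}.
#' @param lambda_schedule vector of lambda values in [0, 1].
#' @param n_per_window samples per window.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (parameters, seed).
#' @return list of \code{"traj_window"} objects with fields \code{lambda},
#'   \code{eps1}, \code{eps2}, \code{vmap}, \code{window_index}.
#' @examples
#' w <- sample_marcus_records(marcus_model(10, 2), seq(1, 0, -0.1), 100, 1)
#' length(w)
#' @export
sample_marcus_records <- function(model, lambda_schedule, n_per_window, seed) {
  stopifnot(inherits(model, "marcus_model"),
            all(lambda_schedule >= 0 & lambda_schedule <= 1),
            n_per_window >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sigma <- sqrt(kBT(model$temperature) / (2 * model$curvature))
  out <- vector("list", length(lambda_schedule))
  for (i in seq_along(lambda_schedule)) {
    lam <- lambda_schedule[i]
    mu <- (1 - lam) * model$displacement
    x <- stats::rnorm(n_per_window, mu, sigma)
    eps <- .marcus_diabats(model, x)
    out[[i]] <- structure(
      list(lambda = lam, eps1 = eps$e1, eps2 = eps$e2,
           vmap = lam * eps$e1 + (1 - lam) * eps$e2,
           step = seq_len(n_per_window), window_index = i),
      class = "traj_window")
  }
  out
}

## save/restore the caller's RNG state so generators are side-effect free
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic harmonic-alchemy work samples with an analytic reference
#'
#' Changing the stiffness of a 1-D harmonic oscillator
#' \eqn{U_k(x) = k x^2 / 2} from \eqn{k_1} to \eqn{k_2} has the closed-form
#' free-energy difference \eqn{\Delta G = (k_B T / 2)\ln(k_2/k_1)}.  Exact
#' Boltzmann samples of each end state give forward work
#' \eqn{(k_2-k_1)x^2/2} and reverse work \eqn{(k_1-k_2)x^2/2} - a
#' controlled benchmark for [zwanzig_increment()] and [bar_estimate()].
#'
#' @param stiffness_initial,stiffness_final force constants
#'   (kcal/mol/Angstrom^2, > 0).
#' @param temperature absolute temperature in K.
#' @param n_samples samples per direction.
#' @param seed integer RNG seed.
#' @return list with \code{work_forward}, \code{work_reverse} (kcal/mol),
#'   \code{dg_ref} (analytic), \code{temperature}.
#' @examples
#' ha <- sample_harmonic_alchemy(100, 400, 300, 1000, seed = 7)
#' ha$dg_ref   # kT * ln 2
#' @export
sample_harmonic_alchemy <- function(stiffness_initial, stiffness_final,
                                    temperature, n_samples, seed) {
  stopifnot(stiffness_initial > 0, stiffness_final > 0, n_samples >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  kT <- kBT(temperature)
  x1 <- stats::rnorm(n_samples, 0, sqrt(kT / stiffness_initial))
  x2 <- stats::rnorm(n_samples, 0, sqrt(kT / stiffness_final))
  list(work_forward = (stiffness_final - stiffness_initial) / 2 * x1^2,
       work_reverse = (stiffness_initial - stiffness_final) / 2 * x2^2,
       dg_ref = kT / 2 * log(stiffness_final / stiffness_initial),
       temperature = temperature)
}
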