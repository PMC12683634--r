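# Two-state EVB surface algebra: mapping potential, adiabatic ground state,
# energy-gap coordinate, restraints, and diabatic force-field energies.

#' Lambda mapping potential
#'
#' The driving potential that carries sampling from the reactant force field
#' to the product force field: \eqn{V(\lambda) = \lambda\,\epsilon_1 +
#' (1-\lambda)\,\epsilon_2}; \eqn{\lambda = 1} is the pure reactant-state
#' potential.
#'
#' @param eps1 reactant-state diabatic energy (kcal/mol).
#' @param eps2 product-state diabatic energy (kcal/mol).
#' @param lam coupling parameter in [0, 1].
#' @return mapped potential energy (kcal/mol); vectorized.
#' @examples
#' mapping_potential(2, 10, 0.5)
#' @export
mapping_potential <- function(eps1, eps2, lam) {
  if (any(lam < 0 | lam > 1)) stop("'lam' must lie in [0, 1]")
  lam * eps1 + (1 - lam) * eps2
}

#' Adiabatic ground state of the two-state EVB Hamiltonian
#'
#' Lowest eigenvalue of \eqn{\begin{pmatrix}\epsilon_1 & H_{ij}\\ H_{ij} &
#' \epsilon_2'\end{pmatrix}}:
#' \deqn{E_g = \tfrac{1}{2}(\epsilon_1+\epsilon_2') -
#'  \sqrt{\tfrac{1}{4}(\epsilon_1-\epsilon_2')^2 + H_{ij}^2}.}
#' \code{eps2_shifted} is the product diabat including any gas-phase shift.
#'
#' @param eps1 reactant diabatic energy (kcal/mol); vectorized.
#' @param eps2_shifted shifted product diabatic energy (kcal/mol).
#' @param h_ij off-diagonal coupling (kcal/mol).
#' @return ground-state energy (kcal/mol).
#' @examples
#' adiabatic_ground_state(0, 0, 5)   # -5
#' @export
adiabatic_ground_state <- function(eps1, eps2_shifted, h_ij) {
  if (any(!is.finite(h_ij))) stop("'h_ij' must be finite")
  0.5 * (eps1 + eps2_shifted) -
    sqrt(0.25 * (eps1 - eps2_shifted)^2 + h_ij^2)
}

#' Energy-gap reaction coordinate
#'
#' The generalized EVB reaction coordinate \eqn{\Delta\epsilon = \epsilon_1
#' - \epsilon_2'}: large and negative near the reactant basin, large and
#' positive near the products.
#'
#' @inheritParams adiabatic_ground_state
#' @return energy gap (kcal/mol); vectorized.
#' @export
energy_gap <- function(eps1, eps2_shifted) eps1 - eps2_shifted

#' Flat-bottom restraint energy
#'
#' Zero inside \code{[lower, upper]}; outside, \eqn{k\,(d - b)^2} with b the
#' violated bound (no 1/2 factor: the stated force constant multiplies the
#' squared excursion directly).  Energy and first derivative vanish
#' continuously at the bounds.
#'
#' @param distance distance in Angstrom (>= 0); vectorized.
#' @param lower,upper flat-bottom bounds in Angstrom (lower < upper).
#' @param force_constant k in kcal/mol/Angstrom^2 (>= 0); default 10.
#' @return restraint energy in kcal/mol.
#' @examples
#' restraint_energy(4.0, 2.5, 3.5, 10)   # 10 * 0.5^2 = 2.5
#' @export
restraint_energy <- function(distance, lower, upper, force_constant = 10) {
  if (lower >= upper) stop("'lower' must be < 'upper'")
  if (force_constant < 0) stop("'force_constant' must be >= 0")
  if (any(distance < 0)) stop("'distance' must be >= 0")
  excess <- pmax(distance - upper, 0) + pmin(distance - lower, 0)
  force_constant * excess^2
}

#' Diabatic force-field energy of a configuration
#'
#' Total potential energy of one EVB valence state for a frame: Morse bonds,
#' harmonic angles, Coulomb interactions with the state's charges,
#' Lennard-Jones terms combined geometrically from square-root-stored
#' parameters, Buckingham \eqn{C e^{-\beta r}} repulsion on the declared
#' reactive pairs (replacing their LJ term), flat-bottom pair restraints,
#' positional restraints and droplet confinement.  The returned energy is
#' the raw force-field value; the gas-phase shift enters only when states
#' are coupled at analysis time.
#'
#' @param topology an \code{"evb_topology"} (see [build_droplet()]).
#' @param frame an \code{"evb_frame"} or an N x 3 coordinate matrix
#'   (Angstrom).
#' @param state \code{"reactant"} or \code{"product"}.
#' @return potential energy in kcal/mol.
#' @seealso [diabatic_forces()] for the gradient.
#' @export
diabatic_energy <- function(topology, frame, state = c("reactant", "product")) {
  state <- match.arg(state)
  prep <- .prepare_engine(topology)
  xyz <- .frame_coords(frame, prep$n)
  res <- evb_eval_cpp(prep, xyz, FALSE)
  if (state == "reactant") res$e1 else res$e2
}

#' Diabatic force-field forces of a configuration
#'
#' Analytic negative gradient of [diabatic_energy()] with respect to the
#' coordinates, in kcal/mol/Angstrom.
#'
#' @inheritParams diabatic_energy
#' @return N x 3 force matrix.
#' @export
diabatic_forces <- function(topology, frame, state = c("reactant", "product")) {
  state <- match.arg(state)
  prep <- .prepare_engine(topology)
  xyz <- .frame_coords(frame, prep$n)
  res <- evb_eval_cpp(prep, xyz, TRUE)
  if (state == "reactant") res$f1 else res$f2
}

.frame_coords <- function(frame, n = NULL) {
  xyz <- if (is.list(frame) && !is.null(frame$coords)) frame$coords else frame
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("coordinates must be an N x 3 matrix")
  if (!is.null(n) && nrow(xyz) != n)
    stop("coordinate count (", nrow(xyz), ") does not match topology (", n, ")")
  storage.mode(xyz) <- "double"
  xyz
}
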