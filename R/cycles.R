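# Charged-solvation corrections and thermodynamic-cycle algebra for single-ion
# hydration free energies (hydroxide + sodium counterion) and for the cost of
# transferring the reactive hydroxide from bulk water to a protein site.

#' Born finite-size correction for a charging transformation in a sphere
#'
#' Continuum correction recovering the solvation free energy missing beyond
#' the boundary of a finite spherical simulation system:
#' \deqn{\Delta G_{Born} = -\frac{166}{R}\,\frac{\epsilon - 1}{\epsilon}\,
#'   (q_B^2 - q_A^2)}
#' with R in Angstrom, charges in elementary units and the result in
#' kcal/mol.  The prefactor 166 is half the Coulomb constant in these units.
#'
#' @param radius_R distance (Angstrom) from the charged moiety to the
#'   liquid-vacuum interface (> 0).
#' @param dielectric relative dielectric constant beyond \code{radius_R}
#'   (>= 1); typically that of water.
#' @param q_initial,q_final net system charge (e) before / after the
#'   alchemical transformation.
#' @return correction in kcal/mol.
#' @examples
#' born_correction(30, 80, 0, -1)
#' @export
born_correction <- function(radius_R, dielectric, q_initial, q_final) {
  if (!is.numeric(radius_R) || any(radius_R <= 0)) stop("'radius_R' must be > 0")
  if (!is.numeric(dielectric) || any(dielectric < 1)) stop("'dielectric' must be >= 1")
  -(166 / radius_R) * ((dielectric - 1) / dielectric) * (q_final^2 - q_initial^2)
}

#' Ewald self-energy correction for a non-neutral charging transformation
#'
#' Under periodic (tinfoil boundary) lattice-sum electrostatics, a change of
#' net charge leaves a spurious self-interaction with the periodic images:
#' \deqn{\Delta U = \frac{k_e\,\xi}{2 L \epsilon}\,(q_B^2 - q_A^2)}
#' where \eqn{\xi = -2.8374} is the cubic-lattice self-energy constant,
#' \eqn{k_e} the Coulomb constant (332.0636 kcal/mol Angstrom e^-2) and L
#' the box edge.
#'
#' @param box_length_L periodic box edge length in Angstrom (> 0).
#' @param dielectric relative dielectric constant of the medium (>= 1).
#' @param q_initial,q_final net system charge (e) before / after.
#' @param xi lattice self-energy constant; default -2.8374.
#' @return correction in kcal/mol.
#' @examples
#' ewald_charge_correction(40, 80, 0, -1)
#' @export
ewald_charge_correction <- function(box_length_L, dielectric, q_initial,
                                    q_final, xi = -2.8374) {
  if (!is.numeric(box_length_L) || any(box_length_L <= 0))
    stop("'box_length_L' must be > 0")
  if (!is.numeric(dielectric) || any(dielectric < 1)) stop("'dielectric' must be >= 1")
  .ke * xi / (2 * box_length_L * dielectric) * (q_final^2 - q_initial^2)
}

#' Single-ion hydration free energies from a counterion cycle pair
#'
#' Two charging cycles that create the ion pair with the counterion charged
#' in the same (cycle "9": OH0 + Na0 -> OH- + Na+) or the opposite
#' (cycle "10": OH0 + Na+ -> OH- + Na0) direction let the periodic
#' self-energies cancel; half their sum and half their difference isolate the
#' single-ion values:
#' \deqn{\Delta G_{OH^-} = (\Delta G_9 + \Delta G_{10})/2, \qquad
#'       \Delta G_{Na^+} = (\Delta G_9 - \Delta G_{10})/2.}
#'
#' @param dg9,dg10 free energies of the two cycles, kcal/mol.
#' @param u9,u10 their standard uncertainties (>= 0, default 0).
#' @return list with \code{dg_hydroxide}, \code{dg_sodium} and propagated
#'   uncertainties \code{u_hydroxide}, \code{u_sodium} (quadrature / 2).
#' @examples
#' solve_ion_cycle(-205.93, -34.51)
#' @export
solve_ion_cycle <- function(dg9, dg10, u9 = 0, u10 = 0) {
  stopifnot(is.numeric(dg9), is.numeric(dg10), all(is.finite(c(dg9, dg10))))
  if (any(c(u9, u10) < 0)) stop("uncertainties must be >= 0")
  u <- sqrt(u9^2 + u10^2) / 2
  list(dg_hydroxide = (dg9 + dg10) / 2,
       dg_sodium = (dg9 - dg10) / 2,
       u_hydroxide = u, u_sodium = u)
}

#' Liquid-vacuum interface correction for a single-ion solvation free energy
#'
#' The potential drop across the liquid-vacuum interface contributes a
#' water-model-dependent constant (about -19 kcal/mol for TIP3P and SPC/E)
#' to single-ion solvation free energies.  It cancels in completed
#' thermodynamic cycles but must be applied when comparing single-ion values
#' with experiment: added for a cation, removed for an anion; neutral
#' species are unchanged.
#'
#' @param dg raw single-ion solvation free energy, kcal/mol.
#' @param charge species net charge in e; must be -1, 0 or +1.
#' @param water_model_constant interface constant, kcal/mol; default -19.
#' @return corrected free energy in kcal/mol.
#' @examples
#' apply_interface_correction(-120.22, -1)  # -> -101.22
#' apply_interface_correction(-85.68, +1)   # -> -104.68
#' @export
apply_interface_correction <- function(dg, charge, water_model_constant = -19) {
  stopifnot(is.numeric(dg), is.numeric(charge))
  if (any(abs(charge) > 1)) stop("only |charge| <= 1 species are supported")
  dg + sign(charge) * water_model_constant
}

#' Read a hydration-cycle table
#'
#' Tab-separated table with columns \code{environment} (e.g. "water",
#' "protein"), \code{leg} (one of dG_H2O, dG9, dG10, dG11, dG12),
#' \code{value} and \code{uncertainty} (kcal/mol); '#' lines are comments.
#'
#' @param path file path.
#' @return a \code{"cycle_table"} data frame.
#' @seealso [hydration_cycles()] for the packaged reference table.
#' @export
read_cycle_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("environment", "leg", "value", "uncertainty")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cycle table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$uncertainty < 0)) stop("uncertainties must be >= 0")
  class(df) <- c("cycle_table", class(df))
  df
}

#' Packaged hydration free energies for H2O and OH- (bulk water vs MAO A)
#'
#' Reference hydration free energies from alchemical charging simulations:
#' the four counterion thermodynamic-cycle legs for hydroxide (dG9..dG12)
#' and the water-molecule hydration free energy (dG_H2O), in bulk water and
#' at the reactive site of the MAO A enzyme.  Values in kcal/mol with
#' standard uncertainties.
#'
#' @return a \code{"cycle_table"} data frame (see [read_cycle_table()]).
#' @examples
#' hydration_cycles()
#' @export
hydration_cycles <- function() {
  read_cycle_table(system.file("extdata", "hydration_free_energies.tsv",
                               package = "protolysis", mustWork = TRUE))
}

.cycle_leg <- function(tab, env, leg) {
  i <- which(tab$environment == env & tab$leg == leg)
  if (length(i) != 1)
    stop("cycle table: missing leg '", leg, "' for environment '", env, "'")
  list(value = unname(tab$value[i]), u = unname(tab$uncertainty[i]))
}

#' Hydroxide and water transfer free energies between two environments
#'
#' Evaluates the cost of moving the reactive hydroxide (and a water
#' molecule) from a reference environment (bulk water) into a target
#' environment (protein site) from a hydration-cycle table.  Reports:
#' the single-ion hydroxide solvation free energy in each environment from
#' the counterion cycle pair; the hydroxide transfer penalty computed twice
#' (via the counterion cycles 9-10 and via the direct charging leg 11) and
#' their average; the water-molecule transfer term; and the total gap
#' (average hydroxide transfer minus the water transfer term).  Sodium is
#' reported both from the direct leg (dG12) and cycle-derived
#' ((dG9 - dG10)/2), which need not agree exactly.
#'
#' @param table a \code{"cycle_table"} with both environments, or the
#'   reference environment's table if \code{protein} is given separately.
#' @param water,protein environment labels; defaults "water" and "protein".
#' @param interface_constant liquid-vacuum interface constant passed to
#'   [apply_interface_correction()] for the experiment-comparable single-ion
#'   values; default -19.
#' @return a \code{"transfer_report"} list; see Details.
#' @examples
#' transfer_gap(hydration_cycles())
#' @export
transfer_gap <- function(table, water = "water", protein = "protein",
                         interface_constant = -19) {
  stopifnot(inherits(table, "cycle_table") || is.data.frame(table))
  env_oh <- function(env) {
    g9 <- .cycle_leg(table, env, "dG9"); g10 <- .cycle_leg(table, env, "dG10")
    solve_ion_cycle(g9$value, g10$value, g9$u, g10$u)
  }
  oh_w <- env_oh(water); oh_p <- env_oh(protein)
  g11_w <- .cycle_leg(table, water, "dG11"); g11_p <- .cycle_leg(table, protein, "dG11")
  g12_w <- .cycle_leg(table, water, "dG12")
  h2o_w <- .cycle_leg(table, water, "dG_H2O"); h2o_p <- .cycle_leg(table, protein, "dG_H2O")

  transfer_cycle <- oh_p$dg_hydroxide - oh_w$dg_hydroxide
  u_cycle <- sqrt(oh_p$u_hydroxide^2 + oh_w$u_hydroxide^2)
  transfer_direct <- g11_p$value - g11_w$value
  u_direct <- sqrt(g11_p$u^2 + g11_w$u^2)
  transfer_mean <- (transfer_cycle + transfer_direct) / 2
  water_transfer <- h2o_p$value - h2o_w$value
  u_water <- sqrt(h2o_p$u^2 + h2o_w$u^2)
  total_gap <- transfer_mean - water_transfer

  out <- list(
    dg_hydroxide_water = oh_w$dg_hydroxide,
    dg_hydroxide_protein = oh_p$dg_hydroxide,
    u_hydroxide_water = oh_w$u_hydroxide,
    u_hydroxide_protein = oh_p$u_hydroxide,
    dg_sodium_cycle_water = oh_w$dg_sodium,
    dg_sodium_direct_water = g12_w$value,
    hydroxide_transfer_counterion_cycles = unname(transfer_cycle),
    hydroxide_transfer_direct_leg = unname(transfer_direct),
    hydroxide_transfer_mean = unname(transfer_mean),
    water_transfer = unname(water_transfer),
    total_gap = unname(total_gap),
    u_hydroxide_transfer_counterion_cycles = unname(u_cycle),
    u_hydroxide_transfer_direct_leg = unname(u_direct),
    u_water_transfer = unname(u_water),
    u_total_gap = unname(sqrt((u_cycle^2 + u_direct^2) / 4 + u_water^2)),
    dg_hydroxide_water_interface_corrected =
      apply_interface_correction(oh_w$dg_hydroxide, -1, interface_constant),
    dg_sodium_water_interface_corrected =
      apply_interface_correction(g12_w$value, +1, interface_constant)
  )
  class(out) <- "transfer_report"
  out
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("Hydroxide / water transfer report (kcal/mol)\n")
  cat(sprintf("  dG_OH- (water)                 %8.2f +- %.2f\n",
              x$dg_hydroxide_water, x$u_hydroxide_water))
  cat(sprintf("  dG_OH- (protein)               %8.2f +- %.2f\n",
              x$dg_hydroxide_protein, x$u_hydroxide_protein))
  cat(sprintf("  dG_Na+ (water, cycle-derived)  %8.2f\n", x$dg_sodium_cycle_water))
  cat(sprintf("  dG_Na+ (water, direct leg)     %8.2f\n", x$dg_sodium_direct_water))
  cat(sprintf("  OH- transfer, counterion route %8.2f +- %.2f\n",
              x$hydroxide_transfer_counterion_cycles,
              x$u_hydroxide_transfer_counterion_cycles))
  cat(sprintf("  OH- transfer, direct route     %8.2f +- %.2f\n",
              x$hydroxide_transfer_direct_leg, x$u_hydroxide_transfer_direct_leg))
  cat(sprintf("  OH- transfer, mean             %8.2f\n", x$hydroxide_transfer_mean))
  cat(sprintf("  H2O transfer                   %8.2f +- %.2f\n",
              x$water_transfer, x$u_water_transfer))
  cat(sprintf("  total gap                      %8.2f +- %.2f\n",
              x$total_gap, x$u_total_gap))
  cat(sprintf("  interface-corrected dG_OH-     %8.2f\n",
              x$dg_hydroxide_water_interface_corrected))
  cat(sprintf("  interface-corrected dG_Na+     %8.2f\n",
              x$dg_sodium_water_interface_corrected))
  invisible(x)
}

#' Lower-bound free-energy budget of the bulk-formation-plus-transport route
#'
#' Cost of forming hydroxide by protolysis in bulk water and then moving it
#' into the target environment: \code{gap + bulk_formation}.  A lower bound,
#' since transport itself encounters additional barriers.
#'
#' @param gap transfer free-energy gap in kcal/mol.
#' @param bulk_formation free energy of hydroxide formation in bulk water,
#'   kcal/mol.
#' @return combined budget in kcal/mol.
#' @examples
#' pathway_budget(9.9, 23.88)
#' @export
pathway_budget <- function(gap, bulk_formation) {
  stopifnot(is.finite(gap), is.finite(bulk_formation))
  gap + bulk_formation
}
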