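# Reference thermodynamics: experimental kinetics and equilibrium data for
# water protolysis, converted to free energies and assembled into the
# five-point bulk-water reaction profile.

#' Activation free energy from a rate constant (Eyring-Polanyi)
#'
#' Transition-state theory relates a first-order rate constant to an
#' activation free energy through \eqn{k = (k_B T / h)\exp(-\Delta
#' G^\ddagger / k_B T)}.  Inverting gives \eqn{\Delta G^\ddagger = -k_B T
#' \ln(k h / k_B T)}, assuming a transmission coefficient of one.
#'
#' @param rate_constant first-order rate constant in s^-1 (> 0).
#' @param temperature absolute temperature in K (> 0).
#' @return activation free energy in kcal/mol.
#' @seealso [barrier_to_rate()] for the inverse, [half_life()].
#' @examples
#' ## slow autoxidation kinetics at body temperature
#' rate_to_barrier(2.56e-7, 310.15)
#' ## diffusion-limited ion recombination at 25 C
#' rate_to_barrier(1.3e11, 298.15)
#' @export
rate_to_barrier <- function(rate_constant, temperature) {
  if (!is.numeric(rate_constant) || any(rate_constant <= 0))
    stop("'rate_constant' must be positive")
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("'temperature' must be positive")
  -kBT(temperature) * log(rate_constant / (.kB_over_h * temperature))
}

#' Rate constant from an activation free energy (Eyring-Polanyi)
#'
#' @param barrier activation free energy in kcal/mol.
#' @param temperature absolute temperature in K (> 0).
#' @return first-order rate constant in s^-1.
#' @examples
#' barrier_to_rate(27.55, 310.15)
#' @export
barrier_to_rate <- function(barrier, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("'temperature' must be positive")
  (.kB_over_h * temperature) * exp(-barrier / kBT(temperature))
}

#' Half-life of a first-order process
#'
#' @param rate_constant first-order rate constant in s^-1 (> 0).
#' @return half-life \eqn{t_{1/2} = \ln 2 / k}, in hours.
#' @examples
#' half_life(2.56e-7)   # ~752 h
#' @export
half_life <- function(rate_constant) {
  if (!is.numeric(rate_constant) || any(rate_constant <= 0))
    stop("'rate_constant' must be positive")
  log(2) / rate_constant / 3600
}

#' Mole-fraction autoprotolysis equilibrium constant
#'
#' Dimensionless equilibrium constant for 2 H2O <-> H3O+ + OH- with all
#' concentrations expressed as mole fractions relative to liquid water, whose
#' own mole fraction is taken as unity: \eqn{K_{eq} = x_{H_3O^+} x_{OH^-}}.
#' Equivalent to adopting the molarity of neat water as the standard state.
#'
#' @param ion_concentration common molar concentration of H3O+ and OH-
#'   (mol/L, > 0).
#' @param water_concentration molar concentration of liquid water (mol/L);
#'   default 55.345, the molarity of neat water at 25 C.
#' @return dimensionless equilibrium constant.
#' @examples
#' autoprotolysis_keq(1e-7)   # ~3.26e-18 at pH 7
#' @export
autoprotolysis_keq <- function(ion_concentration, water_concentration = 55.345) {
  if (!is.numeric(ion_concentration) || any(ion_concentration <= 0))
    stop("'ion_concentration' must be positive")
  if (!is.numeric(water_concentration) || any(water_concentration <= 0))
    stop("'water_concentration' must be positive")
  if (any(ion_concentration > water_concentration))
    stop("'ion_concentration' must not exceed 'water_concentration'")
  (ion_concentration / water_concentration)^2
}

#' Reaction free energy from an equilibrium constant
#'
#' \eqn{\Delta G_0 = -k_B T \ln K_{eq}}.
#'
#' @param keq dimensionless equilibrium constant (> 0).
#' @param temperature absolute temperature in K; default 298.15.
#' @return reaction free energy in kcal/mol.
#' @examples
#' free_energy_from_keq(autoprotolysis_keq(1e-7))
#' @export
free_energy_from_keq <- function(keq, temperature = 298.15) {
  if (!is.numeric(keq) || any(keq <= 0)) stop("'keq' must be positive")
  -kBT(temperature) * log(keq)
}

#' Reaction free energy from a sum of pKa values
#'
#' For water protolysis the reaction free energy can be written as
#' \eqn{\Delta G_0 = k_B T \ln(10)\,(pK_a(OH^-) + |pK_a(H_3O^+)|)}, i.e. the
#' thermal energy times ln 10 times the pKa sum.  The temperature is always
#' explicit; no rounded prefactor is baked in.
#'
#' @param pka_sum sum of the relevant pKa magnitudes (dimensionless).
#' @param temperature absolute temperature in K.
#' @return reaction free energy in kcal/mol.
#' @examples
#' pka_reaction_free_energy(15.7 + 1.7, 298.15)
#' @export
pka_reaction_free_energy <- function(pka_sum, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("'temperature' must be positive")
  kBT(temperature) * .ln10 * pka_sum
}

#' Henderson-Hasselbalch protonation-state penalty
#'
#' Reversible work to hold a titratable species in a given protonation state
#' at a given pH: \eqn{\Delta G = k_B T \ln(10) (pK_a - pH)}.  Negative when
#' pH exceeds the pKa.
#'
#' @param pka acid dissociation pKa of the species.
#' @param ph solution pH.
#' @param temperature absolute temperature in K; default 310.15 (37 C).
#' @return free-energy penalty in kcal/mol.
#' @examples
#' protonation_penalty(15.7, 7.4)   # hydroxide from water at pH 7.4
#' protonation_penalty(8.11, 7.4)   # amine deprotonation
#' @export
protonation_penalty <- function(pka, ph, temperature = 310.15) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("'temperature' must be positive")
  kBT(temperature) * .ln10 * (pka - ph)
}

#' Compose an effective barrier from an intrinsic barrier plus penalties
#'
#' @param intrinsic intrinsic activation free energy in kcal/mol.
#' @param penalties numeric vector of additive free-energy penalties
#'   (kcal/mol); may be empty.
#' @return composite barrier, \code{intrinsic + sum(penalties)}.
#' @examples
#' compose_barrier(18.13, c(11.79))
#' compose_barrier(29.92, c(1.01))
#' @export
compose_barrier <- function(intrinsic, penalties = numeric()) {
  stopifnot(is.numeric(intrinsic), is.numeric(penalties))
  if (!all(is.finite(c(intrinsic, penalties)))) stop("inputs must be finite")
  intrinsic + sum(penalties)
}

#' Assemble the five-point bulk-water protolysis reaction profile
#'
#' Builds the reference free-energy diagram for 2 H2O -> H3O+ + OH-:
#' hydrogen-bonded reactant dimer (anchored at 0), first proton-transfer
#' transition state, contact-ion-pair intermediate, the structural
#' (Grotthuss) proton-diffusion transition state that controls the overall
#' process, and the separated-ion product plateau.  The controlling forward
#' barrier is the reaction free energy plus the reverse recombination
#' barrier.  The contact ion pair is placed at the product free energy (the
#' recombination of the contact ion pair is the postulated reference
#' reaction), with its preceding transition state \code{final_step_barrier}
#' above it.
#'
#' @param reaction_free_energy overall reaction free energy in kcal/mol.
#' @param reverse_barrier barrier of the reverse (ion recombination)
#'   reaction in kcal/mol (>= 0).
#' @param final_step_barrier barrier separating the contact ion pair from
#'   the reactant dimer on the recombination side, in kcal/mol; stored as an
#'   annotation (its measured rate prefactor is not transition-state-like,
#'   so it is never recomputed from a rate constant here).
#' @return an object of class \code{"reaction_profile"}: a list with the
#'   five state free energies plus \code{forward_barrier} and
#'   \code{reaction_free_energy}.
#' @examples
#' assemble_protolysis_profile(23.88, 2.33, 0.59)
#' @export
assemble_protolysis_profile <- function(reaction_free_energy, reverse_barrier,
                                        final_step_barrier = 0) {
  stopifnot(is.numeric(reaction_free_energy), is.numeric(reverse_barrier),
            is.numeric(final_step_barrier))
  if (reverse_barrier < 0) stop("'reverse_barrier' must be >= 0")
  ion_pair <- reaction_free_energy
  profile <- list(
    reactant_level = 0,
    first_ts = ion_pair + final_step_barrier,
    ion_pair_level = ion_pair,
    grotthuss_ts = reaction_free_energy + reverse_barrier,
    product_plateau = reaction_free_energy,
    forward_barrier = reaction_free_energy + reverse_barrier,
    reaction_free_energy = reaction_free_energy,
    final_step_barrier = final_step_barrier
  )
  class(profile) <- "reaction_profile"
  profile
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat("Water protolysis reaction profile (kcal/mol)\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-18s %8.2f\n", df$state_label[i], df$free_energy_kcal_mol[i]))
  cat(sprintf("  forward barrier    %8.2f\n", x$forward_barrier))
  cat(sprintf("  reaction dG0       %8.2f\n", x$reaction_free_energy))
  invisible(x)
}

#' @export
as.data.frame.reaction_profile <- function(x, ...) {
  data.frame(
    state_label = c("reactant", "first_ts", "ion_pair", "grotthuss_ts",
                    "product_plateau"),
    free_energy_kcal_mol = c(x$reactant_level, x$first_ts, x$ion_pair_level,
                             x$grotthuss_ts, x$product_plateau),
    stringsAsFactors = FALSE
  )
}

#' Write a reaction profile as TSV
#'
#' Two-column tab-separated table (state_label, free_energy_kcal_mol) with a
#' '#'-prefixed header comment.
#'
#' @param profile a \code{"reaction_profile"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "reaction_profile"))
  df <- as.data.frame(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# water protolysis reaction profile; energies in kcal/mol", con)
  writeLines("state_label\tfree_energy_kcal_mol", con)
  writeLines(sprintf("%s\t%.6g", df$state_label, df$free_energy_kcal_mol), con)
  invisible(path)
}
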