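# Physical constants (CODATA), AKMA working units: kcal/mol, Angstrom, e.

## Boltzmann constant, kcal mol^-1 K^-1
.kB <- 0.0019872041

## k_B / h in s^-1 K^-1: Eyring-Polanyi prefactor is (.kB_over_h * T)
.kB_over_h <- 2.083661912e10

## Coulomb constant in kcal mol^-1 Angstrom e^-2
.ke <- 332.0636

## kcal/mol -> amu Angstrom^2 fs^-2 (force-to-acceleration conversion in MD)
.kcal_to_akma <- 4.184e-4

.ln10 <- log(10)

#' Thermal energy k_B T
#'
#' @param temperature absolute temperature in K.
#' @return k_B T in kcal/mol.
#' @examples
#' kBT(300)
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .kB * temperature
}

## numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(mean(exp(x)))
.logmeanexp <- function(x) .logsumexp(x) - log(length(x))
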