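## Unit conventions: Angstrom, ps, kcal/mol, K.

#' Physical constants and unit conversions
#'
#' `kB_kcal` is the Boltzmann constant in kcal/(mol K).  `A_per_ps_to_cm_per_s`
#' converts a velocity-like quantity (permeability) from Angstrom/ps to cm/s.
#' `count_per_A3_to_mol_per_L` converts a number density from 1/Angstrom^3 to
#' mol/L.
#'
#' @name units
#' @keywords internal
NULL

kB_kcal <- 0.0019872041
AVOGADRO <- 6.02214076e23
A_per_ps_to_cm_per_s <- 1e4
count_per_A3_to_mol_per_L <- 1e27 / AVOGADRO

#' Inverse thermal energy beta = 1/(kB T)
#'
#' @param temperature temperature in K.
#' @return beta in mol/kcal.
#' @export
beta_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (kB_kcal * temperature)
}

# wrap coordinates into [-L/2, L/2)
wrap_centered <- function(x, L) {
  x - L * floor(x / L + 0.5)
}

# composite trapezoid on a uniform or non-uniform grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
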