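#' Physical constants used throughout the package
#'
#' Energies are in kcal/mol, lengths in nm, forces in pN.
#' `kT_kcal(300)` is 0.596 kcal/mol; `PN_PER_KCAL_NM` converts a gradient in
#' kcal/(mol nm) to pN: 1 kcal/(mol nm) = 6.948 pN.
#'
#' @name constants
NULL

#' @rdname constants
#' @export
PN_PER_KCAL_NM <- 6.948

#' Boltzmann constant in kcal/(mol K)
#' @rdname constants
#' @export
KB_KCAL_MOL_K <- 0.0019872041

#' Thermal energy in kcal/mol
#'
#' @param temperature_K temperature in Kelvin.
#' @return kB * T in kcal/mol (0.596 at 300 K, reported to the precision used
#'   by the Monte Carlo engine).
#' @export
kT_kcal <- function(temperature_K = 300) {
  if (temperature_K <= 0) stop("temperature must be positive")
  KB_KCAL_MOL_K * temperature_K
}

#' Debye screening length of a monovalent salt solution
#'
#' Computes the Debye length kappa^-1 = sqrt(eps0 epsr kB T / (2 NA e^2 I))
#' for an aqueous 1:1 electrolyte, and (via [debye_cutoff()]) the 4 kappa^-1
#' distance beyond which screened electrostatics are conventionally truncated.
#'
#' @param ionic_strength_M ionic strength in mol/L.
#' @param temperature_K temperature in Kelvin.
#' @param rel_permittivity relative permittivity of the solvent (78.4, water).
#' @return Debye length in nm.
#' @examples
#' debye_length(0.15)          # ~0.79 nm at physiological salt
#' debye_cutoff(0.15)          # ~3.14 nm
#' @export
debye_length <- function(ionic_strength_M, temperature_K = 300,
                         rel_permittivity = 78.4) {
  if (ionic_strength_M <= 0) stop("ionic strength must be positive")
  e <- 1.602176634e-19     # C
  eps0 <- 8.8541878128e-12 # F/m
  kB <- 1.380649e-23       # J/K
  NA_ <- 6.02214076e23     # 1/mol
  n <- 1000 * NA_ * ionic_strength_M  # ions per m^3 per species
  kappa_inv_m <- sqrt(eps0 * rel_permittivity * kB * temperature_K /
                        (2 * n * e^2))
  kappa_inv_m * 1e9
}

#' @rdname debye_length
#' @export
debye_cutoff <- function(ionic_strength_M, temperature_K = 300,
                         rel_permittivity = 78.4) {
  4 * debye_length(ionic_strength_M, temperature_K, rel_permittivity)
}
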