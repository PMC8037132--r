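# Physical constants (SI) and unit conversions.
# Internal convention: coordinates and radii in nm, times in ps, energies in kT.
# Analysis-facing interfaces quote Angstrom (distances), Angstrom^2 (areas,
# MSD) and cm^2/s (diffusion coefficients), matching the field's reporting
# conventions; conversions happen at those interfaces only.

.const <- list(
  e        = 1.602176634e-19,   # elementary charge, C
  eps0     = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB       = 1.380649e-23,      # Boltzmann constant, J/K
  N_A      = 6.02214076e23      # Avogadro, 1/mol
)

#' Bjerrum length in a dielectric medium
#'
#' Distance at which two unit charges interact with thermal energy kT:
#' \eqn{l_B = e^2 / (4 \pi \epsilon_0 \epsilon_s k_B T)}.
#'
#' @param dielectric relative permittivity of the solvent (dimensionless)
#' @param temperature absolute temperature, K
#' @return Bjerrum length in nm (about 0.70 nm for water at 300 K).
#' @export
bjerrum_length <- function(dielectric = 78.0, temperature = 300) {
  stopifnot(dielectric > 0, temperature > 0)
  lb_m <- .const$e^2 /
    (4 * pi * .const$eps0 * dielectric * .const$kB * temperature)
  lb_m * 1e9
}

#' Inverse Debye screening length
#'
#' \eqn{\kappa^2 = 8 \pi l_B N_A I} for a 1:1 electrolyte of ionic
#' strength I.
#'
#' @param ionic_strength mol/L
#' @inheritParams bjerrum_length
#' @return kappa in 1/nm (0 for zero ionic strength).
#' @export
debye_kappa <- function(ionic_strength, dielectric = 78.0, temperature = 300) {
  stopifnot(ionic_strength >= 0)
  if (ionic_strength == 0) return(0)
  lb <- bjerrum_length(dielectric, temperature)
  conc_nm3 <- .const$N_A * ionic_strength * 1e-24  # mol/L -> particles/nm^3
  sqrt(8 * pi * lb * conc_nm3)
}

# unit conversions
nm_to_ang  <- function(x) x * 10
ang_to_nm  <- function(x) x / 10
# 1 Angstrom^2/ps = 1e-4 cm^2/s
ang2_per_ps_to_cm2_per_s <- function(x) x * 1e-4
cm2_per_s_to_nm2_per_ps  <- function(x) x * 100
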