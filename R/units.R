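# Physical constants and unit conversions.
#
# Internal units throughout the package: Angstrom, femtosecond, Debye,
# wavenumbers in cm^-1, energies in kJ/mol, collective variables in degrees.

#' Physical constants used by hydrashell
#'
#' A named list of the physical constants the package relies on, in the
#' package's internal unit system (Angstrom, fs, Debye, cm^-1, kJ/mol).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{c_cm_fs}{speed of light, cm per fs (2.99792458e-5)}
#'   \item{debye_per_eA}{Debye per elementary-charge Angstrom (4.803204)}
#'   \item{hartree_kJmol}{kJ/mol per Hartree (2625.4996)}
#'   \item{R_kJmolK}{molar gas constant, kJ/(mol K)}
#'   \item{avogadro}{Avogadro constant, 1/mol}
#'   \item{M_water}{molar mass of water, g/mol (18.015)}
#' }
#' @export
hs_constants <- list(
  c_cm_fs       = 2.99792458e-5,
  debye_per_eA  = 4.803204,
  hartree_kJmol = 2625.4996,
  R_kJmolK      = 8.31446261815324e-3,
  avogadro      = 6.02214076e23,
  M_water       = 18.015
)

#' Convert wavenumber to frequency in cycles per fs
#' @param wavenumber wavenumber(s) in cm^-1
#' @return frequency in fs^-1 (cycles per fs)
#' @export
wavenumber_to_freq <- function(wavenumber) wavenumber * hs_constants$c_cm_fs

#' Convert frequency in cycles per fs to wavenumber
#' @param freq frequency in fs^-1
#' @return wavenumber in cm^-1
#' @export
freq_to_wavenumber <- function(freq) freq / hs_constants$c_cm_fs

#' Nyquist wavenumber for a sampling interval
#'
#' The highest wavenumber representable when dipoles are sampled every
#' `dt` fs: 1 / (2 c dt).
#'
#' @param dt sampling interval in fs
#' @return Nyquist limit in cm^-1
#' @export
nyquist_wavenumber <- function(dt) {
  stopifnot(dt > 0)
  1 / (2 * hs_constants$c_cm_fs * dt)
}

#' Convert Hartree to kJ/mol
#' @param x energy in Hartree
#' @return energy in kJ/mol
#' @export
hartree_to_kJmol <- function(x) x * hs_constants$hartree_kJmol

#' Convert kJ/mol to Hartree
#' @param x energy in kJ/mol
#' @return energy in Hartree
#' @export
kJmol_to_hartree <- function(x) x / hs_constants$hartree_kJmol

# minimum-image displacement for a cubic cell (vectorized)
min_image <- function(d, cell_edge) d - cell_edge * round(d / cell_edge)

# wrap an angle (degrees) into [-180, 180)
wrap_angle <- function(s) ((s + 180) %% 360) - 180

# valence charges under the pseudopotential convention: cores are pseudized,
# so nuclei carry valence charge in the classical dipole sum
default_valence_charges <- c(H = 1, C = 4, N = 5, O = 6)
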