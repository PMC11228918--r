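#' Physical constants used across the package
#'
#' CODATA values for the Boltzmann constant and Avogadro number; the gas
#' constant is kept at 8.314 J/(mol K), the rounded value conventional in
#' classical nucleation theory work, so that printed-table reproductions are
#' exact. The Coulomb conversion factor is the value used by common MD engines
#' for charges in elementary-charge units and distances in nm.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K (1.380649e-23).}
#'   \item{NA_mol}{Avogadro number, 1/mol.}
#'   \item{R_gas}{Gas constant, J/(mol K), rounded to 8.314.}
#'   \item{kB_kJ_mol}{Boltzmann constant in kJ/(mol K), i.e. R in kJ.}
#'   \item{f_coulomb}{Coulomb prefactor, kJ nm/(mol e^2).}
#' }
#' @export
prenuc_constants <- list(
  kB        = 1.380649e-23,
  NA_mol    = 6.02214076e23,
  R_gas     = 8.314,
  kB_kJ_mol = 0.0083144621,
  f_coulomb = 138.935458
)

#' Reference molecular constants for salicylamide
#'
#' The solute molecular volume (0.169 nm^3/molecule, from the crystal
#' structure) and molar volume (1.01853e-4 m^3/mol) used throughout the
#' cluster-occupancy and critical-nucleus calculations, together with the
#' study temperature. The study temperature is 298.15 K (25 C); the nominal
#' reporting temperature elsewhere is 298 K, but table reproduction requires
#' the exact 25 C value.
#'
#' @return A list with `molecular_volume` (nm^3/molecule), `molar_volume`
#'   (m^3/mol) and `temperature` (K).
#' @export
salicylamide_constants <- function() {
  list(
    molecular_volume = 0.169,
    molar_volume     = 1.01853e-4,
    temperature      = 298.15
  )
}

#' Molecular-volume pair used by cluster-occupancy formulas
#'
#' @param molecular_volume Molecular volume in nm^3 per molecule.
#' @param molar_volume Molar volume in m^3/mol. Defaults to
#'   `molecular_volume * N_A` converted to m^3.
#' @return An object of class `molecular_constants`.
#' @export
molecular_constants <- function(molecular_volume,
                                molar_volume = molecular_volume * 1e-27 *
                                  prenuc_constants$NA_mol) {
  stopifnot(is.numeric(molecular_volume), molecular_volume > 0,
            is.numeric(molar_volume), molar_volume > 0)
  structure(list(molecular_volume = molecular_volume,
                 molar_volume = molar_volume),
            class = "molecular_constants")
}
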