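## Internal unit registry. Bond mechanics are carried in pN and nm; the cell
## model in um, s, Pa. All conversions between the two happen through the
## helpers below so each factor appears exactly once in the package.

#' Physical constants used throughout the package
#'
#' `kB_pN_nm` is Boltzmann's constant in pN nm / K; `ke_kJ_mol_nm_e2` is the
#' Coulomb constant in kJ mol^-1 nm e^-2 (the MD convention, giving pairwise
#' forces in kJ mol^-1 nm^-1 when distances are in nm and charges in e).
#'
#' @format Named list with elements `kB_pN_nm`, `ke_kJ_mol_nm_e2`.
#' @export
adhesim_constants <- list(
  kB_pN_nm = 1.380649e-2,      # pN nm / K; kB*T at 310 K = 4.28 pN nm
  ke_kJ_mol_nm_e2 = 138.935458 # Coulomb constant, MD units
)

#' Thermal energy kB*T in pN nm
#'
#' @param T_K temperature in kelvin (310 K throughout the physiology here).
#' @return kB*T in pN nm (4.28 pN nm at 310 K).
#' @export
kBT <- function(T_K = 310) {
  stopifnot(is.numeric(T_K), T_K > 0)
  adhesim_constants$kB_pN_nm * T_K
}

#' Unit conversion helpers
#'
#' Small, explicit converters used at the interface between the bond scale
#' (pN, nm) and the cell scale (Pa, um). `Pa um^2` and `pN` are the same
#' unit, so `pa_um2_to_pN` is the identity with its reasoning on record.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
um_to_nm <- function(x) x * 1e3

#' @rdname units
#' @export
nm_to_um <- function(x) x * 1e-3

#' @rdname units
#' @export
angstrom_to_nm <- function(x) x * 0.1

#' @rdname units
#' @export
pa_um2_to_pN <- function(x) x * 1  # 1 Pa * 1 um^2 = 1e-12 N = 1 pN

#' @rdname units
#' @export
pN_per_nm_to_pN_per_um <- function(x) x * 1e3

## mass conversion: rho [kg/m^3] * volume [um^3] -> mass in pN s^2/um
## (1 pN s^2/um = 1e-6 kg)
mass_pN_units <- function(rho_kg_m3, volume_um3) {
  rho_kg_m3 * volume_um3 * 1e-18 / 1e-6
}
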