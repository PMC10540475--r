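#' Unit conversion constants
#'
#' All internal quantities are kept in atomic units (hartree for energies,
#' bohr for lengths); conversions to the reporting units of the descriptors
#' (kcal/mol, eV, angstrom) happen only at descriptor assembly. Fixing the
#' constants in one place avoids unit drift between descriptors.
#'
#' @format A named numeric vector with elements
#'   \describe{
#'     \item{hartree_to_kcalmol}{627.509474}
#'     \item{hartree_to_ev}{27.211386245988}
#'     \item{angstrom_to_bohr}{1.8897259886}
#'   }
#' @export
pka_units <- c(
  hartree_to_kcalmol = 627.509474,
  hartree_to_ev      = 27.211386245988,
  angstrom_to_bohr   = 1.8897259886
)

#' Convert energies from hartree
#'
#' @param x numeric vector of energies in hartree.
#' @return `hartree_to_ev()` returns electron-volts,
#'   `hartree_to_kcalmol()` kcal/mol.
#' @export
hartree_to_ev <- function(x) x * pka_units[["hartree_to_ev"]]

#' @rdname hartree_to_ev
#' @export
hartree_to_kcalmol <- function(x) x * pka_units[["hartree_to_kcalmol"]]

#' Convert lengths between angstrom and bohr
#'
#' @param x numeric vector of lengths.
#' @return converted lengths.
#' @export
angstrom_to_bohr <- function(x) x * pka_units[["angstrom_to_bohr"]]

#' @rdname angstrom_to_bohr
#' @export
bohr_to_angstrom <- function(x) x / pka_units[["angstrom_to_bohr"]]
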