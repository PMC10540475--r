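#' Deprotonation energy (kcal/mol)
#'
#' Energy required to remove the proton from the conjugate acid,
#' \eqn{\Delta E = E_{base} - E_{acid}}, converted from hartree to
#' kcal/mol. A higher value means deprotonation costs more energy, hence
#' a stronger base and higher pKa.
#'
#' @param pair an `acid_base_pair` from [validate_pair()].
#' @return energy in kcal/mol.
#' @export
delta_e <- function(pair) {
  stopifnot(inherits(pair, "acid_base_pair"))
  hartree_to_kcalmol(pair$base$total_energy -
                       pair$conjugate_acid$total_energy)
}

#' HOMO--LUMO gap (eV)
#'
#' \eqn{HL_{Gap} = \varepsilon_{LUMO} - \varepsilon_{HOMO}}, in eV.
#' Non-negative for any aufbau-ordered orbital spectrum.
#'
#' @param species a [species_record()] with at least one occupied and one
#'   virtual orbital.
#' @return gap in eV.
#' @export
hl_gap <- function(species) {
  stopifnot(inherits(species, "species_record"))
  hartree_to_ev(lumo_energy(species) - homo_energy(species))
}

#' Change in HOMO--LUMO gap upon deprotonation (eV)
#'
#' \eqn{\Delta HL_{Gap} = HL_{Gap}(\mathrm{base}) -
#' HL_{Gap}(\mathrm{acid})}. A larger change signals a less reactive base
#' and a lower pKa.
#'
#' @param pair an `acid_base_pair` from [validate_pair()].
#' @return gap change in eV.
#' @export
delta_hl_gap <- function(pair) {
  stopifnot(inherits(pair, "acid_base_pair"))
  hl_gap(pair$base) - hl_gap(pair$conjugate_acid)
}

#' Charged-state energy triple for vertical electron removal/attachment
#'
#' Holds the total energies of a species with N, N-1 and N+1 electrons,
#' all at the same fixed geometry (vertical, not adiabatic). When full
#' [species_record()]s are supplied, a guard checks that the three
#' geometries coincide within 1e-8 bohr; bare energies are accepted for
#' geometry-free workflows.
#'
#' @param neutral,cation,anion either total energies in hartree or
#'   [species_record()]s for the N, N-1 and N+1 electron states.
#' @return object of class `charged_state_triple` with fields
#'   `neutral_energy`, `cation_energy`, `anion_energy` (hartree).
#' @export
charged_state_triple <- function(neutral, cation, anion) {
  grab <- function(x) {
    if (inherits(x, "species_record")) x$total_energy else as.numeric(x)
  }
  geoms <- lapply(list(neutral, cation, anion), function(x)
    if (inherits(x, "species_record")) x$atoms else NULL)
  have <- !vapply(geoms, is.null, logical(1))
  if (sum(have) >= 2L) {
    ref <- geoms[have][[1]]
    for (g in geoms[have][-1]) {
      if (nrow(g) != nrow(ref) ||
          max(abs(as.matrix(g[, c("x", "y", "z")]) -
                  as.matrix(ref[, c("x", "y", "z")]))) > 1e-8)
        stop("charged-state triple must share one fixed geometry ",
             "(vertical energies); coordinates differ by more than ",
             "1e-8 bohr")
    }
  }
  e <- vapply(list(neutral, cation, anion), grab, numeric(1))
  if (any(!is.finite(e))) stop("all three energies must be finite")
  structure(list(neutral_energy = e[1], cation_energy = e[2],
                 anion_energy = e[3]),
            class = "charged_state_triple")
}

#' Vertical ionization potential and electron affinity (eV)
#'
#' \eqn{VIP = E_{N-1} - E_N} and \eqn{VEA = E_N - E_{N+1}}: the energy
#' change on removing or adding an electron at fixed geometry, converted
#' to eV.
#'
#' @param t a [charged_state_triple()].
#' @return energy in eV.
#' @export
vip <- function(t) {
  stopifnot(inherits(t, "charged_state_triple"))
  hartree_to_ev(t$cation_energy - t$neutral_energy)
}

#' @rdname vip
#' @export
vea <- function(t) {
  stopifnot(inherits(t, "charged_state_triple"))
  hartree_to_ev(t$neutral_energy - t$anion_energy)
}

#' Mulliken electronegativity (eV)
#'
#' \eqn{\chi_M = (VIP + VEA)/2}, computed for the base from vertical
#' single-point energies at the base's optimized geometry. Quantifies the
#' base's electron-attracting power: a lower \eqn{\chi_M} means a more
#' willing electron-pair donor and a higher pKa.
#'
#' @param t a [charged_state_triple()] for the base.
#' @return electronegativity in eV.
#' @export
mulliken_chi <- function(t) {
  (vip(t) + vea(t)) / 2
}
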