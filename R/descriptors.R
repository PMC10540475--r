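#' Construct a validated descriptor vector
#'
#' One row of the six regressors of the pKa model, with units as used by
#' the model: kcal/mol for `delta_e`, eV for `delta_hl_gap`, `chi_m` and
#' `delta_alie_n`, percent for `npsa_percent`, and the 0/1 categorical
#' `base_t`.
#'
#' @param delta_e deprotonation energy, kcal/mol.
#' @param delta_hl_gap HOMO--LUMO gap change, eV.
#' @param chi_m Mulliken electronegativity of the base, eV.
#' @param npsa_percent nonpolar surface area percentage, in [0, 100].
#' @param delta_alie_n nitrogen ALIE change, eV.
#' @param base_t 0 (aromatic amine) or 1 (aliphatic/non-aromatic).
#' @return one-row data frame of class `descriptor_vector`.
#' @export
descriptor_vector <- function(delta_e, delta_hl_gap, chi_m, npsa_percent,
                              delta_alie_n, base_t) {
  vals <- c(delta_e = delta_e, delta_hl_gap = delta_hl_gap, chi_m = chi_m,
            npsa_percent = npsa_percent, delta_alie_n = delta_alie_n,
            base_t = base_t)
  if (any(!is.finite(vals)))
    stop("all descriptors must be finite; got NA/Inf in ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (npsa_percent < 0 || npsa_percent > 100)
    stop("npsa_percent must lie in [0, 100]")
  if (!base_t %in% c(0, 1)) stop("base_t must be 0 or 1")
  out <- as.data.frame(as.list(vals))
  class(out) <- c("descriptor_vector", "data.frame")
  out
}

#' Compute the full descriptor vector for one acid--base pair
#'
#' Assembles all six regressors from quantum-chemistry inputs: the
#' deprotonation energy and HOMO--LUMO gap change from the pair's species
#' records, the Mulliken electronegativity from the base's vertical
#' charged-state triple, \%NPSA from the base's density and ESP grids,
#' and the nitrogen ALIE change from per-orbital densities of both
#' species.
#'
#' @param pair an `acid_base_pair` from [validate_pair()]; both species
#'   must carry a `nitrogen_site`.
#' @param base_triple a [charged_state_triple()] for the base.
#' @param base_density electron-density [volumetric_grid()] of the base.
#' @param base_esp ESP [volumetric_grid()] of the base, congruent enough
#'   to cover the isodensity surface.
#' @param base_orbitals,acid_orbitals [orbital_density_set()]s for the
#'   base and conjugate acid.
#' @param isovalue electron-density contour for the surface (default
#'   0.001 au).
#' @param polarity_threshold nonpolar |ESP| cutoff, kcal/mol (default 10).
#' @param alie_mode atomic condensation mode, see [alie_on_atom()].
#' @return a [descriptor_vector()].
#' @export
compute_descriptors <- function(pair, base_triple, base_density, base_esp,
                                base_orbitals, acid_orbitals,
                                isovalue = 0.001, polarity_threshold = 10,
                                alie_mode = c("voronoi", "nucleus")) {
  stopifnot(inherits(pair, "acid_base_pair"))
  alie_mode <- match.arg(alie_mode)
  if (is.null(pair$base$nitrogen_site) ||
      is.null(pair$conjugate_acid$nitrogen_site))
    stop("both species need a nitrogen_site to compute delta_alie_n")

  surf <- extract_isosurface(base_density, isovalue)
  surf <- map_field(surf, base_esp)
  sa <- npsa(surf, polarity_threshold)

  descriptor_vector(
    delta_e = delta_e(pair),
    delta_hl_gap = delta_hl_gap(pair),
    chi_m = mulliken_chi(base_triple),
    npsa_percent = sa$npsa_percent,
    delta_alie_n = delta_alie_n(base_orbitals, acid_orbitals,
                                pair$base$nitrogen_site,
                                pair$conjugate_acid$nitrogen_site,
                                mode = alie_mode),
    base_t = pair$base_type)
}

#' Read a descriptor-bundle directory
#'
#' A bundle directory collects every input needed for one pair's
#' descriptors under fixed names: `base.props`, `acid.props`,
#' `base_cation.props`, `base_anion.props` (canonical properties files),
#' `base_density.cube`, `base_esp.cube`, and orbital manifests
#' `base_orbitals.manifest` / `acid_orbitals.manifest` whose cube paths
#' are relative to the bundle. `base_type` is read from a one-line
#' `base_type.txt` (0 or 1).
#'
#' @param dir bundle directory path.
#' @return list with elements `pair`, `base_triple`, `base_density`,
#'   `base_esp`, `base_orbitals`, `acid_orbitals` ready for
#'   [compute_descriptors()].
#' @export
read_descriptor_bundle <- function(dir) {
  need <- function(name, what) {
    p <- file.path(dir, name)
    if (!file.exists(p))
      stop("missing input '", name, "' in bundle ", dir,
           " (required for ", what, ")")
    p
  }
  base <- read_properties(need("base.props", "delta_e / HL gap"))
  acid <- read_properties(need("acid.props", "delta_e / HL gap"))
  bt <- as.numeric(readLines(need("base_type.txt", "BaseT"),
                             warn = FALSE)[1])
  pair <- validate_pair(base, acid, bt)

  cation <- read_properties(need("base_cation.props", "chi_m (VIP)"))
  anion <- read_properties(need("base_anion.props", "chi_m (VEA)"))
  triple <- charged_state_triple(base, cation, anion)

  dens <- read_cube(need("base_density.cube", "%NPSA surface"),
                    field_kind = "density")
  esp <- read_cube(need("base_esp.cube", "%NPSA ESP mapping"),
                   field_kind = "esp")

  borb <- read_orbital_manifest(need("base_orbitals.manifest",
                                     "delta_alie_n"))
  aorb <- read_orbital_manifest(need("acid_orbitals.manifest",
                                     "delta_alie_n"))

  list(pair = pair, base_triple = triple, base_density = dens,
       base_esp = esp, base_orbitals = borb, acid_orbitals = aorb)
}

#' Read and write descriptor tables as CSV
#'
#' Canonical column names: `delta_e`, `delta_hl_gap`, `chi_m`,
#' `npsa_percent`, `delta_alie_n`, `base_t`, and optionally `pka_exp`
#' plus any identifier columns.
#'
#' @param path CSV path.
#' @return `read_descriptor_table()` returns a data frame validated to
#'   contain the six descriptor columns.
#' @export
read_descriptor_table <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(pka_descriptor_names, names(d))
  if (length(missing_cols))
    stop("descriptor table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d
}

#' @rdname read_descriptor_table
#' @param table data frame to write.
#' @export
write_descriptor_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
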