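#' Bundle per-orbital densities with their energies
#'
#' Input container for average-local-ionization-energy analysis: one
#' density grid per occupied orbital, the orbital energy, and its
#' occupation, plus the shared molecular geometry used to condense the
#' field onto atoms. All grids must be congruent (identical origin, axes
#' and shape).
#'
#' @param orbitals list of entries, each a list with elements `density`
#'   (a [volumetric_grid()]), `energy` (hartree) and `occupation` (> 0).
#' @param atoms data frame (`element`, `x`, `y`, `z`, bohr) of the shared
#'   geometry.
#' @return object of class `orbital_density_set`.
#' @export
orbital_density_set <- function(orbitals, atoms) {
  if (!length(orbitals)) stop("at least one orbital is required")
  for (o in orbitals) {
    if (!inherits(o$density, "volumetric_grid"))
      stop("each orbital needs a volumetric_grid density")
    if (!is.numeric(o$energy) || !is.finite(o$energy))
      stop("each orbital needs a finite energy (hartree)")
    if (is.null(o$occupation) || o$occupation <= 0)
      stop("orbital occupations must be > 0")
  }
  ref <- orbitals[[1]]$density
  for (o in orbitals[-1]) {
    g <- o$density
    if (!isTRUE(all.equal(g$origin, ref$origin, tolerance = 1e-10)) ||
        !isTRUE(all.equal(g$axes, ref$axes, tolerance = 1e-10)) ||
        !identical(dim(g$values), dim(ref$values)))
      stop("orbital density grids are not congruent ",
           "(origin/axes/shape must match)")
  }
  atoms <- as.data.frame(atoms)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("atoms needs columns element, x, y, z")
  structure(list(orbitals = orbitals, atoms = atoms),
            class = "orbital_density_set")
}

#' Average local ionization energy field
#'
#' Computes the ALIE scalar field
#' \deqn{I(r) = \frac{\sum_i n_i \rho_i(r) |\varepsilon_i|}
#'                   {\sum_i n_i \rho_i(r)}}
#' the density-weighted mean of the absolute orbital energies at each grid
#' point, in hartree. Occupations \eqn{n_i} weight each orbital so that
#' doubly occupied orbitals count twice; with all-equal occupations the
#' weights cancel and the plain orbital-density average is recovered.
#' Voxels with total weighted density below 1e-12 au are undefined and set
#' to `NA`.
#'
#' @param orbitals an [orbital_density_set()].
#' @return a [volumetric_grid()] (field kind `"density"` reused for the
#'   scalar field) of ALIE values in hartree, `NA` where undefined.
#' @export
alie_field <- function(orbitals) {
  stopifnot(inherits(orbitals, "orbital_density_set"))
  ref <- orbitals$orbitals[[1]]$density
  num <- array(0, dim = dim(ref$values))
  den <- array(0, dim = dim(ref$values))
  for (o in orbitals$orbitals) {
    w <- o$occupation * o$density$values
    num <- num + w * abs(o$energy)
    den <- den + w
  }
  vals <- num / den
  vals[den < 1e-12] <- NA_real_
  g <- volumetric_grid(ref$origin, ref$axes, vals, "density",
                       atoms = orbitals$atoms)
  g
}

# Voronoi (nearest-nucleus) assignment of voxels carrying density.
.voxel_nearest_atom <- function(grid, atoms) {
  d <- dim(grid$values)
  ijk <- arrayInd(seq_len(prod(d)), d)
  xyz <- grid_coords(grid, ijk[, 1], ijk[, 2], ijk[, 3])
  best <- rep.int(1L, nrow(xyz))
  bestd <- (xyz[, 1] - atoms$x[1])^2 + (xyz[, 2] - atoms$y[1])^2 +
    (xyz[, 3] - atoms$z[1])^2
  for (a in seq_len(nrow(atoms))[-1]) {
    da <- (xyz[, 1] - atoms$x[a])^2 + (xyz[, 2] - atoms$y[a])^2 +
      (xyz[, 3] - atoms$z[a])^2
    upd <- da < bestd
    best[upd] <- a
    bestd[upd] <- da[upd]
  }
  best
}

#' ALIE condensed onto one atom
#'
#' Condenses the ALIE field onto a single atom -- for pKa work, the
#' reactive nitrogen. Two condensation modes are available:
#' \describe{
#'   \item{`"voronoi"` (default)}{every voxel with total density above
#'     1e-12 au is assigned to its nearest nucleus; the atomic ALIE is the
#'     total-density-weighted mean of the field over the atom's voxels.
#'     Deterministic and parameter-free.}
#'   \item{`"nucleus"`}{the ALIE field trilinearly interpolated at the
#'     nuclear position.}
#' }
#'
#' @param orbitals an [orbital_density_set()].
#' @param atom_index 1-based index into the set's atoms.
#' @param mode `"voronoi"` or `"nucleus"`.
#' @return ALIE value on the atom, in eV.
#' @export
alie_on_atom <- function(orbitals, atom_index,
                         mode = c("voronoi", "nucleus")) {
  stopifnot(inherits(orbitals, "orbital_density_set"))
  mode <- match.arg(mode)
  atoms <- orbitals$atoms
  if (atom_index < 1L || atom_index > nrow(atoms))
    stop("atom_index out of range")

  field <- alie_field(orbitals)

  if (mode == "nucleus") {
    val <- grid_interpolate(
      .na_zero(field), as.numeric(atoms[atom_index, c("x", "y", "z")]))
    if (!is.finite(val) || val == 0)
      stop("descriptor unavailable: no density at the nucleus of atom ",
           atom_index)
    return(hartree_to_ev(val))
  }

  den <- array(0, dim = dim(field$values))
  for (o in orbitals$orbitals)
    den <- den + o$occupation * o$density$values

  assign <- .voxel_nearest_atom(field, atoms)
  sel <- assign == atom_index & as.vector(den) >= 1e-12
  if (!any(sel))
    stop("descriptor unavailable: atom ", atom_index,
         " has no assigned electron density")
  w <- as.vector(den)[sel]
  v <- as.vector(field$values)[sel]
  hartree_to_ev(sum(w * v) / sum(w))
}

# interpolation helper: treat undefined (NA) ALIE voxels as zero so that
# nucleus-mode interpolation near the density edge stays finite
.na_zero <- function(grid) {
  grid$values[is.na(grid$values)] <- 0
  grid
}

#' Change in nitrogen ALIE across the acid--base reaction
#'
#' \eqn{\Delta ALIE_N = ALIE_N(\mathrm{base}) - ALIE_N(\mathrm{acid})}:
#' the change in the average energy needed to remove an electron from the
#' reaction-center nitrogen upon protonation. A smaller value indicates
#' greater stabilization of the positive charge in the conjugate acid,
#' hence a higher pKa.
#'
#' @param base,acid [orbital_density_set()] objects for the base and its
#'   conjugate acid.
#' @param base_n,acid_n 1-based index of the reactive nitrogen in each
#'   set's atom table.
#' @param mode condensation mode, see [alie_on_atom()].
#' @return energy difference in eV.
#' @export
delta_alie_n <- function(base, acid, base_n, acid_n,
                         mode = c("voronoi", "nucleus")) {
  mode <- match.arg(mode)
  alie_on_atom(base, base_n, mode) - alie_on_atom(acid, acid_n, mode)
}

#' Read an orbital manifest and its density cubes
#'
#' The manifest is a plain-text table with one row per occupied orbital:
#' `cube-file energy occupation`, whitespace-separated, `#` comments
#' allowed. Cube paths are resolved relative to the manifest's directory.
#' Geometry is taken from the first cube's atom block.
#'
#' @param path manifest file path.
#' @return an [orbital_density_set()].
#' @export
read_orbital_manifest <- function(path) {
  if (!file.exists(path)) stop("orbital manifest not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("orbital manifest is empty: ", path)
  dir <- dirname(path)
  orbitals <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 3L)
      stop("malformed manifest line: '", ln,
           "' (expected: cube-file energy occupation)")
    list(density = read_cube(file.path(dir, parts[1]),
                             field_kind = "orbital_density"),
         energy = as.numeric(parts[2]),
         occupation = as.numeric(parts[3]))
  })
  atoms <- orbitals[[1]]$density$atoms
  if (is.null(atoms))
    stop("first cube in the manifest carries no atom block; ",
         "geometry is required for atomic condensation")
  orbital_density_set(orbitals, atoms)
}
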