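#' @importFrom stats coef lm model.matrix predict quantile rnorm runif sd setNames var
#' @importFrom utils combn read.csv write.csv
NULL

# Periodic-table symbols accepted for atom sites (H..Og).
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Create a species-level quantum-chemistry record
#'
#' A `species_record` holds one chemical species' results from an electronic
#' structure calculation: total electronic energy, the orbital energy
#' spectrum with occupations, atomic positions, net charge, and (optionally)
#' the index of the nitrogen atom acting as the acid--base reaction center.
#' Everything is stored in atomic units (hartree, bohr).
#'
#' Orbitals are sorted ascending by energy on construction (duplicate
#' energies are preserved). Closed-shell species are assumed: occupations
#' must lie in \eqn{[0, 0.5] \cup [1.5, 2]}; genuinely fractional occupations
#' are rejected. The HOMO is the highest orbital with occupation > 0.5 and
#' the LUMO the lowest with occupation <= 0.5.
#'
#' @param species_id character identifier.
#' @param net_charge integer net charge of the species.
#' @param total_energy total electronic energy, hartree.
#' @param orbital_energies data frame (or 2-column matrix) with columns
#'   `energy` (hartree) and `occupation` (0--2).
#' @param atoms data frame with columns `element`, `x`, `y`, `z`
#'   (positions in bohr), or `NULL` for a geometry-free record.
#' @param nitrogen_site optional 1-based index into `atoms` of the reactive
#'   nitrogen; that atom must be an N.
#' @return an object of class `species_record`.
#' @seealso [read_properties()], [write_properties()], [homo_energy()]
#' @export
species_record <- function(species_id, net_charge, total_energy,
                           orbital_energies, atoms = NULL,
                           nitrogen_site = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (length(net_charge) != 1L || net_charge != round(net_charge))
    stop("net_charge must be a single integer")
  if (!is.numeric(total_energy) || length(total_energy) != 1L ||
      !is.finite(total_energy))
    stop("total_energy must be a single finite number (hartree)")

  orb <- as.data.frame(orbital_energies)
  if (ncol(orb) == 2L && !all(c("energy", "occupation") %in% names(orb)))
    names(orb) <- c("energy", "occupation")
  if (!all(c("energy", "occupation") %in% names(orb)))
    stop("orbital_energies needs columns 'energy' and 'occupation'")
  if (nrow(orb) == 0L) stop("at least one orbital is required")
  if (any(!is.finite(orb$energy))) stop("orbital energies must be finite")
  if (any(orb$occupation < 0 | orb$occupation > 2))
    stop("occupations must lie in [0, 2]")
  frac <- orb$occupation > 0.5 & orb$occupation < 1.5
  if (any(frac))
    stop("fractional occupations outside [0, 0.5] U [1.5, 2] are not ",
         "supported (closed-shell species assumed)")
  orb <- orb[order(orb$energy), c("energy", "occupation"), drop = FALSE]
  rownames(orb) <- NULL
  if (!any(orb$occupation > 0))
    stop("species must have at least one occupied orbital")

  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    if (!all(c("element", "x", "y", "z") %in% names(atoms)))
      stop("atoms needs columns element, x, y, z")
    bad <- setdiff(atoms$element, .element_symbols)
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    atoms <- atoms[, c("element", "x", "y", "z")]
    rownames(atoms) <- NULL
  }
  if (!is.null(nitrogen_site)) {
    nitrogen_site <- as.integer(nitrogen_site)
    if (is.null(atoms) || nitrogen_site < 1L || nitrogen_site > nrow(atoms))
      stop("nitrogen_site must index an atom of the species")
    if (atoms$element[nitrogen_site] != "N")
      stop("nitrogen_site points at element '",
           atoms$element[nitrogen_site], "', expected N")
  }

  structure(
    list(species_id = species_id,
         net_charge = as.integer(net_charge),
         total_energy = as.numeric(total_energy),
         orbital_energies = orb,
         atoms = atoms,
         nitrogen_site = nitrogen_site),
    class = "species_record")
}

#' @export
print.species_record <- function(x, ...) {
  cat("<species_record> ", x$species_id,
      "  (charge ", x$net_charge, ")\n", sep = "")
  cat("  total energy: ", format(x$total_energy, digits = 12),
      " hartree\n", sep = "")
  cat("  orbitals: ", nrow(x$orbital_energies),
      " (", sum(x$orbital_energies$occupation > 0.5), " occupied)\n",
      sep = "")
  if (!is.null(x$atoms))
    cat("  atoms: ", nrow(x$atoms),
        if (!is.null(x$nitrogen_site))
          paste0("  [reactive N at ", x$nitrogen_site, "]"),
        "\n", sep = "")
  invisible(x)
}

#' HOMO and LUMO energies of a species
#'
#' The HOMO is the highest-energy orbital with occupation > 0.5; the LUMO
#' the lowest-energy orbital with occupation <= 0.5.
#'
#' @param species a [species_record()].
#' @return energy in hartree. `lumo_energy()` errors when the record
#'   contains no virtual orbital (the upstream calculation lacked virtuals).
#' @export
homo_energy <- function(species) {
  stopifnot(inherits(species, "species_record"))
  occ <- species$orbital_energies$occupation > 0.5
  max(species$orbital_energies$energy[occ])
}

#' @rdname homo_energy
#' @export
lumo_energy <- function(species) {
  stopifnot(inherits(species, "species_record"))
  virt <- species$orbital_energies$occupation <= 0.5
  if (!any(virt))
    stop("descriptor unavailable: species '", species$species_id,
         "' has no virtual orbital (occupied-only orbital list)")
  min(species$orbital_energies$energy[virt])
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read and write the canonical species properties file
#'
#' A human-writable, diff-friendly plain-text key/value format holding one
#' species' quantum-chemistry results. Keys: `species_id`, `net_charge`,
#' `total_energy` (hartree), optional `coord_units` (`bohr`, the default,
#' or `angstrom`), optional `nitrogen_site` (1-based atom index), an
#' `atoms:` section (`element x y z` per line) and an `orbitals:` section
#' (`energy occupation` per line, hartree). Lines beginning with `#` are
#' comments. Coordinates are normalized to bohr on read. The round trip
#' `write_properties()` then `read_properties()` is lossless to full double
#' precision.
#'
#' @param path file path.
#' @return `read_properties()` returns a [species_record()];
#'   `write_properties()` returns `path` invisibly.
#' @examples
#' rec <- species_record("ammonia", 0, -56.5,
#'                       data.frame(energy = c(-10, -0.4, 0.1),
#'                                  occupation = c(2, 2, 0)),
#'                       atoms = data.frame(element = "N",
#'                                          x = 0, y = 0, z = 0),
#'                       nitrogen_site = 1)
#' f <- tempfile(fileext = ".props")
#' write_properties(rec, f)
#' identical(read_properties(f)$total_energy, rec$total_energy)
#' @export
read_properties <- function(path) {
  if (!file.exists(path)) stop("properties file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  kv <- list()
  atoms <- NULL
  orbitals <- NULL
  section <- NULL
  for (ln in lines) {
    if (grepl("^[A-Za-z_]+\\s*:", ln)) {
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (key %in% c("atoms", "orbitals")) {
        section <- key
      } else {
        section <- NULL
        kv[[key]] <- val
      }
    } else if (identical(section, "atoms")) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 4L)
        stop("malformed atom line: '", ln, "' (expected: element x y z)")
      atoms <- rbind(atoms, data.frame(
        element = parts[1], x = as.numeric(parts[2]),
        y = as.numeric(parts[3]), z = as.numeric(parts[4])))
    } else if (identical(section, "orbitals")) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 2L)
        stop("malformed orbital line: '", ln,
             "' (expected: energy occupation)")
      orbitals <- rbind(orbitals, data.frame(
        energy = as.numeric(parts[1]), occupation = as.numeric(parts[2])))
    } else {
      stop("unexpected line outside any section: '", ln, "'")
    }
  }

  for (req in c("species_id", "net_charge", "total_energy"))
    if (is.null(kv[[req]]))
      stop("properties schema error: missing required field '", req, "'")
  if (is.null(orbitals))
    stop("properties schema error: missing required field 'orbitals'")

  units <- kv[["coord_units"]] %||% "bohr"
  if (!units %in% c("bohr", "angstrom"))
    stop("coord_units must be 'bohr' or 'angstrom', got '", units, "'")
  if (!is.null(atoms) && units == "angstrom")
    atoms[c("x", "y", "z")] <- lapply(atoms[c("x", "y", "z")],
                                      angstrom_to_bohr)

  species_record(
    species_id = kv[["species_id"]],
    net_charge = as.numeric(kv[["net_charge"]]),
    total_energy = as.numeric(kv[["total_energy"]]),
    orbital_energies = orbitals,
    atoms = atoms,
    nitrogen_site = if (!is.null(kv[["nitrogen_site"]]))
      as.integer(kv[["nitrogen_site"]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_properties
#' @param species a [species_record()] to serialize.
#' @export
write_properties <- function(species, path) {
  stopifnot(inherits(species, "species_record"))
  out <- c(
    "# pkaqsar species properties (hartree / bohr)",
    paste0("species_id: ", species$species_id),
    paste0("net_charge: ", species$net_charge),
    paste0("total_energy: ", .fmt_num(species$total_energy)))
  if (!is.null(species$nitrogen_site))
    out <- c(out, paste0("nitrogen_site: ", species$nitrogen_site))
  if (!is.null(species$atoms)) {
    out <- c(out, "atoms:")
    out <- c(out, paste(" ", species$atoms$element,
                        .fmt_num(species$atoms$x),
                        .fmt_num(species$atoms$y),
                        .fmt_num(species$atoms$z)))
  }
  out <- c(out, "orbitals:")
  out <- c(out, paste(" ", .fmt_num(species$orbital_energies$energy),
                      .fmt_num(species$orbital_energies$occupation)))
  writeLines(out, path)
  invisible(path)
}

#' Best-effort parser for plain-text quantum-chemistry output
#'
#' Extracts the last final single-point energy and the last orbital-energy
#' block from common quantum-output text (the `FINAL SINGLE POINT ENERGY`
#' line and the `ORBITAL ENERGIES` table with `NO OCC E(Eh)` columns, as
#' printed by several packages). The canonical properties format
#' ([read_properties()]) remains the contract; this helper only eases
#' transcription from raw logs.
#'
#' @param path path to the output text file.
#' @param species_id identifier for the resulting record; defaults to the
#'   file name.
#' @return a [species_record()] without geometry.
#' @export
read_qc_output <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("output file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  e_lines <- grep("FINAL SINGLE POINT ENERGY", lines, value = TRUE)
  if (!length(e_lines))
    stop("no 'FINAL SINGLE POINT ENERGY' line found in ", path)
  total_energy <- as.numeric(sub(".*FINAL SINGLE POINT ENERGY\\s+", "",
                                 e_lines[length(e_lines)]))

  hdr <- grep("ORBITAL ENERGIES", lines)
  if (!length(hdr)) stop("no 'ORBITAL ENERGIES' block found in ", path)
  i <- hdr[length(hdr)] + 1L
  orbitals <- NULL
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (length(parts) >= 3L && !any(is.na(nums[1:3]))) {
      orbitals <- rbind(orbitals, data.frame(energy = nums[3],
                                             occupation = nums[2]))
    } else if (!is.null(orbitals)) {
      break
    }
    i <- i + 1L
  }
  if (is.null(orbitals))
    stop("could not parse an orbital table after 'ORBITAL ENERGIES' in ",
         path)

  chg <- grep("Total Charge", lines, value = TRUE)
  net_charge <- if (length(chg)) {
    as.numeric(sub(".*?(-?\\d+)\\s*$", "\\1", chg[length(chg)]))
  } else 0

  species_record(species_id %||% basename(path), net_charge, total_energy,
                 orbitals)
}

#' Pair a base with its conjugate acid
#'
#' The unit of descriptor computation is an acid--base pair. The protocol
#' requires the base to carry net charge 0 and the conjugate acid net
#' charge +1; ionic bases must first be neutralized with their counterion
#' (Cl- or Na+). `base_type` is the categorical BaseT descriptor: 0 for
#' aromatic amines, 1 for aliphatic or non-aromatic amines.
#'
#' @param base [species_record()] of the base (net charge 0).
#' @param acid [species_record()] of the conjugate acid (net charge +1).
#' @param base_type 0 (aromatic amine) or 1 (aliphatic/non-aromatic).
#' @return an object of class `acid_base_pair` with elements `base`,
#'   `conjugate_acid`, `base_type`.
#' @export
validate_pair <- function(base, acid, base_type) {
  stopifnot(inherits(base, "species_record"),
            inherits(acid, "species_record"))
  if (base$net_charge != 0L || acid$net_charge != 1L)
    stop("charge convention violated: the base must have net charge 0 and ",
         "the conjugate acid net charge +1 (got ", base$net_charge, " and ",
         acid$net_charge, "); an ionic base should be neutralized with its ",
         "respective counterion (Cl- or Na+) before computing descriptors")
  if (length(base_type) != 1L || !base_type %in% c(0, 1))
    stop("base_type must be 0 (aromatic amine) or 1 (aliphatic or ",
         "non-aromatic amine)")
  structure(list(base = base, conjugate_acid = acid,
                 base_type = as.integer(base_type)),
            class = "acid_base_pair")
}

#' @export
print.acid_base_pair <- function(x, ...) {
  cat("<acid_base_pair> base: ", x$base$species_id,
      "  acid: ", x$conjugate_acid$species_id,
      "  BaseT = ", x$base_type, "\n", sep = "")
  invisible(x)
}
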