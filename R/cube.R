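#' Construct a volumetric grid
#'
#' A scalar field sampled on a (possibly non-orthogonal) regular grid, in
#' atomic units. This is the in-memory form of a Gaussian cube file:
#' electron density, electrostatic potential, or a per-orbital density.
#'
#' @param origin 3-vector, bohr: position of grid point (1,1,1).
#' @param axes 3x3 matrix whose rows are the voxel step vectors, bohr.
#' @param values 3-d numeric array (nx, ny, nz) of field values, atomic
#'   units, or a vector of length nx*ny*nz together with `shape`.
#' @param field_kind one of `"density"`, `"esp"`, `"orbital_density"`.
#' @param shape integer 3-vector, required when `values` is not an array.
#' @param atoms optional data frame (`element`, `x`, `y`, `z`, bohr) carried
#'   along for provenance and written back out by [write_cube()].
#' @return an object of class `volumetric_grid`.
#' @export
volumetric_grid <- function(origin, axes, values,
                            field_kind = c("density", "esp",
                                           "orbital_density"),
                            shape = NULL, atoms = NULL) {
  field_kind <- match.arg(field_kind)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  axes <- matrix(as.numeric(axes), 3L, 3L)
  if (abs(det(axes)) < 1e-14)
    stop("axes rows must be linearly independent")
  if (is.null(dim(values))) {
    if (is.null(shape)) stop("shape required when values is a plain vector")
    shape <- as.integer(shape)
    if (length(values) != prod(shape))
      stop("values count ", length(values), " != product of shape ",
           prod(shape))
    values <- array(as.numeric(values), dim = shape)
  } else {
    if (length(dim(values)) != 3L) stop("values must be a 3-d array")
    storage.mode(values) <- "double"
  }
  if (any(dim(values) < 2L)) stop("each grid dimension needs >= 2 points")
  structure(list(origin = origin, axes = axes, values = values,
                 field_kind = field_kind, atoms = atoms),
            class = "volumetric_grid")
}

#' @export
print.volumetric_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<volumetric_grid> ", x$field_kind, "  ",
      d[1], " x ", d[2], " x ", d[3], " points\n", sep = "")
  cat("  origin (bohr): ", paste(format(x$origin, digits = 6),
                                 collapse = " "), "\n", sep = "")
  cat("  value range: ", format(min(x$values), digits = 6), " .. ",
      format(max(x$values), digits = 6), "\n", sep = "")
  invisible(x)
}

# Cartesian coordinates (n x 3, bohr) of grid points given 1-based integer
# (or fractional) indices i, j, k.
grid_coords <- function(grid, i, j, k) {
  cbind(grid$origin[1] + (i - 1) * grid$axes[1, 1] +
          (j - 1) * grid$axes[2, 1] + (k - 1) * grid$axes[3, 1],
        grid$origin[2] + (i - 1) * grid$axes[1, 2] +
          (j - 1) * grid$axes[2, 2] + (k - 1) * grid$axes[3, 2],
        grid$origin[3] + (i - 1) * grid$axes[1, 3] +
          (j - 1) * grid$axes[2, 3] + (k - 1) * grid$axes[3, 3])
}

# Fractional 1-based grid indices of cartesian points (n x 3).
grid_fractional <- function(grid, points) {
  points <- matrix(points, ncol = 3L)
  rel <- sweep(points, 2L, grid$origin)
  frac <- rel %*% solve(grid$axes)   # axes rows are step vectors
  frac + 1
}

#' Trilinear interpolation of a volumetric grid
#'
#' Evaluates the field at arbitrary cartesian points by trilinear
#' interpolation; exact for fields affine in the grid's fractional
#' coordinates.
#'
#' @param grid a [volumetric_grid()].
#' @param points n x 3 matrix of cartesian coordinates, bohr.
#' @return numeric vector of interpolated values. Errors if any point falls
#'   outside the grid, naming the first offending point.
#' @export
grid_interpolate <- function(grid, points) {
  points <- matrix(points, ncol = 3L)
  f <- grid_fractional(grid, points)
  d <- dim(grid$values)
  eps <- 1e-9
  out_lo <- f < 1 - eps
  out_hi <- sweep(f, 2L, d, `>`) &
    sweep(f, 2L, d + eps, function(a, b) a > b)
  bad <- which(rowSums(out_lo) + rowSums(out_hi) > 0)
  if (length(bad))
    stop("point ", bad[1], " (",
         paste(format(points[bad[1], ], digits = 6), collapse = ", "),
         ") lies outside the field domain")
  f <- pmin(pmax(f, 1), matrix(rep(d, each = nrow(f)), ncol = 3L))

  i0 <- pmin(floor(f[, 1]), d[1] - 1L); tx <- f[, 1] - i0
  j0 <- pmin(floor(f[, 2]), d[2] - 1L); ty <- f[, 2] - j0
  k0 <- pmin(floor(f[, 3]), d[3] - 1L); tz <- f[, 3] - k0

  v <- grid$values
  idx <- function(di, dj, dk)
    v[cbind(i0 + di, j0 + dj, k0 + dk)]
  c000 <- idx(0, 0, 0); c100 <- idx(1, 0, 0)
  c010 <- idx(0, 1, 0); c110 <- idx(1, 1, 0)
  c001 <- idx(0, 0, 1); c101 <- idx(1, 0, 1)
  c011 <- idx(0, 1, 1); c111 <- idx(1, 1, 1)

  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

.symbol_to_z <- function(sym) match(sym, .element_symbols)

#' Read and write Gaussian cube files
#'
#' Standard cube layout: two comment lines; a line with the atom count and
#' grid origin; three axis lines (`n  vx vy vz`); the atom block; then the
#' scalar values with the innermost index varying fastest over the third
#' axis. Two common dialects are handled: a negative atom count marks an
#' orbital cube (one extra line of orbital ids follows the atom block), and
#' a negative voxel count flags angstrom units for that axis (and the
#' origin), which are converted to bohr on read. `write_cube()` emits
#' full-precision values so that a round trip is lossless.
#'
#' @param path file path.
#' @param field_kind field label attached to the grid on read (the cube
#'   format itself does not record one); orbital cubes default to
#'   `"orbital_density"`.
#' @return `read_cube()` returns a [volumetric_grid()] (with an
#'   `orbital_ids` attribute for orbital cubes); `write_cube()` returns
#'   `path` invisibly.
#' @export
read_cube <- function(path, field_kind = NULL) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("cube file too short: ", path)

  num <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms_raw <- hdr[1]
  natoms <- abs(as.integer(natoms_raw))
  origin <- hdr[2:4]

  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  ang <- logical(3)
  for (a in 1:3) {
    ax <- num(lines[3 + a])
    counts[a] <- abs(as.integer(ax[1]))
    ang[a] <- ax[1] < 0
    axes[a, ] <- ax[2:4]
  }
  if (any(ang)) {
    axes[ang, ] <- angstrom_to_bohr(axes[ang, , drop = FALSE])
    origin <- angstrom_to_bohr(origin)
  }

  at_lines <- lines[seq_len(natoms) + 6L]
  atoms <- NULL
  if (natoms > 0L) {
    am <- do.call(rbind, lapply(at_lines, num))
    xyz <- am[, 3:5, drop = FALSE]
    if (any(ang)) xyz <- angstrom_to_bohr(xyz)
    atoms <- data.frame(element = .element_symbols[as.integer(am[, 1])],
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }

  rest <- lines[-seq_len(6L + natoms)]
  orbital_ids <- NULL
  if (natoms_raw < 0) {
    dset <- num(rest[1])
    orbital_ids <- as.integer(dset[-1][seq_len(dset[1])])
    rest <- rest[-1]
  }
  vals <- suppressWarnings(as.numeric(
    unlist(strsplit(trimws(rest), "\\s+"), use.names = FALSE)))
  vals <- vals[!is.na(vals)]
  expected <- prod(counts)
  if (length(vals) != expected)
    stop("cube value block truncated or overlong: expected ", expected,
         " values (", counts[1], "x", counts[2], "x", counts[3],
         "), found ", length(vals))

  # file order: x slowest, z fastest -> array dim (nz, ny, nx), then aperm
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  if (is.null(field_kind))
    field_kind <- if (natoms_raw < 0) "orbital_density" else "density"
  g <- volumetric_grid(origin, axes, arr, field_kind, atoms = atoms)
  attr(g, "orbital_ids") <- orbital_ids
  g
}

#' @rdname read_cube
#' @param grid a [volumetric_grid()] to serialize.
#' @param comment character used for the first comment line.
#' @param orbital_ids optional integer vector; when given, the orbital-cube
#'   dialect (negative atom count + id line) is written.
#' @export
write_cube <- function(grid, path, comment = "pkaqsar volumetric grid",
                       orbital_ids = attr(grid, "orbital_ids")) {
  stopifnot(inherits(grid, "volumetric_grid"))
  d <- dim(grid$values)
  atoms <- grid$atoms
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  if (!is.null(orbital_ids) && natoms == 0L)
    stop("the orbital-cube dialect flags itself with a negative atom ",
         "count; give the grid an atom block to write orbital ids")
  natoms_field <- if (!is.null(orbital_ids)) -natoms else natoms

  f3 <- function(x) paste(sprintf("%25.17e", x), collapse = "")
  out <- c(comment,
           paste0("field: ", grid$field_kind, " (bohr, atomic units)"),
           paste0(sprintf("%5d", natoms_field), f3(grid$origin)))
  for (a in 1:3)
    out <- c(out, paste0(sprintf("%5d", d[a]), f3(grid$axes[a, ])))
  if (natoms > 0L)
    out <- c(out, vapply(seq_len(natoms), function(i)
      paste0(sprintf("%5d", .symbol_to_z(atoms$element[i])),
             f3(c(0, atoms$x[i], atoms$y[i], atoms$z[i]))),
      character(1)))
  if (!is.null(orbital_ids))
    out <- c(out, paste(sprintf("%5d",
                                c(length(orbital_ids), orbital_ids)),
                        collapse = ""))

  # x slowest, z fastest
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  ns <- sprintf("%25.17e", vals)
  grp <- ceiling(seq_along(ns) / 6)
  out <- c(out, vapply(split(ns, grp), paste, character(1), collapse = ""))
  writeLines(out, path)
  invisible(path)
}
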