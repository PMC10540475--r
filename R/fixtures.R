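# Evaluate code under a temporary RNG seed, restoring global RNG state so
# generators are pure functions of (parameters, seed).
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Analytic Gaussian density sphere
#'
#' Samples \eqn{\rho(r) = A e^{-\alpha r^2}} on a cubic grid centred at
#' the origin. The isodensity contour at isovalue \eqn{c} is an exact
#' sphere of radius \eqn{r^* = \sqrt{\ln(A/c)/\alpha}}, giving the surface
#' extraction a closed-form oracle. The fixture attaches its own ground
#' truth as attributes `surface_radius` and `surface_area`
#' (\eqn{4\pi r^{*2}}), or `NA` when the amplitude never reaches the
#' isovalue (empty surface).
#'
#' @param amplitude peak density A, au.
#' @param alpha Gaussian exponent, bohr^-2.
#' @param box edge length of the cubic grid, bohr.
#' @param spacing grid spacing, bohr (0.25 mirrors the surface-analysis
#'   protocol's grid step).
#' @param isovalue contour used for the attached ground truth (default
#'   0.001 au).
#' @return a density [volumetric_grid()] with ground-truth attributes and
#'   a single N atom at the origin in its atom table.
#' @export
gaussian_sphere <- function(amplitude = 1, alpha = 1, box = 24,
                            spacing = 0.25, isovalue = 0.001) {
  if (amplitude > isovalue) {
    boundary <- amplitude * exp(-alpha * (box / 2)^2)
    if (boundary >= isovalue / 10)
      stop("box too small: boundary density ", format(boundary),
           " exceeds isovalue/10; enlarge box")
  }
  n <- as.integer(round(box / spacing)) + 1L
  coords <- seq(-box / 2, by = spacing, length.out = n)
  r2x <- coords^2
  vals <- amplitude * exp(-alpha * outer(outer(r2x, r2x, "+"), r2x, "+"))
  g <- volumetric_grid(origin = rep(coords[1], 3),
                       axes = diag(spacing, 3), values = vals,
                       field_kind = "density",
                       atoms = data.frame(element = "N",
                                          x = 0, y = 0, z = 0))
  if (amplitude > isovalue) {
    rstar <- sqrt(log(amplitude / isovalue) / alpha)
    attr(g, "surface_radius") <- rstar
    attr(g, "surface_area") <- 4 * pi * rstar^2
  } else {
    attr(g, "surface_radius") <- NA_real_
    attr(g, "surface_area") <- 0
  }
  g
}

#' Gaussian sphere with a hemisphere-splitting ESP field
#'
#' Pairs the [gaussian_sphere()] density with an ESP field
#' \eqn{V(z) = 2\,V_{thr}\,\mathrm{logistic}(z/w)} that crosses the
#' polarity threshold exactly at the equator: the upper hemisphere of the
#' isodensity sphere maps above the threshold (polar), the lower below it
#' (nonpolar), so the analytic \%NPSA is 50.
#'
#' @param polarity_threshold threshold the field is scaled to, kcal/mol.
#' @param width logistic width w, bohr; keep at or above the grid spacing
#'   so the transition is resolved.
#' @inheritParams gaussian_sphere
#' @return list with elements `density` and `esp` (both
#'   [volumetric_grid()]s) and attribute `npsa_percent` = 50.
#' @export
dipole_esp_sphere <- function(polarity_threshold = 10, width = 0.5,
                              amplitude = 1, alpha = 1, box = 24,
                              spacing = 0.25, isovalue = 0.001) {
  dens <- gaussian_sphere(amplitude, alpha, box, spacing, isovalue)
  n <- dim(dens$values)[3]
  z <- seq(dens$origin[3], by = spacing, length.out = n)
  thr_au <- polarity_threshold / pka_units[["hartree_to_kcalmol"]]
  esp_z <- 2 * thr_au * stats::plogis(z / width)
  # values vary along the third (z) index only
  esp_vals <- array(rep(esp_z, each = n * n), dim = c(n, n, n))
  esp <- volumetric_grid(dens$origin, diag(spacing, 3), esp_vals, "esp")
  out <- list(density = dens, esp = esp)
  attr(out, "npsa_percent") <- 50
  out
}

#' Two well-separated single-orbital atoms
#'
#' Builds an [orbital_density_set()] of two Gaussian orbitals with
#' effectively disjoint support, one centred on each of two atoms placed
#' `separation` bohr apart along x. Since each atom's density comes from
#' a single orbital, the condensed ALIE on atom A is exactly
#' \eqn{|\varepsilon_A|} (any partition), giving a hand-computable oracle
#' for atomic condensation.
#'
#' @param energies length-2 orbital energies, hartree.
#' @param occupations length-2 occupations.
#' @param separation distance between the atoms, bohr.
#' @param alpha Gaussian exponent of each orbital density, bohr^-2.
#' @param box,spacing grid geometry, bohr.
#' @param elements length-2 element symbols for the two atoms.
#' @return an [orbital_density_set()]; ground-truth per-atom ALIE (eV)
#'   attached as attribute `alie_ev`.
#' @export
disjoint_orbitals <- function(energies = c(-0.5, -0.3),
                              occupations = c(2, 2), separation = 8,
                              alpha = 2, box = 16, spacing = 0.5,
                              elements = c("N", "C")) {
  n <- as.integer(round(box / spacing)) + 1L
  coords <- seq(-box / 2, by = spacing, length.out = n)
  centers <- c(-separation / 2, separation / 2)
  atoms <- data.frame(element = elements, x = centers, y = 0, z = 0)
  orbitals <- lapply(1:2, function(i) {
    dx2 <- (coords - centers[i])^2
    vals <- exp(-alpha * outer(outer(dx2, coords^2, "+"), coords^2, "+"))
    list(density = volumetric_grid(rep(coords[1], 3), diag(spacing, 3),
                                   vals, "orbital_density"),
         energy = energies[i], occupation = occupations[i])
  })
  out <- orbital_density_set(orbitals, atoms)
  attr(out, "alie_ev") <- hartree_to_ev(abs(energies))
  out
}

#' Synthetic descriptor dataset with a known linear law
#'
#' Draws descriptor rows from documented ranges matching the magnitudes
#' of the real training regime (deprotonation energies of a few hundred
#' kcal/mol, gaps and electronegativities of a few eV, \%NPSA between 40
#' and 95, Bernoulli(0.5) amine type) and generates
#' \eqn{y = a_0 + X\beta + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. With the default published
#' coefficients the noiseless response lands in the 0--12 pKa range of
#' the validation tables. Same seed, same table, bit for bit.
#'
#' @param beta named coefficient vector over (a subset of) the canonical
#'   descriptors; defaults to the published model's coefficients.
#' @param intercept intercept a_0 (default the published -30.7139).
#' @param n number of rows (default 130, the training-set size).
#' @param noise_sd Gaussian noise sd (default 0.3, the scale of the
#'   training standard error).
#' @param seed integer RNG seed.
#' @return data frame with the six descriptor columns plus `pka_exp`;
#'   attributes `beta`, `intercept`, `noise_sd` carry the ground truth.
#' @export
linear_dataset <- function(beta = NULL, intercept = -30.7139, n = 130,
                           noise_sd = 0.3, seed = 20230928) {
  if (is.null(beta))
    beta <- coef(published_model())[pka_descriptor_names]
  if (is.null(names(beta)) ||
      !all(names(beta) %in% pka_descriptor_names))
    stop("beta must be named with canonical descriptor names")
  if (n <= length(beta) + 1L)
    stop("n must exceed length(beta) + 1")
  .with_seed(seed, {
    d <- data.frame(
      delta_e = runif(n, 280, 380),
      delta_hl_gap = runif(n, -2, 2),
      chi_m = runif(n, 2, 6),
      npsa_percent = runif(n, 40, 95),
      delta_alie_n = runif(n, -1, 1),
      base_t = stats::rbinom(n, 1, 0.5))
    y <- rep.int(intercept, n)
    for (nm in names(beta)) y <- y + beta[[nm]] * d[[nm]]
    d$pka_exp <- y + rnorm(n, 0, noise_sd)
    attr(d, "beta") <- beta
    attr(d, "intercept") <- intercept
    attr(d, "noise_sd") <- noise_sd
    d
  })
}

#' Write a complete synthetic descriptor bundle
#'
#' Materializes a deterministic, fully synthetic input bundle in the
#' layout expected by [read_descriptor_bundle()]: base and conjugate-acid
#' properties files, vertical cation/anion single points, density and ESP
#' cubes of the base, and single-orbital density manifests for both
#' species. Intended for end-to-end and command-line tests; every
#' quantity is hand-chosen, not derived from any real molecule.
#'
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly. The implied descriptor values are
#'   recomputable through [compute_descriptors()].
#' @export
write_fixture_bundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  natom <- data.frame(element = "N", x = 0, y = 0, z = 0)
  base <- species_record("synthetic_base", 0, -100.0,
                         data.frame(energy = c(-0.5, 0.1),
                                    occupation = c(2, 0)),
                         atoms = natom, nitrogen_site = 1)
  acid <- species_record("synthetic_acid", 1, -100.5,
                         data.frame(energy = c(-0.6, 0.05),
                                    occupation = c(2, 0)),
                         atoms = natom, nitrogen_site = 1)
  cation <- species_record("synthetic_base_cation", 1, -99.7,
                           data.frame(energy = -0.6, occupation = 2),
                           atoms = natom)
  anion <- species_record("synthetic_base_anion", -1, -100.1,
                          data.frame(energy = -0.1, occupation = 2),
                          atoms = natom)
  write_properties(base, file.path(dir, "base.props"))
  write_properties(acid, file.path(dir, "acid.props"))
  write_properties(cation, file.path(dir, "base_cation.props"))
  write_properties(anion, file.path(dir, "base_anion.props"))
  writeLines("1", file.path(dir, "base_type.txt"))

  dens <- gaussian_sphere(amplitude = 1, alpha = 1, box = 14,
                          spacing = 0.5)
  dens$atoms <- natom
  write_cube(dens, file.path(dir, "base_density.cube"))
  esp <- volumetric_grid(dens$origin, dens$axes,
                         array(0.005, dim = dim(dens$values)), "esp")
  write_cube(esp, file.path(dir, "base_esp.cube"))

  orb <- dens
  orb$field_kind <- "orbital_density"
  write_cube(orb, file.path(dir, "base_orbital1.cube"), orbital_ids = 1L)
  write_cube(orb, file.path(dir, "acid_orbital1.cube"), orbital_ids = 1L)
  writeLines("base_orbital1.cube -0.5 2",
             file.path(dir, "base_orbitals.manifest"))
  writeLines("acid_orbital1.cube -0.4 2",
             file.path(dir, "acid_orbitals.manifest"))
  invisible(dir)
}
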