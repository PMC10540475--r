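test_that("species records sort orbitals and locate frontier orbitals", {
  rec <- species_record("s", 0, -100,
                        data.frame(energy = c(0.1, -0.5, -0.3),
                                   occupation = c(0, 2, 2)))
  expect_equal(rec$orbital_energies$energy, c(-0.5, -0.3, 0.1))
  expect_equal(homo_energy(rec), -0.3)
  expect_equal(lumo_energy(rec), 0.1)

  # duplicate energies preserved
  rec2 <- species_record("s", 0, -1,
                         data.frame(energy = c(-0.3, -0.3),
                                    occupation = c(2, 0)))
  expect_equal(nrow(rec2$orbital_energies), 2L)
  expect_equal(homo_energy(rec2), lumo_energy(rec2))

  expect_error(species_record("s", 0, -1,
                              data.frame(energy = -0.5, occupation = 1.0)),
               "fractional")
  expect_error(species_record("s", 0, -1,
                              data.frame(energy = -0.5, occupation = 0)),
               "occupied")
  expect_error(lumo_energy(species_record("s", 0, -1,
                                          data.frame(energy = c(-1, -0.5),
                                                     occupation = c(2, 2)))),
               "no virtual")
})

test_that("nitrogen_site must point at a nitrogen atom", {
  atoms <- data.frame(element = c("C", "N"), x = c(0, 1), y = 0, z = 0)
  orb <- data.frame(energy = c(-0.5, 0.1), occupation = c(2, 0))
  expect_silent(species_record("s", 0, -1, orb, atoms, nitrogen_site = 2))
  expect_error(species_record("s", 0, -1, orb, atoms, nitrogen_site = 1),
               "expected N")
  expect_error(species_record("s", 0, -1, orb,
                              data.frame(element = "Xx", x = 0, y = 0,
                                         z = 0)),
               "unknown element")
})

test_that("properties files round-trip losslessly and report schema errors", {
  rec <- species_record("aniline_base", 0, -287.54321098765432,
                        data.frame(energy = c(-10.2, -0.31415926535,
                                              0.0271828),
                                   occupation = c(2, 2, 0)),
                        atoms = data.frame(element = c("N", "H"),
                                           x = c(0, 1.00700036),
                                           y = c(0, -0.5),
                                           z = c(0.25, 0)),
                        nitrogen_site = 1)
  f <- tempfile(fileext = ".props")
  write_properties(rec, f)
  back <- read_properties(f)
  expect_identical(back$total_energy, rec$total_energy)
  expect_identical(back$orbital_energies, rec$orbital_energies)
  expect_identical(back$atoms$x, rec$atoms$x)
  expect_identical(back$nitrogen_site, rec$nitrogen_site)
  expect_identical(back$net_charge, rec$net_charge)

  # angstrom coordinates are normalized to bohr on read
  fa <- tempfile()
  writeLines(c("species_id: a", "net_charge: 0", "total_energy: -1",
               "coord_units: angstrom", "atoms:", "N 1.0 0 0",
               "orbitals:", "-0.5 2"), fa)
  expect_equal(read_properties(fa)$atoms$x, 1.8897259886)

  fb <- tempfile()
  writeLines(c("species_id: a", "net_charge: 0",
               "orbitals:", "-0.5 2"), fb)
  expect_error(read_properties(fb), "total_energy")
})

test_that("the quantum-output text parser extracts energy and orbitals", {
  f <- tempfile()
  writeLines(c("some header", "Total Charge           Charge ....    1",
               "                 ORBITAL ENERGIES",
               "                 ----------------",
               "  NO   OCC          E(Eh)            E(eV)",
               "   0   2.0000     -10.250000      -278.9166",
               "   1   2.0000      -0.400000       -10.8846",
               "   2   0.0000       0.120000         3.2654",
               "",
               "FINAL SINGLE POINT ENERGY      -123.456789012345"), f)
  rec <- read_qc_output(f, "probe")
  expect_equal(rec$total_energy, -123.456789012345)
  expect_equal(rec$net_charge, 1L)
  expect_equal(rec$orbital_energies$energy, c(-10.25, -0.4, 0.12))
  expect_equal(homo_energy(rec), -0.4)
})

test_that("acid-base pairing enforces the charge convention", {
  orb <- data.frame(energy = c(-0.5, 0.1), occupation = c(2, 0))
  base <- species_record("b", 0, -100, orb)
  acid <- species_record("a", 1, -100.5, orb)
  p <- validate_pair(base, acid, 1)
  expect_s3_class(p, "acid_base_pair")
  expect_identical(p$base_type, 1L)

  anion <- species_record("an", -1, -100, orb)
  neutral <- species_record("n", 0, -100, orb)
  expect_error(validate_pair(anion, neutral, 0), "counterion")
  expect_error(validate_pair(base, acid, 2), "base_type")
})

test_that("cube files round-trip and preserve voxel order", {
  g <- volumetric_grid(c(-1, 0, 0.5), diag(0.5, 3),
                       array(as.numeric(0:63), c(4, 4, 4)), "density",
                       atoms = data.frame(element = "N", x = 0, y = 0,
                                          z = 0))
  f <- tempfile(fileext = ".cube")
  write_cube(g, f)
  back <- read_cube(f)
  expect_identical(back$values, g$values)
  expect_equal(back$origin, g$origin)
  expect_equal(back$axes, g$axes)
  expect_equal(back$atoms$element, "N")

  # voxel-order property: exhaustive identity on small shapes
  for (shape in list(c(2, 3, 4), c(5, 2, 3), c(5, 5, 5))) {
    gg <- volumetric_grid(c(0, 0, 0), diag(1, 3),
                          array(seq_len(prod(shape)) * 1.0, shape),
                          "density")
    ff <- tempfile()
    write_cube(gg, ff)
    bb <- read_cube(ff)
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      expect_identical(bb$values[i, j, ], gg$values[i, j, ])
  }
})

test_that("orbital-cube and angstrom cube dialects are handled", {
  g <- volumetric_grid(c(0, 0, 0), diag(0.4, 3),
                       array(runif(27), c(3, 3, 3)), "orbital_density",
                       atoms = data.frame(element = "C", x = 0.5, y = 0.5,
                                          z = 0.5))
  f <- tempfile()
  write_cube(g, f, orbital_ids = 7L)
  back <- read_cube(f)
  expect_identical(back$values, g$values)
  expect_identical(attr(back, "orbital_ids"), 7L)
  expect_equal(back$field_kind, "orbital_density")

  # negative voxel counts flag angstrom axes: hand conversion oracle
  fa <- tempfile()
  writeLines(c("comment", "comment",
               "   0   1.0 1.0 1.0",
               "  -3   0.5 0.0 0.0",
               "  -3   0.0 0.5 0.0",
               "  -3   0.0 0.0 0.5",
               paste(rep("0.0", 27), collapse = " ")), fa)
  ga <- read_cube(fa)
  expect_equal(ga$axes[1, 1], 0.5 * 1.8897259886)
  expect_equal(ga$origin, rep(1.8897259886, 3))

  # truncated value block reports expected vs found counts
  ft <- tempfile()
  writeLines(c("c", "c", "   0   0 0 0",
               "   3   1 0 0", "   3   0 1 0", "   3   0 0 1",
               paste(rep("0.0", 20), collapse = " ")), ft)
  expect_error(read_cube(ft), "expected 27.*found 20")
})
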