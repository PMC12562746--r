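test_that("Cauchy dispersion evaluates the printed coefficient sets", {
  tio2 <- cauchy_model(2.39513, 0.03471, -0.00835)
  sio2 <- cauchy_model(1.46705, 0.00364, -3.049e-6)

  # at 1 um every wavelength power is 1, so the value is the coefficient sum
  expect_equal(cauchy_index(tio2, 1), 2.39513 + 0.03471 - 0.00835,
               tolerance = 1e-12)
  expect_equal(cauchy_index(sio2, 1), 1.46705 + 0.00364 - 3.049e-6,
               tolerance = 1e-12)

  # degenerate constant-index model
  const <- cauchy_model(1.7, 0, 0)
  expect_equal(cauchy_index(const, c(0.4, 0.8, 1.2)), rep(1.7, 3))

  # normal dispersion through the operating band. The TiO2 set's negative
  # lambda^-4 coefficient turns the curve over below ~0.69 um, so its
  # monotone range starts there; SiO2 is monotone across the full validity
  # window. Both stay above 1 everywhere they are valid.
  grid <- seq(0.30, 1.25, by = 0.005)
  expect_true(all(diff(cauchy_index(tio2, seq(0.70, 1.25, by = 0.005))) < 0))
  expect_true(all(diff(cauchy_index(sio2, grid)) < 0))
  expect_true(all(cauchy_index(tio2, grid) > 1))
  expect_true(all(cauchy_index(sio2, grid) > 1))

  # out-of-range evaluation is an error naming the material, not extrapolation
  expect_error(cauchy_index(tio2, 1.30, name = "TiO2"), "TiO2")
  expect_error(material_index(material("TiO2", tio2), 0.25), "TiO2")
})

test_that("tabulated indices interpolate inside the span only", {
  toy <- tabulated_nk(c(1.0, 1.1), c(0.1, 0.1), c(6.0, 7.0), "toy")
  # knot values are reproduced unchanged
  expect_equal(tabulated_index(toy, 1.0), 0.1 + 6.0i)
  # linear midpoint of a two-row table
  expect_equal(tabulated_index(toy, 1.05), 0.1 + 6.5i, tolerance = 1e-12)
  # flat segment returns the shared value
  flat <- tabulated_nk(c(0.9, 1.2), c(0.2, 0.2), c(5, 5), "flat")
  expect_equal(tabulated_index(flat, 1.07), 0.2 + 5i)

  # continuity across the real metal table's knots
  ag <- jc_metal("Ag")$model
  for (knot in ag$lambda_um[2:(length(ag$lambda_um) - 1)]) {
    lo <- tabulated_index(ag, knot - 1e-6)
    hi <- tabulated_index(ag, knot + 1e-6)
    expect_lt(Mod(hi - lo), 1e-3)
  }

  expect_error(tabulated_index(toy, 1.2, name = "toy"), "toy")
  expect_error(tabulated_nk(c(1.1, 1.0), c(1, 1), c(0, 0)), "increasing")
  expect_error(tabulated_nk(c(1.0, 1.1), c(1, 1), c(0, -0.1)), "passive")
})

test_that("permittivity follows the exp(-i omega t) passivity convention", {
  expect_equal(permittivity(material("x", constant_index(1.5)), 0.8),
               2.25 + 0i)
  expect_equal(permittivity(material("y", constant_index(0.1, 6)), 0.8),
               -35.99 + 1.2i, tolerance = 1e-12)
  tio2 <- material("TiO2", cauchy_model(2.39513, 0.03471, -0.00835))
  expect_equal(Re(permittivity(tio2, 1)), 5.8636, tolerance = 1e-4)

  grid <- seq(0.6, 1.3, by = 0.01)
  for (m in c("Ag", "Au", "Cu")) {
    eps <- permittivity(jc_metal(m), grid)
    expect_true(all(Im(eps) >= 0))
  }
})

test_that("material library files round-trip through the structured format", {
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "metal.tsv")
  writeLines(c("# provenance: toy-metal", "0.6\t0.1\t4.0", "1.4\t0.2\t8.0"),
             tab)
  lib_file <- file.path(dir, "materials.yml")
  yaml::write_yaml(list(
    hi = list(cauchy = c(2.1, 0.02, -0.001)),
    mirror = list(table = "metal.tsv"),
    medium = list(constant = c(1.33, 0))
  ), lib_file)

  lib <- read_material_library(lib_file)
  expect_named(lib, c("hi", "mirror", "medium"))
  expect_equal(Re(material_index(lib$hi, 1)), 2.1 + 0.02 - 0.001)
  expect_equal(lib$mirror$model$provenance, "toy-metal")
  expect_equal(material_index(lib$mirror, 1.0), 0.15 + 6i, tolerance = 1e-12)
  expect_equal(material_index(lib$medium, 0.9), 1.33 + 0i)

  # the built-in library resolves every sensor material
  full <- material_library()
  expect_true(all(c("TiO2", "SiO2", "Ag", "Au", "Cu", "glass", "air") %in%
                    names(full)))
})
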