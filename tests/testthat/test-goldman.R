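test_that("wall-correction factors reach the unbounded limits at large gap", {
  fac <- wall_correction_factors(49, resolution = "coarse")
  expect_equal(fac$Fstar, 1, tolerance = 0.03)
  expect_equal(fac$Tstar, 1, tolerance = 0.03)
  expect_equal(fac$u_ratio, 1, tolerance = 0.03)
  expect_equal(fac$w_ratio, 0.5, tolerance = 0.03)
  expect_error(wall_correction_factors(-0.1), "contact")
})

test_that("near contact the factors plateau at the lubrication values", {
  # self-computed contact plateau: F* -> ~1.70, T* -> ~0.94
  fac <- wall_correction_factors(c(0.02, 0.0138), resolution = "medium")
  expect_equal(fac$Fstar, c(1.70, 1.70), tolerance = 0.015)
  expect_equal(fac$Tstar, c(0.94, 0.94), tolerance = 0.015)
  # factors vary slowly (plateau): less than 1% between the two gaps
  expect_lt(abs(diff(fac$Fstar)) / fac$Fstar[1], 0.01)
})

test_that("stationary loads scale linearly with shear rate", {
  g1 <- goldman_stationary(11.1, 5e-6, 0.069e-6, 9e-4, resolution = "coarse")
  g2 <- goldman_stationary(22.2, 5e-6, 0.069e-6, 9e-4, resolution = "coarse")
  expect_equal(g2$Fx_pN, 2 * g1$Fx_pN, tolerance = 1e-10)
  expect_equal(g2$Tz_pNum, 2 * g1$Tz_pNum, tolerance = 1e-10)
  expect_error(goldman_stationary(11.1, 5e-6, 0, 9e-4), "contact")
})

test_that("free rotation far from the wall approaches half the shear rate", {
  fm <- goldman_free_motion(1.32, 6e-6, 60 * 6e-6, 0.001,
                            resolution = "coarse")
  expect_equal(fm$omega_rad_s, 0.66, tolerance = 0.02)
})

test_that("factor tables round-trip through disk and interpolate", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "factors.txt")
  tab <- goldman_factor_table(eps = c(0.01, 0.05, 0.3, 2, 20),
                              resolution = "coarse", file = f)
  back <- read_goldman_table(f)
  expect_equal(back$Fstar, tab$Fstar, tolerance = 1e-6)
  # tabulated evaluation agrees with direct solves at a grid point...
  st_tab <- goldman_stationary(11.1, 5e-6, 0.05 * 5e-6, 9e-4, table = back)
  st_dir <- goldman_stationary(11.1, 5e-6, 0.05 * 5e-6, 9e-4,
                               resolution = "coarse")
  expect_equal(st_tab$Fx_pN, st_dir$Fx_pN, tolerance = 1e-4)
  expect_identical(st_tab$provenance, "tabulated")
  # ...and interpolates sensibly between grid points
  st_mid <- goldman_stationary(11.1, 5e-6, 0.1 * 5e-6, 9e-4, table = back)
  expect_gt(st_mid$Fx_pN, 0)
  expect_lt(abs(st_mid$Fx_pN / st_dir$Fx_pN - 1), 0.1)
})
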