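test_that("reduced domain preserves the flow area at every station", {
  dom <- reduced_domain(sphere_g1(), chan100())
  A0 <- dom$inlet_width * dom$inlet_height
  st <- dom$stations
  # default inlet cross-section is 80 x 40 um
  expect_equal(dom$inlet_width, 80e-6)
  expect_equal(dom$inlet_height, 40e-6)
  # area available to the flow equals the inlet area to 1e-3 relative
  expect_lt(max(abs(st$available_area - A0)) / A0, 1e-3)
  # outline returns to inlet dimensions at inlet and outlet
  expect_equal(st$width[1], 80e-6, tolerance = 1e-12)
  expect_equal(st$width[nrow(st)], 80e-6, tolerance = 1e-12)
  expect_equal(st$height[nrow(st)], 40e-6, tolerance = 1e-12)
  # fore/aft symmetry of the bulge
  expect_equal(st$width, rev(st$width), tolerance = 1e-12)
  # length at least 8 sphere diameters, sphere at mid-length
  expect_gte(dom$length, 8 * 10e-6)
})

test_that("the bulge outline is continuously differentiable", {
  dom <- reduced_domain(sphere_g1(), chan100(), n_stations = 2001)
  w <- dom$stations$width
  dx <- diff(dom$stations$x)[1]
  d1 <- diff(w) / dx
  # the slope has no jumps: second differences stay bounded by the curvature
  # scale (a C0 kink would blow up as the station spacing shrinks)
  d2 <- diff(d1) / dx
  curv_scale <- max(abs(w)) / (0.2e-6)^2 * 1e-3
  expect_lt(max(abs(d2)), curv_scale)
})

test_that("degenerate and invalid domains are handled", {
  # no sphere: straight duct, zero bulge
  empty <- reduced_domain(NULL, chan100())
  expect_equal(max(abs(empty$stations$width - 80e-6)), 0)
  expect_equal(max(abs(empty$stations$height - 40e-6)), 0)
  # sphere taller than the domain
  expect_error(reduced_domain(sphere_spec(10e-6, 35e-6), chan100()), "fit")
  # cross-section query matches the stored stations
  dom <- reduced_domain(sphere_g1(), chan100())
  cs <- domain_cross_section(dom, c(0, dom$length / 2))
  expect_equal(cs$width[1], max(dom$stations$width), tolerance = 1e-6)
  expect_equal(cs$width[2], 80e-6, tolerance = 1e-12)
})

test_that("VTK exports are well-formed", {
  dir <- withr::local_tempdir()
  m <- sphere_surface_mesh(sphere_g1(), n_target = 256)
  f1 <- write_vtk_surface(m, file.path(dir, "s.vtk"),
                          cell_data = list(area = m$areas))
  l1 <- readLines(f1)
  expect_equal(l1[4], "DATASET POLYDATA")
  expect_match(l1[5], sprintf("POINTS %d double", 4 * m$n))
  expect_true(any(grepl("SCALARS area", l1)))
  dom <- reduced_domain(sphere_g1(), chan100(), n_stations = 11)
  l2 <- readLines(write_vtk_domain(dom, file.path(dir, "d.vtk")))
  expect_true(any(grepl("^LINES 4 ", l2)))
})
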