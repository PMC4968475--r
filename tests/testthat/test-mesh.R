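test_that("surface meshes satisfy the closed-surface identities", {
  sp <- sphere_spec(10e-6, 1e-6)
  for (nt in c(256, 1024)) {
    m <- sphere_surface_mesh(sp, n_target = nt)
    # realized count within 20% of the request
    expect_lt(abs(m$n - nt) / nt, 0.2)
    # exact total area and vanishing vector area
    expect_equal(sum(m$areas), pi * sp$d^2, tolerance = 1e-12)
    expect_lt(max(abs(colSums(m$normals * m$areas))), 1e-9 * pi * sp$d^2)
    # centroids exactly on the sphere, normals unit and radial
    expect_equal(max(abs(sqrt(rowSums(m$centroids^2)) - sp$a)), 0,
                 tolerance = 1e-12 * sp$a)
    expect_equal(max(abs(rowSums(m$normals^2) - 1)), 0, tolerance = 1e-12)
  }
  expect_error(sphere_surface_mesh(sp, n_target = 64), "128")
})

test_that("refinement keeps the discrete area error at rounding level", {
  sp <- sphere_spec(10e-6, 0.069e-6)
  errs <- vapply(c(16, 40, 80), function(nb) {
    m <- sphere_surface_mesh(sp, nb = nb, nphi_max = 32, gap_adaptive = TRUE)
    abs(sum(m$areas) - pi * sp$d^2) / (pi * sp$d^2)
  }, 0)
  expect_true(all(errs < 1e-12))
  expect_true(all(diff(errs) <= 1e-12))  # non-increasing within rounding
})

test_that("gap-adaptive grading concentrates bands in the lubrication zone", {
  sp <- sphere_g1()
  m <- sphere_surface_mesh(sp, nb = 40, nphi_max = 24, gap_adaptive = TRUE)
  theta_gap <- sqrt(2 * sp$h / sp$a)
  n_gap <- sum(unique(m$panels[, "th1"]) < theta_gap)
  expect_gte(n_gap, 5)
  # band heights grow monotonically away from the contact point
  edges <- sort(unique(c(m$panels[, "th1"], m$panels[, "th2"])))
  expect_true(all(diff(diff(edges)) > -1e-12))
})

test_that("sphere and mesh constructors validate their inputs", {
  expect_error(sphere_spec(10e-6, 0), "positive")
  expect_error(sphere_spec(10e-6, -1e-9), "positive")
  sp <- sphere_spec(10e-6, 1e-15)
  # a gap five orders below the facet scale is refused with guidance
  expect_error(
    solve_flow(flow_problem(fluid9(), chan100(), cond_wss(0.1), sp),
               resolution = list(nb = 6L, nphi_max = 8L, near_fac = 4,
                                 max_depth = 4L, level = "tiny")),
    "raise the resolution")
})
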