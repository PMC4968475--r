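test_that("a uniform pressure on a closed surface exerts no load", {
  m <- sphere_surface_mesh(sphere_g1(), n_target = 512)
  tr <- structure(list(pressure = rep(37.5, m$n),
                       viscous = matrix(0, m$n, 3), mesh = m),
                  class = "traction_field")
  ft <- integrate_force_torque(tr)
  expect_lt(max(abs(ft$F)), 1e-12 * 37.5 * pi * m$sphere$d^2)
  expect_equal(max(abs(ft$T)), 0, tolerance = 1e-30)
})

test_that("quiescent fluid produces vanishing tractions", {
  pr0 <- flow_problem(fluid9(), chan100(),
                      flow_conditions(wss = 0, fluid = fluid9()), sphere_g1())
  tr <- surface_tractions(solve_flow(pr0, resolution = "coarse"))
  expect_equal(max(abs(tr$pressure)), 0, tolerance = 1e-20)
  expect_equal(max(abs(tr$viscous)), 0, tolerance = 1e-20)
})

test_that("viscous tractions are linear in the viscosity", {
  # same kinematics (fixed shear rate), doubled viscosity
  fl1 <- fluid_properties(mu = 0.0009); fl2 <- fluid_properties(mu = 0.0018)
  mk <- function(fl) flow_problem(fl, chan100(),
                                  flow_conditions(shear_rate = 11.1,
                                                  profile = "linear",
                                                  fluid = fl), sphere_g1())
  t1 <- surface_tractions(solve_flow(mk(fl1), resolution = "coarse"))
  t2 <- surface_tractions(solve_flow(mk(fl2), resolution = "coarse"))
  expect_equal(t2$viscous, 2 * t1$viscous, tolerance = 1e-9)
  expect_equal(t2$pressure, 2 * t1$pressure, tolerance = 1e-9)
})

test_that("force/torque integration is consistent and symmetric", {
  sol <- solve_flow(problem_g1("parabolic"), resolution = "medium")
  ft <- force_torque(sol)
  # traction-sum route vs exact single-layer integral
  expect_lt(ft$route_discrepancy_rel, 0.005)
  # pressure contributes no torque about the centre (radial normals)
  expect_lt(max(abs(ft$T_pressure)), 1e-6 * abs(ft$T[3]))
  # spanwise/wall-normal force and streamwise/vertical torque are symmetry
  # residuals below 1% of the leading components
  expect_lt(max(ft$off_axis$F_rel), 0.01)
  expect_lt(max(ft$off_axis$T_rel), 0.01)
  # a mesh that no longer closes the surface is rejected
  tr <- surface_tractions(sol)
  tr$mesh$areas <- tr$mesh$areas * 0.99
  expect_error(integrate_force_torque(tr), "closed")
})
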