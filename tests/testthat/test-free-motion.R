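test_that("the resistance matrix is reciprocal and dissipative", {
  rm_ <- resistance_matrix(problem_g1(), resolution = "medium")
  # drag opposes motion
  expect_lt(rm_$R["Fx", "u"], 0)
  expect_lt(rm_$R["Tz", "omega"], 0)
  # Lorentz reciprocity of the couplings within 2%
  expect_lt(rm_$symmetry_rel, 0.02)
  # zero ambient flow: no loading on the held sphere
  pr0 <- flow_problem(fluid9(), chan100(),
                      flow_conditions(wss = 0, fluid = fluid9()), sphere_g1())
  rm0 <- resistance_matrix(pr0, resolution = "medium")
  expect_equal(rm0$F0, 0, tolerance = 1e-30)
  expect_equal(rm0$T0, 0, tolerance = 1e-40)
  # superposition is refused when the convective term is requested
  expect_error(resistance_matrix(problem_g1(include_convective = TRUE)),
               "quasi_static")
})

test_that("far from the wall the resistances reach the unbounded limits", {
  pr <- problem_far("linear")
  rm_ <- resistance_matrix(pr, resolution = "coarse", confinement = "none")
  mu <- pr$fluid$mu; a <- pr$sphere$a
  expect_lt(abs(rm_$R["Fx", "u"] + 6 * pi * mu * a) / (6 * pi * mu * a), 0.05)
  expect_lt(abs(rm_$R["Tz", "omega"] + 8 * pi * mu * a^3) /
              (8 * pi * mu * a^3), 0.05)
  # couplings vanish relative to the geometric mean of the diagonals
  cscale <- sqrt(abs(rm_$R["Fx", "u"] * rm_$R["Tz", "omega"]))
  expect_lt(abs(rm_$R["Fx", "omega"]) / cscale, 0.05)
})

test_that("free motion in unbounded shear reaches the classical limits", {
  pr <- problem_far("linear", shear_rate = 2)
  fm <- solve_free_motion(pr, resolution = "coarse", confinement = "none")
  # omega -> shear_rate / 2, u -> ambient velocity at the centre height
  expect_equal(fm$omega_rad_s, 1, tolerance = 0.02)
  expect_equal(fm$u_um_s, 2 * pr$sphere$yc * 1e6, tolerance = 0.02)
})

test_that("free motion balances force and torque", {
  fm <- solve_free_motion(problem_g1(), resolution = "medium")
  expect_lt(fm$residual_rel, 0.005)
  expect_true(fm$within_tol)
  expect_gt(fm$u_um_s, 0)
  expect_gt(fm$omega_rad_s, 0)
  # near the wall the sphere lags the ambient and rotates below gamma/2
  g <- problem_g1()$conditions$shear_rate
  expect_lt(fm$omega_rad_s, g / 2)
  u_amb <- ambient_velocity_x <- g * sphere_g1()$yc  # linear bound
  expect_lt(fm$u_um_s, u_amb * 1e6)
})

test_that("quasi-static iteration reproduces the superposition solution", {
  fm <- solve_free_motion(problem_g1(), resolution = "coarse")
  qs <- quasi_static_iterate(problem_g1(), resolution = "coarse")
  expect_equal(qs$u_um_s, fm$u_um_s, tolerance = 0.005)
  expect_equal(qs$omega_rad_s, fm$omega_rad_s, tolerance = 0.005)
  # converges in of order twenty damped steps from rest
  expect_lte(qs$steps, 30)
  expect_equal(nrow(qs$trace), qs$steps)
  # starting at the solution: converges immediately with a near-zero update
  qs0 <- quasi_static_iterate(problem_g1(), resolution = "coarse",
                              u0 = fm$u, omega0 = fm$omega)
  expect_lte(qs0$steps, 2)
  expect_equal(qs0$u_um_s, fm$u_um_s, tolerance = 1e-6)
})
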