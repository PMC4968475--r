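ws <- asNamespace("wallstokes")

test_that("the wall Green's function vanishes on the wall and is symmetric", {
  sources <- list(c(2e-6, 5e-6, -1e-6), c(-4e-6, 0.5e-6, 3e-6),
                  c(0, 12e-6, 0))
  wallpts <- list(c(1e-6, 0, 1e-6), c(-8e-6, 0, 0), c(15e-6, 0, -6e-6))
  for (y0 in sources) for (x in wallpts) {
    G <- ws$.bem_kernel(x, y0, 9e-4, TRUE, -1)
    scale <- 1 / (8 * pi * 9e-4 * sqrt(sum((x - y0)^2)))
    expect_lt(max(abs(G)) / scale, 1e-12)
  }
  x <- c(3e-6, 4e-6, -2e-6); y0 <- c(-1e-6, 7e-6, 2e-6)
  G1 <- ws$.bem_kernel(x, y0, 9e-4, TRUE, -1)
  G2 <- ws$.bem_kernel(y0, x, 9e-4, TRUE, -1)
  expect_lt(max(abs(G1 - t(G2))) / max(abs(G1)), 1e-12)
})

test_that("an empty channel reproduces the analytic inlet profile", {
  fl <- fluid9(); ch <- chan100()
  pr <- flow_problem(fl, ch, cond_wss(0.1, "parabolic"), sphere = NULL)
  sol <- solve_flow(pr)
  y <- c(1e-6, 5e-6, 20e-6, 50e-6, 90e-6)
  u <- evaluate_velocity(sol, cbind(0, y, 0))
  expect_equal(u[, 1], inlet_velocity(y - ch$H, pr$conditions, fl, ch),
               tolerance = 1e-12)
  expect_equal(max(abs(u[, 2:3])), 0)
})

test_that("far from the wall the drag matches the unbounded Stokes value", {
  pr <- problem_far("linear")
  sol <- solve_flow(pr, resolution = "coarse", confinement = "none",
                    conf_height = NULL)
  ft <- force_torque(sol)
  mu <- pr$fluid$mu; a <- pr$sphere$a
  # Stokes drag on a held sphere equals 6 pi mu a times the local ambient
  # velocity (uniform-flow limit of the far-field configuration)
  F_ref <- 6 * pi * mu * a * pr$conditions$shear_rate * pr$sphere$yc
  expect_lt(abs(ft$F[1] - F_ref) / F_ref, 0.05)
  # fixed sphere in shear: torque 4 pi mu a^3 shear_rate (within 5%)
  T_ref <- 4 * pi * mu * a^3 * pr$conditions$shear_rate
  expect_lt(abs(ft$Tz_pNum * 1e-18 - T_ref) / T_ref, 0.05)
})

test_that("mass is conserved to quadrature accuracy", {
  sol <- solve_flow(problem_g1("parabolic"), resolution = "coarse")
  mc <- check_mass_conservation(sol)
  expect_lt(mc$net_box_flux_rel, 1e-6)
  expect_lt(mc$sphere_flux_rel, 1e-10)
  expect_false(mc$flagged)
  # zero-inflow problem: identically zero field
  pr0 <- flow_problem(fluid9(), chan100(),
                      flow_conditions(wss = 0, fluid = fluid9()), sphere_g1())
  sol0 <- solve_flow(pr0, resolution = "coarse")
  u0 <- evaluate_velocity(sol0, cbind(c(0, 2e-5), c(8e-6, 1e-5), 0))
  expect_equal(max(abs(u0)), 0, tolerance = 1e-25)
})

test_that("solutions scale linearly with wall shear stress", {
  ft1 <- force_torque(solve_flow(problem_g1(wss_dyn = 0.5),
                                 resolution = "coarse"))
  ft2 <- force_torque(solve_flow(problem_g1(wss_dyn = 2.5),
                                 resolution = "coarse"))
  expect_equal(ft2$Fx_pN, 5 * ft1$Fx_pN, tolerance = 1e-10)
  expect_equal(ft2$Tz_pNum, 5 * ft1$Tz_pNum, tolerance = 1e-10)
  fm1 <- solve_free_motion(problem_g1(wss_dyn = 0.5), resolution = "coarse")
  fm2 <- solve_free_motion(problem_g1(wss_dyn = 2.5), resolution = "coarse")
  expect_equal(fm2$u_um_s, 5 * fm1$u_um_s, tolerance = 1e-10)
  expect_equal(fm2$omega_rad_s, 5 * fm1$omega_rad_s, tolerance = 1e-10)
})

test_that("the direct solve leaves a machine-level linear-system residual", {
  sol <- solve_flow(problem_g1(), resolution = "coarse")
  expect_lt(sol$metadata$residual, 1e-10)
})

test_that("the convective-term contribution is negligible at WSS = 5", {
  sol <- solve_flow(problem_g1(wss_dyn = 5), resolution = "coarse")
  cc <- convective_correction(sol)
  expect_lt(cc$dF_rel, 0.02)
  expect_lt(cc$dT_rel, 0.02)
  # outside the validated regime the solver warns
  fl <- fluid9()
  fast <- flow_conditions(shear_rate = 2e5, fluid = fl)
  expect_warning(
    solve_flow(flow_problem(fl, chan100(), fast, sphere_g1(),
                            include_convective = TRUE),
               resolution = "coarse"),
    "Reynolds")
})
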