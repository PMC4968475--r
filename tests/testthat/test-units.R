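test_that("wall shear stress converts to shear rate and back exactly", {
  fl <- fluid9()
  # 0.1 dyn cm^-2 = 0.01 Pa at mu = 0.0009 gives 11.1 s^-1
  g <- wss_to_shear_rate(dyn_cm2_to_pa(0.1), fl)
  expect_equal(g, 0.01 / 0.0009, tolerance = 1e-12)
  expect_equal(round(g, 1), 11.1)
  expect_identical(wss_to_shear_rate(0, fl), 0)
  # 10x stress -> 10x rate (linearity of the definition)
  expect_equal(wss_to_shear_rate(dyn_cm2_to_pa(1.0), fl), 10 * g,
               tolerance = 1e-12)
  # exact round trip
  for (wss in c(0.01, 0.05, 0.5)) {
    expect_equal(shear_rate_to_wss(wss_to_shear_rate(wss, fl), fl), wss,
                 tolerance = 1e-12)
  }
  expect_error(fluid_properties(mu = -1), "viscosity")
})

test_that("inlet profiles satisfy the wall conditions and Poiseuille flux", {
  fl <- fluid9(); ch <- chan100()
  par <- cond_wss(0.1, "parabolic")
  lin <- cond_wss(0.1, "linear")
  H <- ch$H
  # no-slip at the lower wall
  expect_equal(inlet_velocity(-H, par, fl, ch), 0)
  expect_equal(inlet_velocity(-H, lin, fl, ch), 0)
  expect_equal(inlet_velocity(H, par, fl, ch), 0, tolerance = 1e-20)
  # centreline velocity WSS*H/(2 mu) = 277.8 um/s
  expect_equal(inlet_velocity(0, par, fl, ch),
               dyn_cm2_to_pa(0.1) * H / (2 * fl$mu), tolerance = 1e-12)
  expect_equal(inlet_velocity(0, par, fl, ch) * 1e6, 277.8, tolerance = 1e-3)
  # both profiles produce the same wall shear stress at Y = -H
  dy <- 1e-10
  g_par <- (inlet_velocity(-H + dy, par, fl, ch) - 0) / dy
  g_lin <- (inlet_velocity(-H + dy, lin, fl, ch) - 0) / dy
  expect_equal(fl$mu * g_par, dyn_cm2_to_pa(0.1), tolerance = 1e-5)
  expect_equal(fl$mu * g_lin, dyn_cm2_to_pa(0.1), tolerance = 1e-8)
  # parabolic profile integrates to the analytic Poiseuille flux
  flux <- integrate(function(y) inlet_velocity(y, par, fl, ch), -H, H,
                    rel.tol = 1e-10)$value
  vmax <- inlet_velocity(0, par, fl, ch)
  expect_equal(flux, (2 / 3) * vmax * 2 * H, tolerance = 1e-8)
  # domain errors
  expect_error(inlet_velocity(1.1 * H, par, fl, ch), "outside")
  expect_error(inlet_velocity(-1.1 * H, lin, fl, ch), "below")
})

test_that("particle shear Reynolds number is small across the study range", {
  fl <- fluid9()
  re <- reynolds_number(cond_wss(0.1), fl, 10e-6)
  expect_equal(as.numeric(re), (0.01 / 0.0009) * (1e-5)^2 / fl$nu,
               tolerance = 1e-12)
  expect_equal(as.numeric(re), 1.23e-3, tolerance = 0.01)
  expect_equal(as.numeric(reynolds_number(
    flow_conditions(wss = 0, fluid = fl), fl, 10e-6)), 0)
  # linear in shear rate, and below 1 over the full WSS range
  re50 <- reynolds_number(cond_wss(5.0), fl, 10e-6)
  expect_equal(as.numeric(re50), 50 * as.numeric(re), tolerance = 1e-12)
  expect_lt(as.numeric(re50), 1)
})
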