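test_that("sweeps are validated, ordered and deterministic", {
  expect_error(run_sweep(transform(case_preset("table1_caseA"),
                                   mode = "wobbly")), "mode")
  cases <- rbind(case_preset("table1_caseC"),
                 transform(case_preset("table1_caseC"), wss_dyn_cm2 = 1.0,
                           case = "caseC_wss1"))
  r1 <- run_sweep(cases, resolution = "coarse")
  r2 <- run_sweep(cases, resolution = "coarse")
  expect_identical(r1, r2)                        # bit-identical rerun
  expect_identical(r1$case, cases$case)           # input order preserved
  # linearity across the sweep: 10x WSS, 10x force
  expect_equal(r1$Fx_pN[2], 10 * r1$Fx_pN[1], tolerance = 1e-9)
  # CSV writing round-trips
  dir <- withr::local_tempdir()
  run_sweep(cases, out_dir = dir, resolution = "coarse")
  back <- utils::read.csv(file.path(dir, "sweep_results.csv"))
  expect_equal(back$Fx_pN, r1$Fx_pN, tolerance = 1e-9)
})

test_that("a failing case is recorded without stopping the sweep", {
  cases <- rbind(case_preset("table1_caseA"),
                 transform(case_preset("table1_caseA"), h_um = -1,
                           case = "bad_gap"))
  res <- run_sweep(cases, resolution = "coarse")
  expect_identical(res$status[1], "ok")
  expect_match(res$status[2], "error")
  expect_true(is.na(res$Fx_pN[2]))
})

test_that("the comparison report covers the benchmark cases", {
  rep <- reproduce_benchmark_tables(resolution = "coarse")
  expect_true(all(c("table1_caseA", "table1_caseB", "table1_caseC",
                    "tissot_cfd", "tissot_goldman") %in% rep$case))
  expect_true(all(is.finite(rep$computed)))
  expect_true(all(is.finite(rep$deviation_pct)))
  # the linear-vs-parabolic deviation and rotation-rate ratio lines exist
  expect_true("linear_vs_parabolic_force_dev_pct" %in% rep$quantity)
  expect_true("omega_ratio_cfd_goldman" %in% rep$quantity)
})

test_that("case configurations are read from flat key-value files", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "case.yaml")
  writeLines(c("fluid.mu_Pa_s: 0.0009", "fluid.rho: 1000",
               "channel.height_um: 100", "flow.wss_dyn_cm2: 0.1",
               "flow.profile: parabolic", "sphere.d_um: 10",
               "sphere.h_um: 0.069", "solver.resolution: coarse"), f)
  cf <- read_case_config(f)
  expect_s3_class(cf$problem, "flow_problem")
  expect_equal(cf$problem$conditions$shear_rate, 0.01 / 0.0009,
               tolerance = 1e-12)
  expect_identical(cf$resolution, "coarse")
})
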