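cfg_small <- function(...) video_config(width_px = 160, height_px = 80, ...)

test_that("a static particle renders identical frames up to noise", {
  cfg <- cfg_small(noise_sd = 0.01)
  st <- render_janus_video(cfg, u_um_s = 0, omega_rad_s = 0, seed = 1,
                           duration_s = 1)
  d <- st[[1]] - st[[length(st)]]
  expect_lt(max(abs(d)), 8 * cfg$noise_sd)
  expect_lt(abs(mean(d)), cfg$noise_sd)
})

test_that("the projected-area signal has the constructed periodicity", {
  # omega chosen so one revolution is exactly 12 frames
  cfg <- cfg_small(noise_sd = 0)
  omega <- 2 * pi * 25 / 12
  st <- render_janus_video(cfg, u_um_s = 0, omega_rad_s = omega, seed = 1,
                           duration_s = 48 / 25)
  tr <- track_particles(st, cfg)
  expect_length(tr, 1)
  A <- tr[[1]]$area_px2
  expect_equal(A[1:36], A[13:48], tolerance = 1e-12)   # period 12 frames
  # one cycle per revolution: exactly one upward midline crossing per period
  mid <- (max(A) + min(A)) / 2
  ups <- sum(A[-1] > mid & A[-length(A)] <= mid)
  expect_equal(ups, length(A) / 12)
  # and the crossing-counting estimator recovers the constructed rate
  rot <- rotation_from_area(tr[[1]], cfg)
  expect_equal(rot$omega_rad_s, omega, tolerance = 0.01)
  # the rendered minimum stays above the 5 um size gate
  expect_gt(min(tr[[1]]$diameter_um), 5)
})

test_that("rotation rates violating the Nyquist bound are refused", {
  expect_error(render_janus_video(cfg_small(), 10, pi * 25), "Nyquist")
})

test_that("ground truth is recovered and scales with the true rotation", {
  cfg <- video_config()
  st1 <- render_janus_video(cfg, u_um_s = 35, omega_rad_s = 2.5, seed = 4,
                            duration_s = 10)
  st2 <- render_janus_video(cfg, u_um_s = 35, omega_rad_s = 5.0, seed = 4,
                            duration_s = 10)
  m1 <- measure_video(st1); m2 <- measure_video(st2)
  expect_equal(m1$u_um_s[1], 35, tolerance = 0.02)
  expect_equal(m1$omega_rad_s[1], 2.5, tolerance = 0.05)
  # doubling the true rotation doubles the estimate
  expect_equal(m2$omega_rad_s[1] / m1$omega_rad_s[1], 2, tolerance = 0.07)
})

test_that("rotation is invariant to intensity scaling and translation", {
  cfg <- video_config()
  st <- render_janus_video(cfg, u_um_s = 30, omega_rad_s = 5, seed = 7,
                           duration_s = 8)
  w0 <- measure_video(st)$omega_rad_s[1]
  # uniform intensity scaling (threshold scaled accordingly)
  st_scaled <- structure(lapply(st, function(f) 1.8 * f),
                         class = "janus_stack", cfg = cfg)
  thr <- 1.8 * (cfg$bg + 0.25 * (cfg$fg - cfg$bg))
  w1 <- measure_video(st_scaled, cfg, threshold = thr)$omega_rad_s[1]
  expect_equal(w1, w0, tolerance = 1e-8)
  # a stationary copy of the same rotation gives the same estimate
  st_still <- render_janus_video(cfg, u_um_s = 0, omega_rad_s = 5, seed = 7,
                                 duration_s = 8)
  w2 <- measure_video(st_still)$omega_rad_s[1]
  expect_equal(w2, 5, tolerance = 0.05)
})

test_that("small particles are gated out and distant particles stay distinct", {
  cfg <- video_config()
  st4 <- render_janus_video(cfg, u_um_s = 30, omega_rad_s = 0, seed = 1,
                            duration_s = 3, plain_spheres = TRUE,
                            diameters_um = 4)
  expect_length(track_particles(st4, cfg), 0)
  # two well-separated particles: two tracks, no identity swap
  st2 <- render_janus_video(cfg, u_um_s = 30, omega_rad_s = 5, seed = 2,
                            duration_s = 6, n_particles = 2)
  tr <- track_particles(st2, cfg)
  expect_length(tr, 2)
  # tracks never cross in the spanwise coordinate (layout keeps them apart)
  z1 <- range(tr[[1]]$y_px); z2 <- range(tr[[2]]$y_px)
  expect_true(z1[2] < z2[1] || z2[2] < z1[1])
})

test_that("association enforces the divergence-angle constraint", {
  cfg <- cfg_small()
  st <- blank_stack(6, cfg)
  r_px <- 5 / cfg$pixel_pitch_um
  # straight downstream motion for three frames, then a 45-degree drift whose
  # step length stays within the displacement gate
  pos <- rbind(c(30, 30), c(33, 30), c(36, 30),
               c(37.5, 31.5), c(39, 33), c(40.5, 34.5))
  for (f in 1:6) st[[f]] <- paint_disc(st[[f]], pos[f, 1], pos[f, 2], r_px)
  tr <- track_particles(st, cfg, min_track_frames = 2, lookahead = 1)
  # the 45-degree continuation violates the 15-degree gate: the track stops
  expect_lte(max(tr[[1]]$frame), 3)
  # with a permissive angle gate the same stack yields one unbroken track
  tr2 <- track_particles(st, cfg, min_track_frames = 2, lookahead = 1,
                         max_angle_deg = 60)
  expect_length(tr2, 1)
  expect_equal(nrow(tr2[[1]]), 6)
})

test_that("aperiodic signals yield a no-estimate flag", {
  cfg <- video_config()
  st <- render_janus_video(cfg, u_um_s = 30, omega_rad_s = 0, seed = 1,
                           duration_s = 6, plain_spheres = TRUE)
  m <- measure_video(st)
  expect_identical(m$flag[1], "no_estimate")
  expect_true(is.na(m$omega_rad_s[1]))
})
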