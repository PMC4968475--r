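# Shared fixtures.  Solver results are memoised inside the package's
# geometry cache, so repeated calls across test files reuse factorizations.

fluid9 <- function() fluid_properties(mu = 0.0009, rho = 1000)
chan100 <- function() channel_spec(height = 100e-6)

# benchmark sphere: 10 um diameter, 0.069 um gap
sphere_g1 <- function() sphere_spec(10e-6, 0.069e-6)

cond_wss <- function(wss_dyn = 0.1, profile = "parabolic",
                     fluid = fluid9()) {
  flow_conditions(wss = dyn_cm2_to_pa(wss_dyn), profile = profile,
                  fluid = fluid)
}

problem_g1 <- function(profile = "parabolic", wss_dyn = 0.1, ...) {
  flow_problem(fluid9(), chan100(), cond_wss(wss_dyn, profile),
               sphere_g1(), ...)
}

# far-field configuration: sphere 49 radii from the wall
problem_far <- function(profile = "linear", shear_rate = 1) {
  fl <- fluid9()
  sp <- sphere_spec(10e-6, 49 * 5e-6)
  ch <- channel_spec(height = 2e-3)
  co <- flow_conditions(shear_rate = shear_rate, profile = profile,
                        fluid = fl)
  flow_problem(fl, ch, co, sp)
}

# lymphocyte benchmark: d = 12 um, h = 1.4 um, mu = 0.001, shear 1.32 /s
problem_tissot <- function(profile = "parabolic") {
  fl <- fluid_properties(mu = 0.001, rho = 1000)
  co <- flow_conditions(shear_rate = 1.32, profile = profile, fluid = fl)
  flow_problem(fl, chan100(), co, sphere_spec(12e-6, 1.4e-6))
}

# paint a plain fluorescent disc into a frame matrix (for constructed
# tracking cases that the renderer cannot produce, e.g. diagonal motion)
paint_disc <- function(img, cx_px, cz_px, radius_px, fg = 0.85) {
  H <- nrow(img); W <- ncol(img)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if ((c - cx_px)^2 + (r - cz_px)^2 <= radius_px^2) img[r, c] <- fg
  }
  img
}

blank_stack <- function(n, cfg) {
  frames <- replicate(n, matrix(cfg$bg, cfg$height_px, cfg$width_px),
                      simplify = FALSE)
  structure(frames, class = "janus_stack", cfg = cfg)
}
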