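# Reduced computational domain: an 80 x 40 um duct around the sphere whose
# side and upper boundaries bulge outward so that the cross-sectional area
# available to the flow (outline minus sphere cross-section) stays equal to
# the inlet area at every streamwise station.  This is the geometric device
# that removes blockage from a truncated domain and licenses inviscid
# (impenetrable free-slip) far boundaries; in the boundary-element solver the
# same role is played by the open exterior plus the optional free-slip
# reflection at the duct height.

#' Construct the reduced computational domain
#'
#' Builds the bulged reduced domain around the sphere.  The outline is scaled
#' isotropically at each station so that outline area minus the sphere's
#' cross-section equals the inlet area; the bulge amplitude is taken from the
#' area constraint exactly under the sphere and tapered to zero with a C1
#' cubic Hermite blend over a short window at the sphere's edges, so the
#' outline is continuously differentiable, fore/aft symmetric, and returns to
#' the inlet dimensions at the outlet.
#'
#' @param sphere A [sphere_spec()], or `NULL` for an empty (straight) duct.
#' @param channel A [channel_spec()] (used for validation only).
#' @param inlet_width,inlet_height Inlet cross-section (default 80 x 40 um).
#' @param length Domain length; default 8 sphere diameters (minimum enforced),
#'   sphere at mid-length.
#' @param n_stations Number of streamwise stations describing the outline.
#' @param blend_width Half-width of the C1 taper at the bulge edges (m).
#' @return An object of class `reduced_domain` with a `stations` data frame
#'   (x, width, height, outline area, sphere cross-section, available area).
#' @export
#' @examples
#' dom <- reduced_domain(sphere_spec(10e-6, 0.069e-6), channel_spec())
#' range(dom$stations$available_area) / (80e-6 * 40e-6) # -> 1 within 1e-3
reduced_domain <- function(sphere, channel = channel_spec(),
                           inlet_width = 80e-6, inlet_height = 40e-6,
                           length = NULL, n_stations = 201,
                           blend_width = 0.2e-6) {
  d <- if (is.null(sphere)) 0 else sphere$d
  a <- d / 2
  if (!is.null(sphere)) {
    stopifnot(inherits(sphere, "sphere_spec"))
    if (sphere$yc + a >= inlet_height)
      stop("sphere does not fit inside the reduced domain height")
    if (d >= inlet_width) stop("sphere wider than the domain")
  }
  if (is.null(length)) length <- max(8 * d, 8e-6)
  if (d > 0 && length < 8 * d)
    stop("domain length must be at least 8 sphere diameters")
  x <- seq(-length / 2, length / 2, length.out = n_stations)

  # added outline area: exact sphere cross-section inboard, C1 taper at edges
  added_area <- function(x) {
    ax <- abs(x)
    out <- numeric(base::length(x))
    if (a <= 0) return(out)
    del <- min(blend_width, a / 4)
    core <- ax <= a - del
    out[core] <- pi * (a^2 - ax[core]^2)
    bl <- ax > a - del & ax < a + del
    if (any(bl)) {
      t <- (ax[bl] - (a - del)) / (2 * del)
      v0 <- pi * (a^2 - (a - del)^2)
      s0 <- -2 * pi * (a - del)             # d(area)/d|x| at the join
      h00 <- 2 * t^3 - 3 * t^2 + 1
      h10 <- t^3 - 2 * t^2 + t
      out[bl] <- pmax(0, h00 * v0 + h10 * (2 * del) * s0)
    }
    out
  }
  A0 <- inlet_width * inlet_height
  Aadd <- added_area(x)
  s <- sqrt(1 + Aadd / A0)
  Asph <- if (a > 0) pi * pmax(0, a^2 - x^2) else numeric(base::length(x))
  stations <- data.frame(x = x,
                         width = inlet_width * s,
                         height = inlet_height * s,
                         outline_area = A0 * s^2,
                         sphere_area = Asph,
                         available_area = A0 * s^2 - Asph)
  structure(list(stations = stations, inlet_width = inlet_width,
                 inlet_height = inlet_height, length = length,
                 sphere = sphere, blend_width = blend_width,
                 added_area_fun = added_area),
            class = "reduced_domain")
}

#' Cross-section of the reduced domain at a station
#'
#' @param domain A [reduced_domain()].
#' @param x Streamwise station(s) in metres.
#' @return Data frame with width, height, outline and available areas at `x`.
#' @export
domain_cross_section <- function(domain, x) {
  stopifnot(inherits(domain, "reduced_domain"))
  A0 <- domain$inlet_width * domain$inlet_height
  s <- sqrt(1 + domain$added_area_fun(x) / A0)
  a <- if (is.null(domain$sphere)) 0 else domain$sphere$a
  Asph <- if (a > 0) pi * pmax(0, a^2 - x^2) else numeric(length(x))
  data.frame(x = x, width = domain$inlet_width * s,
             height = domain$inlet_height * s,
             outline_area = A0 * s^2, available_area = A0 * s^2 - Asph)
}

#' Sensitivity of the solution to the domain truncation
#'
#' Recomputes the stationary force and torque with the free-slip truncation
#' plane at the nominal domain height and at twice that height (and with no
#' truncation at all) and reports the relative changes -- the domain-doubling
#' check used to justify the reduced domain.
#'
#' @param problem A [flow_problem()].
#' @param resolution Solver resolution.
#' @param conf_height Nominal truncation height (m).
#' @return Data frame with force/torque at each height and relative changes.
#' @export
domain_truncation_sensitivity <- function(problem, resolution = "coarse",
                                          conf_height = 40e-6) {
  f1 <- force_torque(solve_flow(problem, resolution = resolution,
                                confinement = "upper_freeslip",
                                conf_height = conf_height))
  f2 <- force_torque(solve_flow(problem, resolution = resolution,
                                confinement = "upper_freeslip",
                                conf_height = 2 * conf_height))
  f3 <- force_torque(solve_flow(problem, resolution = resolution,
                                confinement = "none"))
  data.frame(height_um = c(conf_height, 2 * conf_height, Inf) * 1e6,
             Fx_pN = c(f1$Fx_pN, f2$Fx_pN, f3$Fx_pN),
             Tz_pNum = c(f1$Tz_pNum, f2$Tz_pNum, f3$Tz_pNum),
             dF_rel = c(NA, abs(f2$Fx_pN - f1$Fx_pN) / abs(f1$Fx_pN),
                        abs(f3$Fx_pN - f1$Fx_pN) / abs(f1$Fx_pN)),
             dT_rel = c(NA, abs(f2$Tz_pNum - f1$Tz_pNum) / abs(f1$Tz_pNum),
                        abs(f3$Tz_pNum - f1$Tz_pNum) / abs(f1$Tz_pNum)))
}

#' @export
print.reduced_domain <- function(x, ...) {
  dev <- max(abs(x$stations$available_area /
                   (x$inlet_width * x$inlet_height) - 1))
  cat(sprintf(
    "reduced domain: %.0f x %.0f um inlet, length %.0f um, %d stations\n",
    x$inlet_width * 1e6, x$inlet_height * 1e6, x$length * 1e6,
    nrow(x$stations)))
  cat(sprintf("  max relative deviation of available area: %.2e\n", dev))
  invisible(x)
}
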