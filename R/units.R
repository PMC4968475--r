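#' Fluid properties
#'
#' Bundle the dynamic viscosity and density of the working fluid.  The
#' kinematic viscosity is derived as `nu = mu / rho`.  All quantities are SI:
#' the package works internally in metres, seconds and pascals and converts to
#' the conventional reporting units (dynes cm^-2, pN, pN um, um s^-1) only at
#' the reporting layer.
#'
#' @param mu Dynamic viscosity in Pa s (N s m^-2).  Aqueous buffers at room
#'   temperature are near 0.0009--0.001 Pa s.
#' @param rho Density in kg m^-3.
#' @return An object of class `fluid_properties` with fields `mu`, `rho`, `nu`.
#' @export
#' @examples
#' fluid_properties(mu = 0.0009)
fluid_properties <- function(mu = 0.0009, rho = 1000) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("invalid fluid: dynamic viscosity must be a single positive number")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("invalid fluid: density must be a single positive number")
  structure(list(mu = mu, rho = rho, nu = mu / rho),
            class = "fluid_properties")
}

#' Channel geometry
#'
#' Parallel-plate channel of full height `height` (the half-height `H` used in
#' the parabolic profile is `height / 2`).  Width and length describe the
#' physical device; the flow model only requires `height`.
#'
#' @param height Full channel height 2H in metres (default 100 um).
#' @param width,length Full channel width and length in metres (defaults match
#'   a typical 14 x 2 x 0.1 mm perfusion chamber).
#' @return An object of class `channel_spec` with `H` (half-height) derived.
#' @export
channel_spec <- function(height = 100e-6, width = 2e-3, length = 14e-3) {
  stopifnot(is.numeric(height), length(height) == 1L, height > 0,
            width > 0, length > 0)
  structure(list(height = height, H = height / 2,
                 width = width, length = length),
            class = "channel_spec")
}

#' Convert a wall shear stress in dynes cm^-2 to pascals
#'
#' 1 dyn cm^-2 = 0.1 Pa.
#' @param wss_dyn_cm2 Wall shear stress in dynes cm^-2.
#' @return Stress in Pa.
#' @export
dyn_cm2_to_pa <- function(wss_dyn_cm2) wss_dyn_cm2 * 0.1

#' Convert pascals to dynes cm^-2
#' @param wss_pa Stress in Pa.
#' @return Stress in dynes cm^-2.
#' @export
pa_to_dyn_cm2 <- function(wss_pa) wss_pa * 10

#' Wall shear stress to wall shear rate
#'
#' The wall shear stress is the viscous stress at the lower wall,
#' `WSS = mu * dVx/dY` evaluated at the wall, so the wall shear rate is
#' `WSS / mu`.
#'
#' @param wss Wall shear stress in Pa (use [dyn_cm2_to_pa()] for CGS input).
#' @param fluid A [fluid_properties()] object.
#' @return Wall shear rate in s^-1.
#' @export
#' @examples
#' wss_to_shear_rate(dyn_cm2_to_pa(0.1), fluid_properties(mu = 0.0009))
wss_to_shear_rate <- function(wss, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(wss < 0)) stop("wall shear stress must be non-negative")
  wss / fluid$mu
}

#' Wall shear rate to wall shear stress
#' @param shear_rate Wall shear rate in s^-1.
#' @param fluid A [fluid_properties()] object.
#' @return Wall shear stress in Pa.
#' @export
shear_rate_to_wss <- function(shear_rate, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(shear_rate < 0)) stop("shear rate must be non-negative")
  shear_rate * fluid$mu
}

#' Flow conditions
#'
#' Specify the ambient flow by its wall shear stress (Pa) or wall shear rate
#' (s^-1) -- one implies the other through the viscosity -- and the profile
#' kind: `"parabolic"` for fully developed plane Poiseuille flow, `"linear"`
#' for the constant-shear (Couette-like) profile classically assumed for
#' near-wall sphere hydrodynamics.  Both profiles produce the same wall shear
#' stress and wall shear rate at the lower wall.
#'
#' @param wss Wall shear stress in Pa (optional if `shear_rate` given).
#' @param shear_rate Wall shear rate in s^-1 (optional if `wss` given).
#' @param profile `"parabolic"` or `"linear"`.
#' @param fluid A [fluid_properties()] object used for the conversion.
#' @return An object of class `flow_conditions` with both `wss` and
#'   `shear_rate` populated.
#' @export
flow_conditions <- function(wss = NULL, shear_rate = NULL,
                            profile = c("parabolic", "linear"),
                            fluid = fluid_properties()) {
  profile <- match.arg(profile)
  stopifnot(inherits(fluid, "fluid_properties"))
  if (is.null(wss) && is.null(shear_rate))
    stop("supply either `wss` (Pa) or `shear_rate` (s^-1)")
  if (is.null(wss)) wss <- shear_rate_to_wss(shear_rate, fluid)
  if (is.null(shear_rate)) shear_rate <- wss_to_shear_rate(wss, fluid)
  if (abs(shear_rate * fluid$mu - wss) > 1e-9 * max(wss, 1e-30))
    stop("inconsistent wss / shear_rate pair for this fluid")
  structure(list(wss = wss, shear_rate = shear_rate, profile = profile),
            class = "flow_conditions")
}

#' Ambient (inlet) velocity profile
#'
#' Streamwise velocity at channel coordinate `Y` (origin mid-channel, wall at
#' `Y = -H`).  Parabolic: `Vx = -WSS (Y^2 - H^2) / (2 mu H)`, the fully
#' developed plane Poiseuille profile whose wall shear stress is `WSS`.
#' Linear: `Vx = (WSS/mu) (Y + H)`, the unbounded constant-shear profile with
#' the same wall shear rate.
#'
#' @param Y Channel coordinate(s) in metres; `-H <= Y <= H` for the parabolic
#'   profile, `Y >= -H` for the linear one.
#' @param cond A [flow_conditions()] object.
#' @param fluid A [fluid_properties()] object.
#' @param channel A [channel_spec()] object.
#' @return Velocity in m s^-1, same length as `Y`.
#' @export
#' @examples
#' ch <- channel_spec()
#' fl <- fluid_properties(0.0009)
#' co <- flow_conditions(wss = dyn_cm2_to_pa(0.1), profile = "parabolic",
#'                       fluid = fl)
#' inlet_velocity(0, co, fl, ch) # centreline, = WSS * H / (2 mu)
inlet_velocity <- function(Y, cond, fluid, channel) {
  stopifnot(inherits(cond, "flow_conditions"),
            inherits(fluid, "fluid_properties"),
            inherits(channel, "channel_spec"))
  H <- channel$H
  if (any(Y < -H - 1e-12 * H))
    stop("Y below the lower wall (Y < -H)")
  if (cond$profile == "parabolic") {
    if (any(Y > H + 1e-12 * H))
      stop("Y outside the channel for the parabolic profile")
    -cond$wss / (2 * fluid$mu * H) * (Y^2 - H^2)
  } else {
    cond$shear_rate * (Y + H)
  }
}

#' Particle shear Reynolds number
#'
#' `Re = shear_rate * d^2 / nu`, the shear Reynolds number on the particle
#' scale.  This definition is recorded in the returned attributes; it is the
#' quantity that must stay well below one for the Stokes (inertia-free)
#' solver mode to be the appropriate default.
#'
#' @param cond A [flow_conditions()] object.
#' @param fluid A [fluid_properties()] object.
#' @param diameter Sphere diameter in metres.
#' @return Dimensionless Reynolds number with a `definition` attribute.
#' @export
reynolds_number <- function(cond, fluid, diameter) {
  stopifnot(inherits(cond, "flow_conditions"),
            inherits(fluid, "fluid_properties"),
            diameter > 0)
  re <- cond$shear_rate * diameter^2 / fluid$nu
  attr(re, "definition") <- "shear_rate * diameter^2 / nu"
  re
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("fluid: mu = %g Pa s, rho = %g kg m^-3, nu = %g m^2 s^-1\n",
              x$mu, x$rho, x$nu))
  invisible(x)
}

#' @export
print.flow_conditions <- function(x, ...) {
  cat(sprintf("flow: WSS = %g Pa (%g dyn cm^-2), shear rate = %g s^-1, %s profile\n",
              x$wss, pa_to_dyn_cm2(x$wss), x$shear_rate, x$profile))
  invisible(x)
}
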