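# Wall-correction reference for the classical constant-shear model: a rigid
# sphere near a single plane wall in unbounded linear shear flow at zero
# Reynolds number.  Dimensionless conventions:
#   stationary:  Fx = 6 pi mu a (a + h) shear_rate * Fstar(h/a)
#                Tz = 4 pi mu a^3 shear_rate * Tstar(h/a)
#   free motion: u  = shear_rate (a + h) * u_ratio(h/a)
#                omega = shear_rate * w_ratio(h/a)
# As h/a -> infinity Fstar, Tstar -> 1, u_ratio -> 1, w_ratio -> 1/2; toward
# contact Fstar and Tstar plateau near 1.70 and 0.944 while u_ratio and
# w_ratio decay logarithmically to zero.
#
# Factors are computed by running the linear-profile solver in the unbounded
# half-space (no truncation boundary) at the requested gap ratio; they can
# also be interpolated from a table previously produced by
# goldman_factor_table() or supplied by the user.

goldman_problem <- function(shear_rate, radius, gap, mu) {
  if (gap <= 0) stop("contact singularity: gap must be positive")
  fl <- fluid_properties(mu = mu)
  # channel plays no role in linear mode but a spec is required; make it deep
  ch <- channel_spec(height = max(1e-3, 40 * radius))
  co <- flow_conditions(shear_rate = shear_rate, profile = "linear",
                        fluid = fl)
  flow_problem(fl, ch, co, sphere_spec(2 * radius, gap))
}

#' Wall-correction factors for a sphere near a plane wall in linear shear
#'
#' Computes the dimensionless stationary force/torque factors and free-motion
#' velocity ratios at gap ratio(s) `eps = h / a` by solving the unbounded
#' half-space problem with the linear-profile boundary-element solver.
#'
#' @param eps Gap ratio(s) h/a.
#' @param resolution Solver resolution (see [mesh_resolution()]).
#' @param table Optional factor table (from [goldman_factor_table()] or
#'   [read_goldman_table()]); when supplied, factors are interpolated in
#'   log(eps) instead of solved.
#' @return A data frame with columns `eps`, `Fstar`, `Tstar`, `u_ratio`,
#'   `w_ratio` and a `provenance` attribute (`"computed"` or `"tabulated"`).
#' @export
wall_correction_factors <- function(eps, resolution = "fine", table = NULL) {
  if (any(eps <= 0)) stop("contact singularity: eps must be positive")
  if (!is.null(table)) {
    need <- c("eps", "Fstar", "Tstar", "u_ratio", "w_ratio")
    stopifnot(all(need %in% names(table)))
    interp <- function(col)
      stats::approx(log(table$eps), table[[col]], xout = log(eps),
                    rule = 2)$y
    out <- data.frame(eps = eps, Fstar = interp("Fstar"),
                      Tstar = interp("Tstar"), u_ratio = interp("u_ratio"),
                      w_ratio = interp("w_ratio"))
    attr(out, "provenance") <- "tabulated"
    return(out)
  }
  a <- 5e-6; mu <- 1e-3; g <- 1  # factors are dimensionless: any scales do
  rows <- lapply(eps, function(e) {
    pr <- goldman_problem(g, a, e * a, mu)
    ft <- force_torque(solve_flow(pr, resolution = resolution,
                                  confinement = "none"))
    fm <- solve_free_motion(pr, resolution = resolution,
                            confinement = "none")
    data.frame(eps = e,
               Fstar = ft$F[1] / (6 * pi * mu * a * (a + e * a) * g),
               Tstar = -ft$T[3] / (4 * pi * mu * a^3 * g),
               u_ratio = fm$u / (g * (a + e * a)),
               w_ratio = fm$omega / g)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- "computed"
  out
}

#' Stationary force and torque from the constant-shear wall model
#'
#' Force and torque on a stationary sphere of radius `a` at gap `h` above a
#' plane wall in unbounded linear shear flow (the classical comparison
#' baseline for near-wall sphere hydrodynamics).
#'
#' @param shear_rate Wall shear rate in s^-1.
#' @param radius Sphere radius in metres.
#' @param gap Wall-to-surface gap in metres (> 0).
#' @param mu Dynamic viscosity in Pa s.
#' @param resolution Solver resolution used when factors are computed.
#' @param table Optional factor table (see [wall_correction_factors()]).
#' @return A list: `Fx_pN`, `Tz_pNum`, the factors used, and provenance.
#' @export
#' @examples
#' \donttest{
#' goldman_stationary(11.1, 5e-6, 0.069e-6, 0.0009, resolution = "coarse")
#' }
goldman_stationary <- function(shear_rate, radius, gap, mu,
                               resolution = "fine", table = NULL) {
  fac <- wall_correction_factors(gap / radius, resolution, table)
  Fx <- 6 * pi * mu * radius * (radius + gap) * shear_rate * fac$Fstar
  Tz <- 4 * pi * mu * radius^3 * shear_rate * fac$Tstar
  list(Fx_pN = Fx * 1e12, Tz_pNum = Tz * 1e18,
       Fstar = fac$Fstar, Tstar = fac$Tstar,
       provenance = attr(fac, "provenance"))
}

#' Free motion from the constant-shear wall model
#'
#' Translational and angular velocities of the force-free, torque-free sphere
#' in unbounded linear shear near a plane wall.
#'
#' @inheritParams goldman_stationary
#' @return A list: `u_um_s`, `omega_rad_s`, the velocity ratios used, and
#'   provenance.
#' @export
goldman_free_motion <- function(shear_rate, radius, gap, mu,
                                resolution = "fine", table = NULL) {
  fac <- wall_correction_factors(gap / radius, resolution, table)
  u <- shear_rate * (radius + gap) * fac$u_ratio
  w <- shear_rate * fac$w_ratio
  list(u_um_s = u * 1e6, omega_rad_s = w,
       u_ratio = fac$u_ratio, w_ratio = fac$w_ratio,
       provenance = attr(fac, "provenance"))
}

#' Build a wall-correction factor table
#'
#' Solves the unbounded linear-shear problem over a grid of gap ratios and
#' returns (optionally writes) a plain-text coefficient table that
#' [wall_correction_factors()] can interpolate.  The written file carries a
#' provenance header.
#'
#' @param eps Grid of gap ratios h/a.
#' @param resolution Solver resolution.
#' @param file Optional output path.
#' @return The factor table (data frame).
#' @export
goldman_factor_table <- function(eps = 10^seq(-2.2, 1, length.out = 12),
                                 resolution = "medium", file = NULL) {
  tab <- wall_correction_factors(eps, resolution = resolution)
  if (!is.null(file)) {
    con <- file(file, "w")
    writeLines(c(
      "# Wall-correction factors for a sphere near a plane wall in linear shear",
      sprintf("# provenance: computed by wallstokes %s (boundary-element solver, resolution %s)",
              as.character(utils::packageVersion("wallstokes")),
              if (is.character(resolution)) resolution else resolution$level),
      "# columns: eps=h/a, Fstar, Tstar, u_ratio=u/(shear_rate*(a+h)), w_ratio=omega/shear_rate"),
      con)
    utils::write.table(format(tab, digits = 8), con, row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  tab
}

#' Read a wall-correction factor table
#'
#' @param file Path to a plain-text table written by [goldman_factor_table()]
#'   (or user-supplied with the same columns).
#' @return A data frame usable as the `table` argument of the goldman
#'   functions.
#' @export
read_goldman_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, comment.char = "#")
  stopifnot(all(c("eps", "Fstar", "Tstar", "u_ratio", "w_ratio") %in%
                  names(tab)))
  tab
}
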