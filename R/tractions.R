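# Surface traction extraction and force/torque integration.
#
# The single-layer density q equals the disturbance traction up to an
# arbitrary constant multiple of the outward normal (the interior pressure
# level of the representation), which carries no force or torque.  The
# constant is pinned so the area-weighted mean disturbance pressure on the
# sphere vanishes; the ambient Poiseuille/Couette stress is added
# analytically.  On a rigid no-slip sphere the viscous normal stress vanishes
# identically, so the normal traction is (minus) the pressure and the
# tangential traction is the viscous stress vector.

#' Extract the surface traction field
#'
#' Facet-resolved pressure and viscous traction on the sphere surface, the
#' integrands of the force and torque sums.
#'
#' @param sol A [solve_flow()] solution (with a sphere).
#' @return An object of class `traction_field`: `pressure` (Pa, per facet),
#'   `viscous` (N x 3 viscous traction vector, Pa), plus the mesh and
#'   diagnostic decompositions.
#' @export
surface_tractions <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  if (is.null(sol$mesh)) stop("no sphere in this solution")
  m <- sol$mesh
  mu <- sol$problem$fluid$mu
  q <- matrix(sol$q, ncol = 3, byrow = TRUE)

  # disturbance traction t = -q + c n (q is the force density on the fluid;
  # c is the free interior pressure level of the representation), split into
  # normal (pressure) and tangential (viscous) parts
  qn <- rowSums(q * m$normals)
  cpin <- sum(qn * m$areas) / sum(m$areas)
  p_dist <- qn - cpin
  t_visc_dist <- -(q - qn * m$normals)

  # ambient stress on the sphere surface (analytic)
  c_s <- sol$coef[1]; c_q <- sol$coef[2]
  yl <- sol$problem$sphere$yc + m$centroids[, 2]
  xl <- m$centroids[, 1]
  dpdx <- 2 * mu * c_q                        # Poiseuille pressure gradient
  p_amb <- dpdx * xl                          # reference level 0 at centre
  gamma_local <- c_s + 2 * c_q * yl
  t_amb <- cbind(mu * gamma_local * m$normals[, 2],
                 mu * gamma_local * m$normals[, 1],
                 rep(0, m$n))                 # sigma_visc . n for u_x(y)

  structure(list(pressure = p_amb + p_dist,
                 viscous = t_amb + t_visc_dist,
                 mesh = m,
                 pressure_dist = p_dist, viscous_dist = t_visc_dist,
                 pressure_amb = p_amb, viscous_amb = t_amb,
                 q = q, mu = mu),
            class = "traction_field")
}

#' Integrate force and torque over the sphere surface
#'
#' Discrete surface sums of the traction field: the force sums pressure and
#' viscous contributions over every facet; the torque about the sphere centre
#' sums only the viscous traction, because the pressure acts along the facet
#' normal, which passes through the centre and therefore produces no moment
#' (for this mesh the discrete pressure torque is exactly zero).
#'
#' @param tr A [surface_tractions()] field.
#' @return An object of class `force_torque` with fields `Fx_pN`, `Tz_pNum`
#'   (positive downstream / forward-rolling), full 3-component `F` (N) and
#'   `T` (N m), the pressure-torque diagnostic, and symmetry diagnostics.
#' @export
integrate_force_torque <- function(tr) {
  stopifnot(inherits(tr, "traction_field"))
  m <- tr$mesh
  if (abs(sum(m$areas) - pi * m$sphere$d^2) > 1e-6 * pi * m$sphere$d^2)
    stop("mesh is not closed")
  Fv <- colSums((-tr$pressure * m$normals + tr$viscous) * m$areas)
  r <- m$centroids
  tv <- tr$viscous * m$areas
  Tv <- c(sum(r[, 2] * tv[, 3] - r[, 3] * tv[, 2]),
          sum(r[, 3] * tv[, 1] - r[, 1] * tv[, 3]),
          sum(r[, 1] * tv[, 2] - r[, 2] * tv[, 1]))
  pn <- -tr$pressure * m$areas
  Tp <- c(sum(r[, 2] * pn * m$normals[, 3] - r[, 3] * pn * m$normals[, 2]),
          sum(r[, 3] * pn * m$normals[, 1] - r[, 1] * pn * m$normals[, 3]),
          sum(r[, 1] * pn * m$normals[, 2] - r[, 2] * pn * m$normals[, 1]))
  structure(list(Fx_pN = Fv[1] * 1e12,
                 Tz_pNum = -Tv[3] * 1e18,     # forward-rolling positive
                 F = Fv, T = Tv, T_pressure = Tp,
                 off_axis = list(
                   F_rel = abs(Fv[2:3]) / max(abs(Fv[1]), 1e-300),
                   T_rel = abs(Tv[1:2]) / max(abs(Tv[3]), 1e-300))),
            class = "force_torque")
}

#' Force and torque of a flow solution
#'
#' Convenience wrapper: extracts tractions and integrates them.  The result
#' carries a diagnostic comparing the traction-integrated force with the
#' exact single-layer integral (the two agree to quadrature error).
#'
#' @param sol A [solve_flow()] solution.
#' @return A `force_torque` object.
#' @export
force_torque <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  ft <- integrate_force_torque(surface_tractions(sol))
  # exact route: F = sum q ds, T = sum r x q ds
  Fq <- as.vector(sol$unit$F %*% sol$coef)
  Tq <- as.vector(sol$unit$T %*% sol$coef)
  ft$F_exact <- Fq
  ft$T_exact <- Tq
  ft$route_discrepancy_rel <-
    max(abs(ft$F[1] - Fq[1]) / max(abs(Fq[1]), 1e-300),
        abs(ft$T[3] - Tq[3]) / max(abs(Tq[3]), 1e-300))
  ft
}

#' @export
print.force_torque <- function(x, ...) {
  cat(sprintf("Fx = %.4f pN, Tz = %.4f pN um\n", x$Fx_pN, x$Tz_pNum))
  invisible(x)
}

#' Write a case result table to CSV
#'
#' Standard result schema shared by stationary and free-motion runs.
#'
#' @param rows A data frame (one row per case).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_results_csv <- function(rows, file) {
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
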