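# Boundary-element Stokes solver for a sphere near the lower wall of a
# microchannel.  The single-layer density q on the sphere surface solves
#   integral_S G(x_i, y) q(y) dS(y) = U_rigid(x_i) - u_ambient(x_i)
# where G is the Blake image-system Green's function for a no-slip plane at
# y = 0 (optionally augmented by one mirror reflection across an upper
# free-slip truncation plane).  Force and torque on the sphere equal the
# integrals of q because the ambient stress is self-equilibrated over the
# sphere and the single-layer density differs from the disturbance traction
# by a constant multiple of the normal, which integrates to zero.

.ws_env <- new.env(parent = emptyenv())

ws_clear_cache <- function() {
  rm(list = ls(.ws_env), envir = .ws_env)
  invisible(NULL)
}

resolve_resolution <- function(resolution) {
  if (is.character(resolution)) mesh_resolution(resolution) else resolution
}

#' Define a flow problem
#'
#' Couples fluid, channel, ambient-flow conditions, sphere geometry and the
#' sphere's rigid-body kinematics into one fully specified simulation case.
#'
#' Sign conventions: x points downstream, y from the lower wall into the
#' channel, z spanwise.  Translational velocity `u` is positive downstream;
#' angular velocity `omega` is positive in the forward-rolling sense (the
#' sense in which an ambient shear flow spins a free sphere).  A stationary
#' sphere has `u = omega = 0`.
#'
#' @param fluid A [fluid_properties()] object.
#' @param channel A [channel_spec()] object.
#' @param conditions A [flow_conditions()] object.
#' @param sphere A [sphere_spec()] object, or `NULL` for the empty channel.
#' @param u Sphere translational velocity along x, m s^-1.
#' @param omega Sphere angular velocity (forward-rolling positive), rad s^-1.
#' @param include_convective If `TRUE`, the first-order inertial (convective
#'   term) correction to force and torque is evaluated by the reciprocal
#'   theorem on top of the Stokes solution; see [convective_correction()].
#' @return An object of class `flow_problem`.
#' @export
flow_problem <- function(fluid, channel, conditions, sphere,
                         u = 0, omega = 0, include_convective = FALSE) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(channel, "channel_spec"),
            inherits(conditions, "flow_conditions"))
  if (!is.null(sphere)) {
    stopifnot(inherits(sphere, "sphere_spec"))
    if (sphere$yc + sphere$a >= channel$height)
      stop("sphere does not fit inside the channel")
  }
  structure(list(fluid = fluid, channel = channel, conditions = conditions,
                 sphere = sphere, u = u, omega = omega,
                 include_convective = include_convective),
            class = "flow_problem")
}

# Ambient profile in wall-local coordinates y (height above the lower wall):
# u_x(y) = c_s * y + c_q * y^2.  Parabolic: c_s = shear rate,
# c_q = -shear_rate / (2H); linear: c_q = 0.
ambient_coefficients <- function(conditions, channel) {
  g <- conditions$shear_rate
  if (conditions$profile == "parabolic")
    c(c_s = g, c_q = -g / (2 * channel$H))
  else
    c(c_s = g, c_q = 0)
}

ambient_velocity_x <- function(y, c_s, c_q) c_s * y + c_q * y^2

# Solve the four unit problems (unit ambient shear, unit ambient curvature,
# unit translation, unit rotation) for one geometry/kernel combination with a
# single matrix factorization; everything else follows by Stokes linearity.
# Cached per geometry within the session.
ws_unit_solutions <- function(sphere, fluid, resolution, conf_h,
                              min_gap_layers = 3L, cache = TRUE) {
  res <- resolve_resolution(resolution)
  # the kernel is linear in 1/mu, so the system is assembled and solved at
  # unit viscosity and the density rescaled; the cache is viscosity-free
  mu <- fluid$mu
  key <- paste(sphere$d, sphere$h, res$nb, res$nphi_max,
               res$near_fac, res$max_depth, conf_h, sep = "|")
  if (cache && !is.null(.ws_env[[key]])) {
    out <- .ws_env[[key]]
    return(rescale_unit_solutions(out, mu))
  }

  eps <- sphere$h / sphere$a
  if (gap_band_count(res$nb, eps) < min_gap_layers)
    stop(sprintf(paste("gap is thinner than the finest resolvable facet layer",
                       "at this resolution (%d bands in the gap zone, %d",
                       "required); raise the resolution"),
                 gap_band_count(res$nb, eps), min_gap_layers))

  mesh <- sphere_surface_mesh(sphere, nb = res$nb, nphi_max = res$nphi_max,
                              gap_adaptive = TRUE)
  a <- sphere$a; yc <- sphere$yc
  n <- mesh$n

  A <- .bem_assemble(mesh$panels, a, yc, 1.0, TRUE, conf_h,
                     res$near_fac, res$max_depth)

  # boundary data: rows interleave (x,y,z) per facet
  yl <- yc + mesh$centroids[, 2]          # lab height of facet centroids
  B <- matrix(0, 3 * n, 4)
  ix <- seq(1, 3 * n, by = 3)
  B[ix, 1] <- -yl                          # minus unit-shear ambient
  B[ix, 2] <- -yl^2                        # minus unit-curvature ambient
  B[ix, 3] <- 1                            # unit translation along x
  B[ix, 4] <- -mesh$centroids[, 2]         # unit rotation omega_z = 1:
  B[ix + 1, 4] <- mesh$centroids[, 1]      #   u = z_hat x r

  # keep a few rows of A to report the linear-system residual after the
  # in-place solve destroys it (deterministic row choice: no RNG anywhere)
  chk <- unique(round(seq(1, 3 * n, length.out = min(24L, 3 * n))))
  Achk <- A[chk, , drop = FALSE]
  Bchk <- B[chk, , drop = FALSE]
  Bmax <- max(abs(B))

  X <- .bem_solve_inplace(A, B)   # overwrites A and B; X aliases B
  rm(A)

  resid <- max(abs(Achk %*% X - Bchk)) / Bmax

  # force and torque (about the sphere centre) of each unit solution; the
  # single-layer density is the force density exerted ON the fluid, so the
  # load on the sphere is minus its integral
  Fmat <- matrix(0, 3, 4); Tmat <- matrix(0, 3, 4)
  for (k in 1:4) {
    q <- matrix(X[, k], ncol = 3, byrow = TRUE)
    qa <- q * mesh$areas
    Fmat[, k] <- -colSums(qa)
    r <- mesh$centroids
    Tmat[, k] <- -c(sum(r[, 2] * qa[, 3] - r[, 3] * qa[, 2]),
                    sum(r[, 3] * qa[, 1] - r[, 1] * qa[, 3]),
                    sum(r[, 1] * qa[, 2] - r[, 2] * qa[, 1]))
  }
  out <- list(mesh = mesh, X = X, F = Fmat, T = Tmat, mu = 1.0,
              conf_h = conf_h, resolution = res, residual = resid,
              near_fac = res$near_fac, max_depth = res$max_depth)
  if (cache) .ws_env[[key]] <- out
  rescale_unit_solutions(out, mu)
}

rescale_unit_solutions <- function(unit, mu) {
  if (identical(unit$mu, mu)) return(unit)
  s <- mu / unit$mu
  unit$X <- unit$X * s
  unit$F <- unit$F * s
  unit$T <- unit$T * s
  unit$mu <- mu
  unit
}

# Composition coefficients of a problem in the unit-solution basis
# (c_shear, c_quad, u, omega_z) -- note omega_z is right-handed about z, the
# negative of the reported forward-rolling omega.
case_coefficients <- function(problem) {
  ac <- ambient_coefficients(problem$conditions, problem$channel)
  c(ac[["c_s"]], ac[["c_q"]], problem$u, -problem$omega)
}

#' Solve the steady Stokes flow around the sphere
#'
#' Solves the steady incompressible Stokes equations around a rigid sphere
#' near the lower channel wall with the prescribed ambient profile and
#' rigid-body kinematics, using a single-layer boundary-element method with
#' the exact wall Green's function.  Momentum and continuity are satisfied
#' identically by the representation; the linear system for the surface
#' density is solved directly, and its residual is recorded in the metadata.
#'
#' The reduced-domain truncation of the channel is represented by
#' `confinement`: `"upper_freeslip"` (default) adds a single mirror reflection
#' across the plane `y = conf_height`, emulating the impenetrable free-slip
#' upper boundary of an 80 x 40 um computational sub-domain; `"none"` solves
#' the unbounded half-space above the wall (the classical constant-shear
#' wall-correction configuration).
#'
#' @param problem A [flow_problem()].
#' @param domain Optional [reduced_domain()]; when given, its inlet height
#'   sets `conf_height`.
#' @param resolution `"coarse"`, `"medium"`, `"fine"`, or a list from
#'   [mesh_resolution()].
#' @param confinement `"upper_freeslip"` or `"none"`.
#' @param conf_height Height of the free-slip truncation plane in metres
#'   (default 40 um, the reduced-domain height).
#' @param cache Reuse the factorized geometry within the session.
#' @return An object of class `flow_solution`.
#' @export
#' @examples
#' \donttest{
#' fl <- fluid_properties(0.0009)
#' ch <- channel_spec()
#' co <- flow_conditions(wss = dyn_cm2_to_pa(0.1), profile = "parabolic",
#'                       fluid = fl)
#' sp <- sphere_spec(10e-6, 0.069e-6)
#' sol <- solve_flow(flow_problem(fl, ch, co, sp), resolution = "coarse")
#' force_torque(sol)
#' }
solve_flow <- function(problem, domain = NULL, resolution = "medium",
                       confinement = c("upper_freeslip", "none"),
                       conf_height = NULL, cache = TRUE) {
  stopifnot(inherits(problem, "flow_problem"))
  confinement <- match.arg(confinement)
  if (!is.null(domain)) conf_height <- domain$inlet_height
  if (is.null(conf_height)) conf_height <- 40e-6
  conf_h <- if (confinement == "upper_freeslip") conf_height else -1
  if (isTRUE(problem$include_convective) && !is.null(problem$sphere)) {
    re <- reynolds_number(problem$conditions, problem$fluid,
                          problem$sphere$d)
    if (re > 10)
      warning(sprintf(paste("particle shear Reynolds number %.3g exceeds 10;",
                            "the first-order convective correction is outside",
                            "its validated regime"), as.numeric(re)))
  }

  if (is.null(problem$sphere)) {
    # empty channel: the ambient profile is the exact solution
    out <- list(problem = problem, mesh = NULL, q = NULL,
                coef = case_coefficients(problem), unit = NULL,
                conf_h = conf_h,
                metadata = list(resolution = NULL, residual = 0,
                                method = "analytic ambient (no sphere)"))
    class(out) <- "flow_solution"
    return(out)
  }

  unit <- ws_unit_solutions(problem$sphere, problem$fluid, resolution,
                            conf_h, cache = cache)
  coef <- case_coefficients(problem)
  q <- as.vector(unit$X %*% coef)
  out <- list(problem = problem, mesh = unit$mesh, q = q, coef = coef,
              unit = unit, conf_h = conf_h,
              metadata = list(resolution = unit$resolution,
                              residual = unit$residual,
                              n_facets = unit$mesh$n,
                              method = "single-layer BEM, Blake wall kernel, direct LU",
                              confinement = confinement))
  class(out) <- "flow_solution"
  out
}

#' Evaluate the velocity field of a solution
#'
#' Total velocity (ambient plus disturbance) at arbitrary points given in
#' wall-local coordinates: origin on the lower wall below the sphere centre,
#' x downstream, y wall-normal (up), z spanwise.
#'
#' @param sol A [solve_flow()] solution.
#' @param points M x 3 matrix of evaluation points (metres, wall frame).
#' @return M x 3 matrix of velocities (m s^-1).
#' @export
evaluate_velocity <- function(sol, points) {
  stopifnot(inherits(sol, "flow_solution"))
  points <- rbind(points)
  u <- matrix(0, nrow(points), 3)
  u[, 1] <- ambient_velocity_x(points[, 2], sol$coef[1], sol$coef[2])
  if (!is.null(sol$q)) {
    sp <- sol$problem$sphere
    u <- u + .bem_velocity(points, sol$mesh$panels, sp$a, sp$yc, sol$q,
                           sol$problem$fluid$mu, TRUE, sol$conf_h,
                           sol$unit$near_fac, sol$unit$max_depth)
  }
  u
}

#' Check discrete mass conservation
#'
#' Computes the net volumetric flux through a closed control box enclosing
#' the sphere (five quadrature faces plus the no-slip wall, where the
#' velocity vanishes identically), the net flux through the sphere surface
#' implied by the boundary data, and the maximum pointwise divergence of the
#' velocity field near the sphere estimated by central differences.
#'
#' For this discretization the field is divergence-free analytically; the
#' reported numbers measure quadrature and rounding error and should be many
#' orders of magnitude below one.
#'
#' @param sol A [solve_flow()] solution.
#' @param nq Gauss-Legendre points per face edge.
#' @param margin Box clearance from the sphere surface in sphere radii.
#' @return A list: `net_box_flux_rel` (net box flux / inlet-face influx),
#'   `sphere_flux_rel` (net flux through the sphere surface / reference),
#'   `max_divergence_rel` (max |div u| * a / |u|_ref), `flagged`.
#' @export
check_mass_conservation <- function(sol, nq = 40, margin = 1.0) {
  stopifnot(inherits(sol, "flow_solution"))
  sp <- sol$problem$sphere
  if (is.null(sp)) stop("mass check requires a sphere in the problem")
  a <- sp$a; yc <- sp$yc
  cx <- a * (1 + margin)
  ytop <- yc + a * (1 + margin)

  gl <- gauss_legendre(nq)
  # face integrals: x = +-cx (normal x), z = +-cx (normal z), y = ytop
  face_flux <- function(fixed, axis) {
    s1 <- gl$x; w1 <- gl$w
    if (axis == "x") { # vary y in (0, ytop), z in (-cx, cx)
      yv <- ytop * (s1 + 1) / 2; zv <- cx * s1
      gr <- expand.grid(y = yv, z = zv)
      pts <- cbind(fixed, gr$y, gr$z)
      wts <- outer(w1 * ytop / 2, w1 * cx)
      un <- evaluate_velocity(sol, pts)[, 1]
    } else if (axis == "z") {
      yv <- ytop * (s1 + 1) / 2; xv <- cx * s1
      gr <- expand.grid(y = yv, x = xv)
      pts <- cbind(gr$x, gr$y, fixed)
      wts <- outer(w1 * ytop / 2, w1 * cx)
      un <- evaluate_velocity(sol, pts)[, 3]
    } else {
      xv <- cx * s1; zv <- cx * s1
      gr <- expand.grid(x = xv, z = zv)
      pts <- cbind(gr$x, fixed, gr$z)
      wts <- outer(w1 * cx, w1 * cx)
      un <- evaluate_velocity(sol, pts)[, 2]
    }
    sum(un * as.vector(wts))
  }
  influx <- face_flux(-cx, "x")
  outflux <- face_flux(cx, "x")
  side1 <- face_flux(-cx, "z"); side2 <- face_flux(cx, "z")
  top <- face_flux(ytop, "y")
  net <- (outflux - influx) + (side2 - side1) + top
  net_rel <- abs(net) / abs(influx)

  # flux through the sphere surface: the boundary condition makes the total
  # velocity on the surface the rigid-body velocity u x_hat + omega_z z_hat x r
  m <- sol$mesh
  wz <- case_coefficients(sol$problem)[4]
  urig <- cbind(sol$problem$u - wz * m$centroids[, 2],
                wz * m$centroids[, 1],
                rep(0, m$n))
  sflux <- sum(rowSums(urig * m$normals) * m$areas)
  sflux_rel <- abs(sflux) / max(abs(influx), 1e-300)

  # pointwise divergence by central differences on a ring of probes
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  probe <- cbind(1.6 * a * cos(th), yc + 0.2 * a * sin(th), 0.3 * a)
  hstep <- 5e-3 * a
  divs <- vapply(seq_len(nrow(probe)), function(i) {
    p <- probe[i, ]
    d <- 0
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- hstep
      up <- evaluate_velocity(sol, rbind(p + e, p - e))
      d <- d + (up[1, k] - up[2, k]) / (2 * hstep)
    }
    d
  }, 0)
  uref <- max(abs(evaluate_velocity(sol, probe)))
  div_rel <- max(abs(divs)) * a / max(uref, 1e-300)

  list(net_box_flux_rel = net_rel, sphere_flux_rel = sflux_rel,
       max_divergence_rel = div_rel,
       flagged = net_rel > 1e-6 || sflux_rel > 1e-10)
}

gauss_legendre <- function(n) {
  # Golub-Welsch via the symmetric tridiagonal Jacobi matrix
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("Stokes flow solution\n")
  if (!is.null(x$mesh)) {
    ft <- force_torque(x)
    cat(sprintf("  %d facets (%s), residual %.2e\n", x$mesh$n,
                x$metadata$resolution$level, x$metadata$residual))
    cat(sprintf("  Fx = %.4g pN, Tz = %.4g pN um\n", ft$Fx_pN, ft$Tz_pNum))
  } else cat("  empty channel (analytic ambient profile)\n")
  invisible(x)
}
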