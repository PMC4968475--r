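# Force-free / torque-free motion of a neutrally buoyant sphere.
#
# Under Stokes linearity the force and torque on the sphere are affine in its
# rigid-body velocities:
#   Fx = F0 + R_Fu u + R_Fw w,   Tz = T0 + R_Tu u + R_Tw w
# (reported conventions: u downstream-positive, w forward-rolling-positive,
# Tz forward-rolling-positive).  The free-motion state solves the 2x2 linear
# system Fx = Tz = 0.  The resistance entries come from unit-translation and
# unit-rotation solves in quiescent fluid and (F0, T0) from the held-fixed
# sphere in the ambient profile -- all three share one matrix factorization.

#' Resistance matrix and ambient loading
#'
#' Assembles the 2x2 resistance matrix mapping (u, omega) to (Fx, Tz) and the
#' ambient force/torque on the held-fixed sphere.  Diagonal entries are
#' negative (drag opposes motion); the off-diagonal entries are equal by the
#' Lorentz reciprocal theorem, up to discretization error.
#'
#' @inheritParams solve_flow
#' @return An object of class `resistance_matrix`: `R` (2x2, N and N m per
#'   (m/s, rad/s)), `F0`, `T0` (N, N m, reported sign conventions),
#'   `symmetry_rel` (relative asymmetry of the couplings).
#' @export
resistance_matrix <- function(problem, resolution = "medium",
                              confinement = c("upper_freeslip", "none"),
                              conf_height = NULL, cache = TRUE) {
  stopifnot(inherits(problem, "flow_problem"))
  if (isTRUE(problem$include_convective))
    stop(paste("superposition is invalid with the convective term;",
               "use quasi_static_iterate()"))
  confinement <- match.arg(confinement)
  if (is.null(conf_height)) conf_height <- 40e-6
  conf_h <- if (confinement == "upper_freeslip") conf_height else -1
  unit <- ws_unit_solutions(problem$sphere, problem$fluid, resolution,
                            conf_h, cache = cache)
  ac <- ambient_coefficients(problem$conditions, problem$channel)

  # reported-convention scalars from the right-handed unit solutions
  # (omega_reported = -omega_z, Tz_reported = -Tz_rh)
  F0 <- sum(unit$F[1, 1:2] * ac)
  T0 <- -sum(unit$T[3, 1:2] * ac)
  R_Fu <- unit$F[1, 3]
  R_Tu <- -unit$T[3, 3]
  R_Fw <- -unit$F[1, 4]
  R_Tw <- unit$T[3, 4]
  R <- matrix(c(R_Fu, R_Tu, R_Fw, R_Tw), 2, 2,
              dimnames = list(c("Fx", "Tz"), c("u", "omega")))
  sym <- abs(R_Fw - R_Tu) / max(abs(R_Fw), abs(R_Tu))
  structure(list(R = R, F0 = F0, T0 = T0, symmetry_rel = sym,
                 unit = unit, problem = problem,
                 confinement = confinement, conf_height = conf_height),
            class = "resistance_matrix")
}

#' Free-motion (mobility) solution
#'
#' Finds the translational and angular velocities at which the net
#' hydrodynamic force and torque on the sphere vanish, by inverting the
#' resistance matrix (exact under Stokes linearity).  The residual force and
#' torque at the solution are evaluated by superposing the three unit
#' solutions at the found velocities.
#'
#' @inheritParams resistance_matrix
#' @param tol Residual tolerance as a fraction of the stationary-sphere force
#'   and torque (default 0.5 percent).
#' @return An object of class `free_motion_result`: `u_um_s`, `omega_rad_s`
#'   (forward-rolling positive), residuals in pN and pN um, and the mode.
#' @export
#' @examples
#' \donttest{
#' fl <- fluid_properties(0.0009); ch <- channel_spec()
#' co <- flow_conditions(wss = dyn_cm2_to_pa(0.1), fluid = fl)
#' pr <- flow_problem(fl, ch, co, sphere_spec(10e-6, 0.069e-6))
#' solve_free_motion(pr, resolution = "coarse")
#' }
solve_free_motion <- function(problem, resolution = "medium",
                              confinement = c("upper_freeslip", "none"),
                              conf_height = NULL, tol = 0.005, cache = TRUE) {
  rm_ <- resistance_matrix(problem, resolution, confinement, conf_height,
                           cache = cache)
  if (abs(det(rm_$R)) < 1e-30 * abs(rm_$R[1, 1] * rm_$R[2, 2]))
    stop("singular resistance matrix")
  uw <- as.numeric(solve(rm_$R, -c(rm_$F0, rm_$T0)))
  resid <- as.numeric(rm_$R %*% uw + c(rm_$F0, rm_$T0))
  res_rel <- c(abs(resid[1]) / abs(rm_$F0), abs(resid[2]) / abs(rm_$T0))
  structure(list(u_um_s = uw[1] * 1e6, omega_rad_s = uw[2],
                 u = uw[1], omega = uw[2],
                 residual_force_pN = resid[1] * 1e12,
                 residual_torque_pNum = resid[2] * 1e18,
                 residual_rel = max(res_rel), tol = tol,
                 within_tol = max(res_rel) <= tol,
                 resistance = rm_, mode = "superposition"),
            class = "free_motion_result")
}

#' Quasi-static free-motion iteration
#'
#' Reproduces the time-stepping procedure in which the sphere's velocities
#' are repeatedly updated from the current force and torque imbalance until
#' both approach zero.  Updates are damped Richardson steps scaled by the
#' unbounded-fluid drag coefficients; on divergence the step is halved.  In
#' Stokes mode each force evaluation is exact superposition of the cached
#' unit solutions, so the iteration converges to the same state as
#' [solve_free_motion()].
#'
#' @inheritParams solve_free_motion
#' @param u0,omega0 Initial velocity guesses (m s^-1, rad s^-1).
#' @param damping Initial damping factor for the updates.
#' @param max_steps Iteration cap.
#' @return A `free_motion_result` with the iteration trace in `$trace`.
#' @export
quasi_static_iterate <- function(problem, resolution = "medium",
                                 confinement = c("upper_freeslip", "none"),
                                 conf_height = NULL, u0 = 0, omega0 = 0,
                                 damping = 0.7, tol = 0.005,
                                 max_steps = 200, cache = TRUE) {
  convective <- isTRUE(problem$include_convective)
  pr0 <- problem
  pr0$include_convective <- FALSE
  rm_ <- resistance_matrix(pr0, resolution, confinement, conf_height,
                           cache = cache)
  mu <- problem$fluid$mu; a <- problem$sphere$a
  cF <- 6 * pi * mu * a          # unbounded translational drag scale
  cT <- 8 * pi * mu * a^3        # unbounded rotational drag scale
  Fref <- abs(rm_$F0); Tref <- abs(rm_$T0)
  u <- u0; w <- omega0; lam <- damping
  trace <- data.frame(step = integer(), u_um_s = numeric(),
                      omega_rad_s = numeric(), Fx_pN = numeric(),
                      Tz_pNum = numeric(), damping = numeric())
  prev <- Inf
  for (k in seq_len(max_steps)) {
    Fx <- rm_$F0 + rm_$R[1, 1] * u + rm_$R[1, 2] * w
    Tz <- rm_$T0 + rm_$R[2, 1] * u + rm_$R[2, 2] * w
    trace[k, ] <- list(k, u * 1e6, w, Fx * 1e12, Tz * 1e18, lam)
    res <- max(abs(Fx) / Fref, abs(Tz) / Tref)
    if (res <= tol) break
    if (res > 1.05 * prev) {
      lam <- lam / 2
      if (lam < 1e-4) stop("quasi-static iteration diverged")
    }
    prev <- res
    u <- u + lam * Fx / cF
    w <- w + lam * Tz / cT
  }
  if (res > tol)
    stop("quasi-static iteration did not converge within max_steps")
  inertial <- NULL
  if (convective) {
    # one corrected update at the converged Stokes state: the first-order
    # inertial load shift is re-balanced through the resistance matrix
    pr1 <- pr0; pr1$u <- u; pr1$omega <- w
    sol <- solve_flow(pr1, resolution = resolution,
                      confinement = rm_$confinement,
                      conf_height = rm_$conf_height, cache = cache)
    cc <- convective_correction(sol)
    duw <- solve(rm_$R, -c(cc$dF_pN * 1e-12, cc$dT_pNum * 1e-18))
    u <- u + duw[1]; w <- w + duw[2]
    inertial <- cc
  }
  structure(list(u_um_s = u * 1e6, omega_rad_s = w, u = u, omega = w,
                 inertial_correction = inertial,
                 residual_force_pN = Fx * 1e12,
                 residual_torque_pNum = Tz * 1e18,
                 residual_rel = res, tol = tol, within_tol = TRUE,
                 steps = k, trace = trace, resistance = rm_,
                 mode = "quasi-static iteration"),
            class = "free_motion_result")
}

#' @export
print.free_motion_result <- function(x, ...) {
  cat(sprintf("free motion (%s): u = %.4g um/s, omega = %.4g rad/s\n",
              x$mode, x$u_um_s, x$omega_rad_s))
  cat(sprintf("  residuals: %.2e pN, %.2e pN um (rel %.2e)\n",
              x$residual_force_pN, x$residual_torque_pNum, x$residual_rel))
  invisible(x)
}

#' @export
print.resistance_matrix <- function(x, ...) {
  cat("resistance matrix (Fx, Tz) per (u, omega), reported conventions:\n")
  print(x$R)
  cat(sprintf("ambient loading: F0 = %.4g pN, T0 = %.4g pN um; coupling asymmetry %.2e\n",
              x$F0 * 1e12, x$T0 * 1e18, x$symmetry_rel))
  invisible(x)
}
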