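# First-order inertial (convective-term) correction by the reciprocal
# theorem.  With u the Stokes solution and u_hat an auxiliary Stokes field
# that equals a unit rigid motion on the sphere, vanishes on the wall and
# decays at infinity, the leading effect of the convective term rho (u . grad u)
# on the hydrodynamic load is
#   dF_k = -rho * integral_fluid (u . grad u) . u_hat_k dV.
# At the shear Reynolds numbers of microchannel cell assays (Re ~ 1e-3 to
# 1e-2) this correction is a fraction of a percent; it is computed so the
# package can quantify, not merely assert, that neglecting inertia is safe.

#' Convective-term correction to force and torque
#'
#' Evaluates the first-order inertial correction to the streamwise force and
#' spanwise torque of a Stokes solution via the reciprocal theorem, using the
#' unit-translation and unit-rotation solutions as auxiliary fields and a
#' spherical-shell quadrature of the convective volume integrand around the
#' sphere (clipped at the wall, where all fields vanish).
#'
#' @param sol A [solve_flow()] solution.
#' @param n_r,n_t,n_p Radial, polar and azimuthal quadrature counts.
#' @param r_max Outer integration radius in sphere radii (the integrand
#'   decays like r^-4 and beyond).
#' @return A list with `dF_pN`, `dT_pNum`, and the relative corrections
#'   `dF_rel`, `dT_rel` (relative to the Stokes force and torque).
#' @export
convective_correction <- function(sol, n_r = 14, n_t = 12, n_p = 12,
                                  r_max = 8) {
  stopifnot(inherits(sol, "flow_solution"))
  sp <- sol$problem$sphere
  if (is.null(sp)) stop("convective correction requires a sphere")
  a <- sp$a; yc <- sp$yc
  rho <- sol$problem$fluid$rho

  gl <- gauss_legendre(n_t)
  # radial: log-spaced shells from just off the surface outward
  rr <- a * exp(seq(log(1.04), log(r_max), length.out = n_r))
  wr <- c(diff(rr), 0) / 2 + c(0, diff(rr)) / 2
  ph <- 2 * pi * (seq_len(n_p) - 0.5) / n_p
  grid <- expand.grid(ir = seq_len(n_r), it = seq_len(n_t), ip = seq_len(n_p))
  ct <- gl$x[grid$it]; st <- sqrt(1 - ct^2)
  pts <- cbind(grid_x = rr[grid$ir] * st * cos(ph[grid$ip]),
               yc + rr[grid$ir] * ct,
               rr[grid$ir] * st * sin(ph[grid$ip]))
  w <- rr[grid$ir]^2 * wr[grid$ir] * gl$w[grid$it] * (2 * pi / n_p)
  keep <- pts[, 2] > 1e-3 * a          # fluid region only (above the wall)
  pts <- pts[keep, , drop = FALSE]; w <- w[keep]
  M <- nrow(pts)

  # main field and its gradient (central differences)
  u0 <- evaluate_velocity(sol, pts)
  hstep <- 3e-3 * a
  adv <- matrix(0, M, 3)               # (u . grad) u
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- hstep
    up <- evaluate_velocity(sol, sweep(pts, 2, e, "+"))
    um <- evaluate_velocity(sol, sweep(pts, 2, e, "-"))
    adv <- adv + u0[, k] * (up - um) / (2 * hstep)
  }

  # auxiliary unit-translation and unit-rotation disturbance fields
  unit <- sol$unit
  aux <- function(col) {
    .bem_velocity(pts, unit$mesh$panels, sp$a, sp$yc, unit$X[, col],
                  sol$problem$fluid$mu, TRUE, sol$conf_h,
                  unit$near_fac, unit$max_depth)
  }
  uT <- aux(3); uR <- aux(4)
  dF <- -rho * sum(w * rowSums(adv * uT))
  dTz_rh <- -rho * sum(w * rowSums(adv * uR))
  ft <- force_torque(sol)
  list(dF_pN = dF * 1e12, dT_pNum = -dTz_rh * 1e18,
       dF_rel = abs(dF * 1e12 / ft$Fx_pN),
       dT_rel = abs(dTz_rh * 1e18 / ft$Tz_pNum))
}
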