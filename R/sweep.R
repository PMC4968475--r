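# Batch driver and comparison reports: named case presets, WSS sweeps, and
# regeneration of the headline stationary/free-motion tables.

#' Published reference values used in comparison reports
#'
#' Reported stationary force/torque and free-motion velocities for the
#' standard benchmark cases (10 um sphere, 0.069 um gap, WSS = 0.1 dynes
#' cm^-2 in a 100 um channel; and the 12 um / 1.4 um-gap lymphocyte case),
#' used by [reproduce_benchmark_tables()] as the comparison baseline.
#'
#' @return A data frame with case id, quantity, units and reference value.
#' @export
reference_values <- function() {
  data.frame(
    case = c("table1_caseA", "table1_caseA", "table1_caseB", "table1_caseB",
             "table1_caseC", "table1_caseC", "free_wss0.1_cfd",
             "free_wss0.1_goldman", "tissot_cfd", "tissot_cfd",
             "tissot_goldman", "tissot_goldman",
             "tissot_experiment", "tissot_experiment"),
    quantity = c("Fx_pN", "Tz_pNum", "Fx_pN", "Tz_pNum", "Fx_pN", "Tz_pNum",
                 "omega_rad_s", "omega_rad_s", "u_um_s", "omega_rad_s",
                 "u_um_s", "omega_rad_s", "u_um_s", "omega_rad_s"),
    reference = c(6.64, 11.51, 8.31, 14.51, 8.07, 14.83, 5.0, 3.1,
                  7.60, 0.81, 7.88, 0.54, 7.07, 0.78))
}

#' Named case presets
#'
#' Fully specified benchmark cases: `table1_caseA` (parabolic profile, full
#' reduced-domain solve), `table1_caseB` (linear profile, reduced domain),
#' `table1_caseC` (constant-shear wall model), `tissot_cfd` /
#' `tissot_goldman` (12 um cell at 1.4 um gap, shear rate 1.32 s^-1),
#' `fig4_wss_grid` and `fig6_wss_grid` (WSS sweeps, stationary and free).
#'
#' @param name Preset name.
#' @return A data frame of case rows suitable for [run_sweep()].
#' @export
case_preset <- function(name = c("table1_caseA", "table1_caseB",
                                 "table1_caseC", "table1", "tissot_cfd",
                                 "tissot_goldman", "fig4_wss_grid",
                                 "fig6_wss_grid")) {
  name <- match.arg(name)
  base <- data.frame(case = name, wss_dyn_cm2 = 0.1, shear_rate = NA,
                     profile = "parabolic", mode = "stationary",
                     method = "solver", d_um = 10, h_um = 0.069, mu = 0.0009,
                     rho = 1000, channel_height_um = 100,
                     stringsAsFactors = FALSE)
  switch(name,
    table1_caseA = base,
    table1_caseB = transform(base, profile = "linear"),
    table1_caseC = transform(base, profile = "linear", method = "goldman"),
    table1 = {
      rows <- rbind(case_preset("table1_caseA"), case_preset("table1_caseB"),
                    case_preset("table1_caseC"))
      rows$case <- c("table1_caseA", "table1_caseB", "table1_caseC")
      rows
    },
    tissot_cfd = transform(base, case = "tissot_cfd", wss_dyn_cm2 = NA,
                           shear_rate = 1.32, d_um = 12, h_um = 1.4,
                           mu = 0.001, mode = "free"),
    tissot_goldman = transform(base, case = "tissot_goldman",
                               wss_dyn_cm2 = NA, shear_rate = 1.32,
                               d_um = 12, h_um = 1.4, mu = 0.001,
                               mode = "free", method = "goldman",
                               profile = "linear"),
    fig4_wss_grid = {
      w <- c(0.1, 0.5, 1.0, 2.5, 5.0)
      rows <- base[rep(1, 2 * length(w)), ]
      rows$wss_dyn_cm2 <- rep(w, 2)
      rows$profile <- rep(c("parabolic", "linear"), each = length(w))
      rows$method <- rep(c("solver", "goldman"), each = length(w))
      rows$case <- sprintf("fig4_%s_wss%.2g", rows$profile, rows$wss_dyn_cm2)
      rows
    },
    fig6_wss_grid = {
      w <- c(0.1, 0.25, 0.5, 1.0)
      rows <- base[rep(1, 2 * length(w)), ]
      rows$wss_dyn_cm2 <- rep(w, 2)
      rows$mode <- "free"
      rows$profile <- rep(c("parabolic", "linear"), each = length(w))
      rows$method <- rep(c("solver", "goldman"), each = length(w))
      rows$case <- sprintf("fig6_%s_wss%.2g", rows$profile, rows$wss_dyn_cm2)
      rows
    })
}

run_one_case <- function(row, resolution) {
  fl <- fluid_properties(mu = row$mu, rho = row$rho)
  ch <- channel_spec(height = row$channel_height_um * 1e-6)
  co <- flow_conditions(
    wss = if (is.na(row$wss_dyn_cm2)) NULL else dyn_cm2_to_pa(row$wss_dyn_cm2),
    shear_rate = if (is.na(row$shear_rate)) NULL else row$shear_rate,
    profile = row$profile, fluid = fl)
  sp <- sphere_spec(row$d_um * 1e-6, row$h_um * 1e-6)
  out <- data.frame(case = row$case, wss_dyn_cm2 = pa_to_dyn_cm2(co$wss),
                    shear_rate = co$shear_rate, profile = row$profile,
                    mode = row$mode, method = row$method, d_um = row$d_um,
                    h_um = row$h_um, mu = row$mu,
                    Fx_pN = NA_real_, Tz_pNum = NA_real_,
                    u_um_s = NA_real_, omega_rad_s = NA_real_,
                    resolution = if (is.character(resolution)) resolution
                    else resolution$level,
                    residual = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  if (row$method == "goldman") {
    if (row$mode == "stationary") {
      g <- goldman_stationary(co$shear_rate, sp$a, sp$h, fl$mu,
                              resolution = resolution)
      out$Fx_pN <- g$Fx_pN; out$Tz_pNum <- g$Tz_pNum
    } else {
      g <- goldman_free_motion(co$shear_rate, sp$a, sp$h, fl$mu,
                               resolution = resolution)
      out$u_um_s <- g$u_um_s; out$omega_rad_s <- g$omega_rad_s
    }
  } else {
    pr <- flow_problem(fl, ch, co, sp)
    if (row$mode == "stationary") {
      sol <- solve_flow(pr, resolution = resolution)
      ft <- force_torque(sol)
      out$Fx_pN <- ft$Fx_pN; out$Tz_pNum <- ft$Tz_pNum
      out$residual <- sol$metadata$residual
    } else {
      fm <- solve_free_motion(pr, resolution = resolution)
      out$u_um_s <- fm$u_um_s; out$omega_rad_s <- fm$omega_rad_s
      out$residual <- fm$residual_rel
    }
  }
  out
}

#' Run a batch of cases
#'
#' Evaluates each case row (see [case_preset()] for the schema) and returns
#' one result row per case, in input order; individual case failures are
#' recorded in the `status` column and do not stop the sweep.  Results are
#' fully deterministic: re-running an identical sweep reproduces the same
#' table bit for bit.
#'
#' @param cases Data frame of case rows.
#' @param out_dir Optional directory for a `sweep_results.csv`.
#' @param resolution Solver resolution for all cases.
#' @return Data frame of results.
#' @export
run_sweep <- function(cases, out_dir = NULL, resolution = "medium") {
  stopifnot(is.data.frame(cases), nrow(cases) > 0)
  if (any(!cases$mode %in% c("stationary", "free")))
    stop("mode must be 'stationary' or 'free'")
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    row <- cases[i, ]
    tryCatch(run_one_case(row, resolution),
             error = function(e) {
               data.frame(case = row$case, wss_dyn_cm2 = row$wss_dyn_cm2,
                          shear_rate = row$shear_rate, profile = row$profile,
                          mode = row$mode, method = row$method,
                          d_um = row$d_um, h_um = row$h_um, mu = row$mu,
                          Fx_pN = NA_real_, Tz_pNum = NA_real_,
                          u_um_s = NA_real_, omega_rad_s = NA_real_,
                          resolution = if (is.character(resolution))
                            resolution else resolution$level,
                          residual = NA_real_,
                          status = paste("error:", conditionMessage(e)),
                          stringsAsFactors = FALSE)
             })
  })
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(res, file.path(out_dir, "sweep_results.csv"))
  }
  res
}

#' Recompute the benchmark tables and compare with published values
#'
#' Recomputes the stationary Table-1 trio (parabolic, linear, constant-shear
#' model), the free-motion angular velocities at WSS = 0.1 dynes cm^-2, the
#' free-motion rotation-rate ratio over a WSS grid, and the 12 um lymphocyte
#' case, and reports each against the published reference value with percent
#' deviations.
#'
#' @param out_dir Optional directory for the CSV report.
#' @param resolution Solver resolution.
#' @return Data frame: case, quantity, computed, reference, deviation_pct.
#' @export
reproduce_benchmark_tables <- function(out_dir = NULL, resolution = "medium") {
  t1 <- run_sweep(case_preset("table1"), resolution = resolution)
  free_p <- run_one_case(transform(case_preset("table1_caseA"),
                                   mode = "free", case = "free_wss0.1_cfd"),
                         resolution)
  free_g <- run_one_case(transform(case_preset("table1_caseC"), mode = "free",
                                   case = "free_wss0.1_goldman"),
                         resolution)
  tis <- run_sweep(rbind(case_preset("tissot_cfd"),
                         case_preset("tissot_goldman")),
                   resolution = resolution)
  comp <- rbind(
    data.frame(case = "table1_caseA", quantity = c("Fx_pN", "Tz_pNum"),
               computed = c(t1$Fx_pN[1], t1$Tz_pNum[1])),
    data.frame(case = "table1_caseB", quantity = c("Fx_pN", "Tz_pNum"),
               computed = c(t1$Fx_pN[2], t1$Tz_pNum[2])),
    data.frame(case = "table1_caseC", quantity = c("Fx_pN", "Tz_pNum"),
               computed = c(t1$Fx_pN[3], t1$Tz_pNum[3])),
    data.frame(case = "free_wss0.1_cfd", quantity = "omega_rad_s",
               computed = free_p$omega_rad_s),
    data.frame(case = "free_wss0.1_goldman", quantity = "omega_rad_s",
               computed = free_g$omega_rad_s),
    data.frame(case = "tissot_cfd", quantity = c("u_um_s", "omega_rad_s"),
               computed = c(tis$u_um_s[1], tis$omega_rad_s[1])),
    data.frame(case = "tissot_goldman", quantity = c("u_um_s", "omega_rad_s"),
               computed = c(tis$u_um_s[2], tis$omega_rad_s[2])))
  comp <- merge(comp, reference_values(), by = c("case", "quantity"),
                sort = FALSE)
  comp$deviation_pct <- 100 * (comp$computed - comp$reference) / comp$reference

  # derived comparison lines: profile deviation and rotation-rate ratio
  extra <- data.frame(
    case = c("table1", "free_wss0.1"),
    quantity = c("linear_vs_parabolic_force_dev_pct", "omega_ratio_cfd_goldman"),
    computed = c(100 * (t1$Fx_pN[2] - t1$Fx_pN[1]) / t1$Fx_pN[1],
                 free_p$omega_rad_s / free_g$omega_rad_s),
    reference = c(25, 1.49))
  extra$deviation_pct <- 100 * (extra$computed - extra$reference) /
    extra$reference
  comp <- rbind(comp, extra)

  # agreement with the measured lymphocyte velocities is reported (the
  # experimental scatter itself is not modelled, so it is never gated)
  meas <- data.frame(
    case = "tissot_vs_experiment", quantity = c("u_um_s", "omega_rad_s"),
    computed = c(tis$u_um_s[1], tis$omega_rad_s[1]),
    reference = c(7.07, 0.78))
  meas$deviation_pct <- 100 * (meas$computed - meas$reference) /
    meas$reference
  comp <- rbind(comp, meas)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(comp, file.path(out_dir, "comparison_report.csv"))
  }
  comp
}

#' Read a flat key-value case configuration
#'
#' Reads a YAML (or plain `key: value`) configuration with keys
#' `fluid.mu_Pa_s`, `fluid.rho`, `channel.height_um`, `flow.wss_dyn_cm2` or
#' `flow.shear_rate_per_s`, `flow.profile`, `sphere.d_um`, `sphere.h_um`,
#' and optional `solver.resolution`, `mode`.
#'
#' @param file Path to the configuration file.
#' @return A list with `problem` (a [flow_problem()]), `resolution`, `mode`.
#' @export
read_case_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cf <- yaml::read_yaml(file)
  g <- function(key, default = NULL) if (is.null(cf[[key]])) default else cf[[key]]
  fl <- fluid_properties(mu = g("fluid.mu_Pa_s", 0.0009),
                         rho = g("fluid.rho", 1000))
  ch <- channel_spec(height = g("channel.height_um", 100) * 1e-6)
  co <- flow_conditions(
    wss = if (!is.null(cf[["flow.wss_dyn_cm2"]]))
      dyn_cm2_to_pa(cf[["flow.wss_dyn_cm2"]]) else NULL,
    shear_rate = g("flow.shear_rate_per_s"),
    profile = g("flow.profile", "parabolic"), fluid = fl)
  sp <- sphere_spec(g("sphere.d_um", 10) * 1e-6, g("sphere.h_um", 0.069) * 1e-6)
  list(problem = flow_problem(fl, ch, co, sp),
       resolution = g("solver.resolution", "medium"),
       mode = g("mode", "stationary"))
}
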