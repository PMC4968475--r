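# Minimal legacy-ASCII VTK writers for inspection of meshes, domains and
# fields in standard visualization tools.

#' Export the sphere surface mesh to legacy VTK
#'
#' Writes the facet mesh (quads; polar facets degenerate to triangles) as VTK
#' POLYDATA, optionally with per-facet scalar data such as pressure.
#'
#' @param mesh A [sphere_surface_mesh()].
#' @param file Output path (`.vtk`).
#' @param offset Translation applied to vertices (e.g. `c(0, yc, 0)` to place
#'   the sphere in wall coordinates).
#' @param cell_data Named list of numeric vectors (one value per facet).
#' @return The file path, invisibly.
#' @export
write_vtk_surface <- function(mesh, file, offset = c(0, mesh$sphere$yc, 0),
                              cell_data = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  p <- mesh$panels
  a <- mesh$sphere$a
  corner <- function(th, ph)
    cbind(a * sin(th) * cos(ph), -a * cos(th), a * sin(th) * sin(ph))
  pts <- rbind(corner(p[, 1], p[, 3]), corner(p[, 1], p[, 4]),
               corner(p[, 2], p[, 4]), corner(p[, 2], p[, 3]))
  pts <- sweep(pts, 2, offset, "+")
  n <- nrow(p)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "wallstokes sphere surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", 4 * n)), con)
  utils::write.table(format(pts, digits = 9), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", n, 5 * n), con)
  idx <- cbind(4L, seq_len(n) - 1L, n + seq_len(n) - 1L,
               2L * n + seq_len(n) - 1L, 3L * n + seq_len(n) - 1L)
  utils::write.table(idx, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(cell_data) && length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", n), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 9), con)
    }
  }
  invisible(file)
}

#' Export the reduced-domain outline to legacy VTK
#'
#' Writes the bulged domain outline (four edge polylines along x) as VTK
#' POLYDATA for inspection.
#'
#' @param domain A [reduced_domain()].
#' @param file Output path (`.vtk`).
#' @return The file path, invisibly.
#' @export
write_vtk_domain <- function(domain, file) {
  stopifnot(inherits(domain, "reduced_domain"))
  st <- domain$stations
  n <- nrow(st)
  pts <- rbind(cbind(st$x, 0, -st$width / 2),
               cbind(st$x, 0, st$width / 2),
               cbind(st$x, st$height, -st$width / 2),
               cbind(st$x, st$height, st$width / 2))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "wallstokes reduced domain outline", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", 4 * n)), con)
  utils::write.table(format(pts, digits = 9), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("LINES %d %d", 4L, 4L * (n + 1L)), con)
  for (k in 0:3)
    writeLines(paste(c(n, k * n + seq_len(n) - 1L), collapse = " "), con)
  invisible(file)
}

#' Export the velocity field on a structured grid to legacy VTK
#'
#' Evaluates the solution on a regular grid in wall coordinates and writes a
#' STRUCTURED_POINTS dataset with the velocity vector field.
#'
#' @param sol A [solve_flow()] solution.
#' @param file Output path (`.vtk`).
#' @param nx,ny,nz Grid dimensions.
#' @param bounds List with `x`, `y`, `z` ranges (m); default covers the
#'   neighbourhood of the sphere.
#' @return The file path, invisibly.
#' @export
write_vtk_velocity <- function(sol, file, nx = 24, ny = 16, nz = 9,
                               bounds = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  a <- if (is.null(sol$problem$sphere)) 5e-6 else sol$problem$sphere$a
  if (is.null(bounds))
    bounds <- list(x = c(-4, 4) * a, y = c(1e-3, 4) * a, z = c(-2, 2) * a)
  gx <- seq(bounds$x[1], bounds$x[2], length.out = nx)
  gy <- seq(bounds$y[1], bounds$y[2], length.out = ny)
  gz <- seq(bounds$z[1], bounds$z[2], length.out = nz)
  gr <- expand.grid(x = gx, y = gy, z = gz)   # x fastest: VTK ordering
  u <- evaluate_velocity(sol, as.matrix(gr))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "wallstokes velocity field",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("ORIGIN %g %g %g", gx[1], gy[1], gz[1]),
               sprintf("SPACING %g %g %g", diff(gx[1:2]), diff(gy[1:2]),
                       diff(gz[1:2])),
               sprintf("POINT_DATA %d", nrow(gr)),
               "VECTORS velocity double"), con)
  utils::write.table(format(u, digits = 9), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}
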