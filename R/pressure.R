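#' Tributary area of mesh vertices
#'
#' The tributary (nodal) area of a vertex is one third of the summed areas of
#' its incident triangles, so that the tributary areas of all vertices
#' partition the total surface area exactly.
#'
#' @param mesh a [tri_mesh()].
#' @param vertices integer vertex indices (default all).
#' @return numeric vector of areas (mm^2); errors on an isolated vertex.
#' @export
tributary_area <- function(mesh, vertices = seq_len(nrow(mesh$vertices))) {
  a <- triangle_areas(mesh)
  acc <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    contrib <- tapply(a, mesh$triangles[, k], sum)
    acc[as.integer(names(contrib))] <- acc[as.integer(names(contrib))] + contrib
  }
  out <- acc[vertices] / 3
  if (any(out <= 0))
    stop("isolated vertex (zero tributary area) at index ",
         vertices[which(out <= 0)[1]])
  out
}

#' Nodal contact pressures from a contact solution
#'
#' Converts each active pair's contact force to a nodal pressure by dividing
#' by the vertex's tributary area. Paired-but-inactive vertices (dropped in
#' gap screening or released by the active-set loop) carry zero pressure and
#' are counted in `zero_pressure_count`; summary statistics are reported both
#' including and excluding those zeros (the headline `mean`/`sd`/`max`
#' include them, since uncontacted patches are part of fit quality). The
#' standard deviation uses the population formula (divisor N).
#'
#' @param mesh a [tri_mesh()].
#' @param solution a [solve_contact()] result.
#' @param problem the [build_contact_problem()] the solution came from.
#' @return object of class `pressure_field`: list with `vertex`, `area_mm2`,
#'   `lambda_N`, `pressure_MPa` (aligned vectors over all paired vertices,
#'   zeros included), `zero_pressure_count`, and `summary` (mean, sd, max,
#'   n, plus `mean_nonzero`, `sd_nonzero`).
#' @export
pressures_from_solution <- function(mesh, solution, problem) {
  cand <- problem$all_candidates
  # all paired vertices: candidates dropped by screening get lambda 0
  vert <- cand$face_vertex
  lam <- numeric(length(vert))
  act_vert <- problem$pairs$face_vertex[solution$active]
  lam[match(act_vert, vert)] <- solution$lambda[solution$active]
  area <- tributary_area(mesh, vert)
  p <- lam / area
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  nz <- p[p > 0]
  structure(list(vertex = vert, area_mm2 = area, lambda_N = lam,
                 pressure_MPa = p,
                 zero_pressure_count = sum(p == 0),
                 summary = list(mean = mean(p), sd = pop_sd(p), max = max(p),
                                n = length(p),
                                mean_nonzero = if (length(nz)) mean(nz) else 0,
                                sd_nonzero = if (length(nz)) pop_sd(nz) else 0)),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  s <- x$summary
  cat("Nodal contact pressure field\n")
  cat(sprintf("  paired nodes: %d  zero-pressure nodes: %d\n", s$n, x$zero_pressure_count))
  cat(sprintf("  mean %.4g MPa  sd %.4g  max %.4g (zeros included)\n", s$mean, s$sd, s$max))
  cat(sprintf("  mean %.4g MPa  sd %.4g (contacting nodes only)\n",
              s$mean_nonzero, s$sd_nonzero))
  invisible(x)
}

#' Export a pressure field as CSV
#'
#' Columns: `vertex_id, x, y, z, area_mm2, lambda_N, pressure_MPa`.
#'
#' @param field a [pressures_from_solution()] result.
#' @param mesh the mesh it refers to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(field, mesh, path) {
  v <- mesh$vertices[field$vertex, , drop = FALSE]
  utils::write.csv(data.frame(vertex_id = field$vertex, x = v[, 1], y = v[, 2],
                              z = v[, 3], area_mm2 = field$area_mm2,
                              lambda_N = field$lambda_N,
                              pressure_MPa = field$pressure_MPa),
                   path, row.names = FALSE)
  invisible(path)
}

#' Full-mesh pressure vector for visualization
#'
#' @param field a [pressures_from_solution()] result.
#' @param mesh the mesh it refers to.
#' @return numeric vector over all vertices (MPa), zero off the contact zone;
#'   suitable for [write_mesh()] with `format = "vtk"`.
#' @export
pressure_vertex_field <- function(field, mesh) {
  p <- numeric(nrow(mesh$vertices))
  p[field$vertex] <- field$pressure_MPa
  p
}
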