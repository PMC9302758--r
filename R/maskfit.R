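#' Fit a mask to a face: end-to-end contact pressure analysis
#'
#' The one-call interface of the package. Assembles the flat-shell face
#' stiffness (unless a prebuilt model is supplied), samples the mask design
#' into rigid contact nodes, selects master nodes and statically condenses
#' the face to them, solves the Lagrange-multiplier contact problem at the
#' prescribed push depth, and converts the contact forces to nodal pressures.
#'
#' @param mesh a [tri_mesh()] face surface (open boundary required).
#' @param design a [mask_design()], or a reference-point matrix which is
#'   wrapped in a default design.
#' @param push_depth mask push depth (mm; default 3).
#' @param material a [shell_material()]; default soft-tissue constants.
#' @param direction unit approach axis from face toward mask (default `+Z`).
#' @param model optional precomputed [assemble_stiffness()] result for `mesh`.
#' @param reduced optional precomputed [condense()] result (e.g. shared
#'   across designs); must cover this design's contact footprint.
#' @return object of class `maskfit`: the fitted contact state, with
#'   components `mesh`, `design`, `model`, `reduced`, `problem`, `solution`,
#'   `pressure` and `push_depth`. Methods: [print.maskfit()],
#'   [summary.maskfit()], [coef.maskfit()] (contact forces),
#'   [fitted.maskfit()] (nodal pressures), [residuals.maskfit()] (contact
#'   constraint residuals), [plot.maskfit()].
#' @export
#' @examples
#' face <- generate_synthetic_face(synthetic_face_spec(target_vertex_count = 600))
#' fit <- maskfit(face, mask_reference_points(face), push_depth = 3)
#' fit
#' coef(fit)[1:5]
maskfit <- function(mesh, design, push_depth = 3, material = shell_material(),
                    direction = c(0, 0, 1), model = NULL, reduced = NULL) {
  if (is.matrix(design)) design <- mask_design(design)
  if (is.null(model)) model <- assemble_stiffness(mesh, material)
  mask_nodes <- sample_mask_nodes(design)
  if (is.null(reduced)) {
    masters <- select_master_nodes(mesh, mask_nodes)
    reduced <- condense(model, masters)
  }
  problem <- build_contact_problem(mesh, reduced, mask_nodes, push_depth, direction)
  solution <- solve_contact(reduced, problem)
  pressure <- pressures_from_solution(mesh, solution, problem)
  structure(list(mesh = mesh, design = design, mask_nodes = mask_nodes,
                 model = model, reduced = reduced, problem = problem,
                 solution = solution, pressure = pressure,
                 push_depth = push_depth, direction = direction),
            class = "maskfit")
}

#' @export
print.maskfit <- function(x, ...) {
  cat("Face-mask contact fit\n")
  cat(sprintf("  face: %d nodes (%d DOFs), mask: %d contact nodes, push %.2g mm\n",
              nrow(x$mesh$vertices), x$model$n_dofs, nrow(x$mask_nodes$nodes),
              x$push_depth))
  cat(sprintf("  master DOFs: %d (%s%% of total)\n", x$reduced$n_master_dofs,
              condensation_ratio(x$reduced$n_master_dofs, x$model$n_dofs)))
  s <- x$pressure$summary
  cat(sprintf("  contact pressure: mean %.4g MPa, sd %.4g, max %.4g (%d zero-pressure nodes)\n",
              s$mean, s$sd, s$max, x$pressure$zero_pressure_count))
  invisible(x)
}

#' @export
#' @rdname print.maskfit
#' @param object,x a `maskfit` object.
#' @param ... unused.
summary.maskfit <- function(object, ...) {
  print(object)
  cat(sprintf("  total contact force: %.4g N over %d active pairs (%d candidate pairs)\n",
              object$solution$total_force, sum(object$solution$active),
              nrow(object$problem$pairs) + object$problem$n_dropped))
  cat(sprintf("  constraint residual: %.2e mm; active-set iterations: %d\n",
              object$solution$constraint_residual, object$solution$iterations))
  cat(sprintf("  boundary reaction along push axis: %.4g N\n",
              boundary_reaction(object$reduced, object$solution, object$direction)))
  invisible(object)
}

#' @export
#' @describeIn print.maskfit contact forces (Lagrange multipliers, N) named
#'   by face vertex.
coef.maskfit <- function(object, ...) {
  stats::setNames(object$solution$lambda, object$problem$pairs$face_vertex)
}

#' @export
#' @describeIn print.maskfit nodal contact pressures (MPa) over paired
#'   vertices, zeros included.
fitted.maskfit <- function(object, ...) {
  stats::setNames(object$pressure$pressure_MPa, object$pressure$vertex)
}

#' @export
#' @describeIn print.maskfit contact constraint violations (mm) on active
#'   pairs: penetration minus prescribed gap.
residuals.maskfit <- function(object, ...) {
  act <- object$solution$active
  pen <- as.numeric(Matrix::crossprod(object$problem$C_r[, act, drop = FALSE],
                                      object$solution$u_m))
  stats::setNames(pen - object$problem$pairs$gap[act],
                  object$problem$pairs$face_vertex[act])
}

#' @export
#' @describeIn print.maskfit map of the nodal pressure field: face vertices
#'   in the x-y plane, point size and colour by pressure.
plot.maskfit <- function(x, ...) {
  v <- x$mesh$vertices
  p <- pressure_vertex_field(x$pressure, x$mesh)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::plot(v[, 1], v[, 2], pch = 16, cex = 0.3, col = "grey85",
                 xlab = "x (mm)", ylab = "y (mm)", asp = 1,
                 main = sprintf("Contact pressure, push %.2g mm", x$push_depth), ...)
  on <- p > 0
  if (any(on)) {
    ci <- pmax(1L, ceiling(63 * p[on] / max(p[on])))
    graphics::points(v[on, 1], v[on, 2], pch = 16, cex = 0.8, col = pal[ci])
  }
  zero <- x$pressure$vertex[x$pressure$pressure_MPa == 0]
  if (length(zero))
    graphics::points(v[zero, 1], v[zero, 2], pch = 4, cex = 0.6, col = "steelblue")
  invisible(x)
}

#' Read a solver configuration file
#'
#' YAML with blocks `material` (`E_MPa`, `nu`, `h_mm`, `kappa`,
#' `drilling_factor`), `contact` (`push_depth_mm`, `direction`,
#' `max_active_set_iters`), `mask` (`spacing_mm`) and `solver` (`rel_tol`).
#' Missing keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return list with `material` (a [shell_material()]), `push_depth`,
#'   `direction`, `max_active_set_iters`, `spacing`, `rel_tol`.
#' @export
read_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  m <- cfg$material
  mat <- shell_material(
    E = m$E_MPa %||% 0.03, nu = m$nu %||% 0.49, h = m$h_mm %||% 2,
    kappa = m$kappa %||% (5 / 6),
    drilling_factor = m$drilling_factor %||% 1e-6)
  list(material = mat,
       push_depth = cfg$contact$push_depth_mm %||% 3.0,
       direction = unlist(cfg$contact$direction) %||% c(0, 0, 1),
       max_active_set_iters = cfg$contact$max_active_set_iters %||% 50L,
       spacing = cfg$mask$spacing_mm %||% 1.0,
       rel_tol = cfg$solver$rel_tol %||% 1e-8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
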