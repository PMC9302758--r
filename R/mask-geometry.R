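#' Cross-section profile of the mask contact surface
#'
#' Offsets in the local normal-plane frame of the reference line. The default
#' single point at the origin places the contact nodes on the reference line
#' itself (a contact line); a flat strip of `m` points across a width `w`
#' models a band of contact.
#'
#' @param offsets numeric matrix (m x 2) of in-plane offsets (mm), or `NULL`
#'   for the single-point default.
#' @return object of class `cross_section_profile`.
#' @export
cross_section_profile <- function(offsets = NULL) {
  if (is.null(offsets)) offsets <- matrix(0, 1, 2)
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2 || nrow(offsets) < 1 || any(!is.finite(offsets)))
    stop("`offsets` must be a finite m x 2 matrix")
  structure(list(offsets = offsets), class = "cross_section_profile")
}

#' @rdname cross_section_profile
#' @param width strip width (mm).
#' @param m number of points across the strip.
#' @export
strip_profile <- function(width, m) {
  stopifnot(width > 0, m >= 2)
  cross_section_profile(cbind(seq(-width / 2, width / 2, length.out = m), 0))
}

#' Parametric mask design
#'
#' A mask contact surface described by an ordered closed loop of reference
#' points (through which a periodic cubic spline is fitted), a cross-section
#' profile, and a target arc-length interval between cross-sections.
#'
#' @param reference_points numeric matrix (n x 3), ordered around the closed
#'   loop, n >= 4, consecutive points distinct.
#' @param profile a [cross_section_profile()]; default single point.
#' @param spacing target arc-length interval between cross-sections (mm).
#' @param design_id optional identifier carried through sweeps.
#' @return object of class `mask_design`.
#' @export
mask_design <- function(reference_points, profile = cross_section_profile(),
                        spacing = 1.0, design_id = "design") {
  reference_points <- as.matrix(reference_points)
  if (ncol(reference_points) != 3 || nrow(reference_points) < 4)
    stop("`reference_points` must be an n x 3 matrix with n >= 4")
  if (!is.finite(spacing) || spacing <= 0) stop("`spacing` must be positive")
  d <- rbind(diff(reference_points),
             reference_points[1, ] - reference_points[nrow(reference_points), ])
  if (any(sqrt(rowSums(d^2)) <= 1e-6))
    stop("consecutive reference points coincide")
  if (!inherits(profile, "cross_section_profile"))
    stop("`profile` must be a cross_section_profile")
  structure(list(reference_points = reference_points, profile = profile,
                 spacing = spacing, design_id = design_id),
            class = "mask_design")
}

#' @export
print.mask_design <- function(x, ...) {
  cat(sprintf("Mask design '%s': %d reference points, %d-point profile, %.2g mm spacing\n",
              x$design_id, nrow(x$reference_points), nrow(x$profile$offsets), x$spacing))
  invisible(x)
}

#' Translate selected reference points along an axis
#'
#' Returns a new design with the named reference points moved by `offset`
#' millimetres along the given axis; the input design is unchanged. This is
#' the elementary design adjustment that sweeps enumerate.
#'
#' @param design a [mask_design()].
#' @param point_indices integer indices of reference points to move.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param offset signed distance (mm).
#' @return a new `mask_design`.
#' @export
adjust_reference_points <- function(design, point_indices, axis = c("x", "y", "z"),
                                    offset) {
  axis <- match.arg(tolower(axis), c("x", "y", "z"))
  point_indices <- as.integer(point_indices)
  if (any(point_indices < 1L | point_indices > nrow(design$reference_points)))
    stop("point index out of range")
  ax <- match(axis, c("x", "y", "z"))
  pts <- design$reference_points
  pts[point_indices, ax] <- pts[point_indices, ax] + offset
  mask_design(pts, design$profile, design$spacing, design$design_id)
}

# Dense arc-length table of the whole loop: parameter grid with `per_piece`
# subintervals per spline piece and composite-Simpson cumulative arc length.
# Simpson on the smooth speed gives relative errors far below 1e-6 at the
# default resolution; the table also serves to invert s(p).
arclength_table <- function(spline, per_piece = 100L) {
  n <- length(spline$knots) - 1L
  per_piece <- 2L * ceiling(per_piece / 2)  # even, for Simpson pairs
  pg <- unlist(lapply(seq_len(n), function(k)
    seq(spline$knots[k], spline$knots[k + 1],
        length.out = per_piece + 1L)[-(per_piece + 1L)]))
  pg <- c(pg, spline$knots[n + 1])
  sp <- sqrt(rowSums(evaluate_spline(spline, pg, 1L)^2))
  m <- length(pg)
  h <- diff(pg)
  # Simpson over consecutive point pairs (uniform h within each piece)
  inc <- numeric(m - 1)
  odd <- seq(1, m - 2, by = 2)
  mid <- sp[odd + 1]
  simp <- (h[odd] + h[odd + 1]) / 6 * (sp[odd] + 4 * mid + sp[odd + 2])
  # split each Simpson pair back into two increments via local quadratic
  inc[odd] <- h[odd] / 6 * (2.5 * sp[odd] + 4 * mid - 0.5 * sp[odd + 2])
  inc[odd + 1] <- simp - inc[odd]
  list(p = pg, s = c(0, cumsum(inc)))
}

spline_piece_lengths <- function(spline, table = NULL) {
  if (is.null(table)) table <- arclength_table(spline)
  n <- length(spline$knots) - 1L
  s_at_knots <- stats::approx(table$p, table$s, xout = spline$knots)$y
  diff(s_at_knots)
}

# Parameter values at given arc lengths from the loop start (s in [0, L)),
# by monotone inverse interpolation of the dense arc-length table.
arclength_to_parameter <- function(spline, s_targets, table = NULL) {
  if (is.null(table)) table <- arclength_table(spline)
  stats::approx(table$s, table$p, xout = s_targets, rule = 2)$y
}

# Rotation-minimizing frames along the curve via the double-reflection
# method; returns list of per-origin orthonormal (normal1, normal2) spanning
# the plane orthogonal to the tangent.
rotation_minimizing_frames <- function(origins, tangents) {
  n <- nrow(origins)
  t1 <- tangents / sqrt(rowSums(tangents^2))
  # initial normal: any vector orthogonal to t1[1,]
  a <- if (abs(t1[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  r <- a - sum(a * t1[1, ]) * t1[1, ]
  r <- r / sqrt(sum(r^2))
  N1 <- matrix(0, n, 3); N1[1, ] <- r
  for (i in seq_len(n - 1)) {
    v1 <- origins[i + 1, ] - origins[i, ]
    c1 <- sum(v1 * v1)
    rL <- N1[i, ] - (2 / c1) * sum(v1 * N1[i, ]) * v1
    tL <- t1[i, ] - (2 / c1) * sum(v1 * t1[i, ]) * v1
    v2 <- t1[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    N1[i + 1, ] <- rL - (2 / c2) * sum(v2 * rL) * v2
  }
  N2 <- cbind(t1[, 2] * N1[, 3] - t1[, 3] * N1[, 2],
              t1[, 3] * N1[, 1] - t1[, 1] * N1[, 3],
              t1[, 1] * N1[, 2] - t1[, 2] * N1[, 1])
  list(N1 = N1, N2 = N2, T = t1)
}

#' Sample the rigid contact nodes of a mask design
#'
#' Fits the periodic spline through the reference points, measures the total
#' arc length by adaptive quadrature, places `round(L / spacing)` (at least
#' 8) cross-section origins equally spaced in arc length, and maps the
#' profile offsets into the plane normal to the curve tangent at each origin
#' using a rotation-minimizing frame.
#'
#' @param design a [mask_design()].
#' @return object of class `mask_nodes`: list with `nodes` (N x 3 matrix,
#'   mm), `section_index` (integer per node), `n_sections`, `arc_length`,
#'   `design_id`, `spline` and the per-section `frames`.
#' @export
sample_mask_nodes <- function(design) {
  spline <- fit_periodic_spline(design$reference_points)
  tab <- arclength_table(spline)
  L <- tab$s[length(tab$s)]
  n_sec <- max(8L, as.integer(round(L / design$spacing)))
  s <- (seq_len(n_sec) - 1L) * L / n_sec
  par <- arclength_to_parameter(spline, s, tab)
  origins <- evaluate_spline(spline, par)
  tangents <- evaluate_spline(spline, par, 1L)
  fr <- rotation_minimizing_frames(origins, tangents)
  off <- design$profile$offsets
  m <- nrow(off)
  nodes <- matrix(0, n_sec * m, 3)
  for (i in seq_len(n_sec)) {
    rows <- (i - 1L) * m + seq_len(m)
    nodes[rows, ] <- origins[rep(i, m), , drop = FALSE] +
      off[, 1] %o% fr$N1[i, ] + off[, 2] %o% fr$N2[i, ]
  }
  structure(list(nodes = nodes,
                 section_index = rep(seq_len(n_sec), each = m),
                 n_sections = n_sec, arc_length = L,
                 design_id = design$design_id, spline = spline, frames = fr),
            class = "mask_nodes")
}

#' @export
print.mask_nodes <- function(x, ...) {
  cat(sprintf("Mask node set '%s': %d nodes in %d cross-sections, loop length %.1f mm\n",
              x$design_id, nrow(x$nodes), x$n_sections, x$arc_length))
  invisible(x)
}

#' Export mask nodes
#'
#' @param mask a [sample_mask_nodes()] result.
#' @param path output path.
#' @param format `"csv"` (columns x, y, z, section) or `"obj"` (point cloud).
#' @return `path`, invisibly.
#' @export
write_mask_nodes <- function(mask, path, format = c("csv", "obj")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(x = mask$nodes[, 1], y = mask$nodes[, 2],
                                z = mask$nodes[, 3], section = mask$section_index),
                     path, row.names = FALSE)
  } else {
    writeLines(c("# maskfit mask nodes (mm)",
                 sprintf("v %.9g %.9g %.9g", mask$nodes[, 1], mask$nodes[, 2],
                         mask$nodes[, 3])), path)
  }
  invisible(path)
}

#' Read mask reference points from JSON
#'
#' The file holds a JSON object `{"points": [[x,y,z], ...], "closed": true}`
#' (a bare JSON list of points is also accepted).
#'
#' @param path JSON file path.
#' @return numeric matrix (n x 3), ordered around the loop.
#' @export
read_reference_points <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- if (is.list(obj) && !is.null(obj$points)) obj$points else obj
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop("reference points must be [x, y, z] triples")
  pts
}

#' @rdname read_reference_points
#' @param points numeric matrix (n x 3).
#' @export
write_reference_points <- function(points, path) {
  jsonlite::write_json(list(points = as.matrix(points), closed = TRUE), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
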