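#' Triangulated surface mesh
#'
#' Container for an open or closed triangulated surface in millimetres, the
#' geometric substrate of the face model. Landmarks are stored as vertex
#' indices so that they stay attached to the surface under any operation that
#' preserves vertex identity.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @param landmarks optional named integer vector mapping landmark names (e.g.
#'   `"sellion"`, `"pronasale"`) to vertex indices.
#' @param validate logical; check the mesh invariants (default `TRUE`).
#'
#' @return An object of class `tri_mesh`: a list with elements `vertices`,
#'   `triangles`, `landmarks` and `boundary_vertices` (indices of vertices on
#'   open edges, i.e. edges used by exactly one triangle).
#' @export
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' m <- tri_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)))
#' m$boundary_vertices  # every vertex of a two-triangle strip is on the rim
tri_mesh <- function(vertices, triangles, landmarks = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z in mm)")
  if (ncol(triangles) != 3L) stop("`triangles` must have 3 columns of vertex indices")
  if (!is.null(landmarks)) {
    landmarks <- vapply(landmarks, as.integer, integer(1))
    if (is.null(names(landmarks)) || any(!nzchar(names(landmarks))))
      stop("`landmarks` must be a named vector")
  }
  mesh <- structure(
    list(vertices = vertices, triangles = triangles, landmarks = landmarks,
         boundary_vertices = integer(0)),
    class = "tri_mesh")
  mesh$boundary_vertices <- boundary_vertex_set(mesh)
  if (validate) validate_tri_mesh(mesh)
  mesh
}

#' Validate a `tri_mesh`
#'
#' Checks the structural invariants: finite coordinates, in-range triangle
#' indices, no repeated vertex within a triangle, and no degenerate triangle
#' (area below `1e-9` mm^2).
#'
#' @param mesh a [tri_mesh()].
#' @return `mesh`, invisibly; errors describe the first violated invariant.
#' @export
validate_tri_mesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(v) < 3L) stop("mesh needs at least 3 vertices")
  if (!all(is.finite(v))) stop("vertex coordinates must be finite")
  if (any(tr < 1L) || any(tr > nrow(v)))
    stop("triangle refers to vertex index outside 1..", nrow(v))
  if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
    stop("triangle repeats a vertex index")
  a <- triangle_areas(mesh)
  if (any(a <= 1e-9)) {
    bad <- which(a <= 1e-9)[1]
    stop("degenerate (zero-area) triangle at row ", bad)
  }
  if (!is.null(mesh$landmarks) &&
      (any(mesh$landmarks < 1L) || any(mesh$landmarks > nrow(v))))
    stop("landmark index out of range")
  invisible(mesh)
}

#' Triangle areas of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return numeric vector of triangle areas (mm^2), one per triangle row.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Triangle unit normals
#'
#' @param mesh a [tri_mesh()].
#' @return numeric matrix (n_triangles x 3) of unit normals following the
#'   right-hand rule on the stored vertex order.
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

# Undirected edge table: one row per triangle edge, columns (min, max) index.
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Vertices on open (boundary) edges
#'
#' An edge is open when it is used by exactly one triangle; the boundary
#' vertex set is every vertex incident to such an edge. A closed surface has
#' an empty boundary set. These vertices receive the fixed (clamped) boundary
#' condition in the face model.
#'
#' @param mesh a [tri_mesh()].
#' @return sorted integer vector of boundary vertex indices.
#' @export
boundary_vertex_set <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- e[, 1] * (nrow(mesh$vertices) + 1) + e[, 2]
  cnt <- tabulate(match(key, unique(key)))
  open_keys <- unique(key)[cnt == 1L]
  open <- e[key %in% open_keys, , drop = FALSE]
  sort(unique(as.integer(open)))
}

# Edge multiplicities keyed by (min,max) pair; used by manifold checks.
edge_multiplicities <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2], sep = "-")
  table(key)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("Triangulated surface mesh (mm)\n")
  cat(sprintf("  vertices : %d\n", nrow(x$vertices)))
  cat(sprintf("  triangles: %d\n", nrow(x$triangles)))
  cat(sprintf("  boundary vertices: %d%s\n", length(x$boundary_vertices),
              if (length(x$boundary_vertices) == 0) " (closed surface)" else ""))
  if (!is.null(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tri_mesh <- function(object, ...) {
  a <- triangle_areas(object)
  cat("Triangulated surface mesh summary\n")
  print(object)
  cat(sprintf("  total area: %.2f mm^2\n", sum(a)))
  cat(sprintf("  triangle area range: [%.4g, %.4g] mm^2\n", min(a), max(a)))
  bb <- apply(object$vertices, 2, range)
  cat(sprintf("  bounding box: x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(object)
}

#' Remove vertices (and incident triangles) from a mesh
#'
#' Utility for trimming a mesh to an exact vertex count or cutting away a
#' region; remaining vertices are re-indexed densely and landmarks that
#' survive are remapped.
#'
#' @param mesh a [tri_mesh()].
#' @param drop integer vector of vertex indices to remove.
#' @return a new `tri_mesh`.
#' @export
drop_vertices <- function(mesh, drop) {
  drop <- unique(as.integer(drop))
  keep <- setdiff(seq_len(nrow(mesh$vertices)), drop)
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  tr <- mesh$triangles
  tr_keep <- !(tr[, 1] %in% drop | tr[, 2] %in% drop | tr[, 3] %in% drop)
  tr <- tr[tr_keep, , drop = FALSE]
  tr[] <- remap[tr]
  lm <- mesh$landmarks
  if (!is.null(lm)) {
    lm <- lm[!(lm %in% drop)]
    if (length(lm)) lm[] <- remap[lm] else lm <- NULL
  }
  tri_mesh(mesh$vertices[keep, , drop = FALSE], tr, landmarks = lm)
}
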