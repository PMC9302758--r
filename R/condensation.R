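#' Select master nodes covering a family of mask designs
#'
#' For every contact node of every mask variant, finds the nearest face
#' triangle (exact point-to-triangle distance, with a vertex-proximity
#' prefilter standing in for a spatial index) and collects that triangle's
#' three vertices. The union over all variants, minus the clamped boundary
#' vertices, is the master set: the face vertices any candidate mask can
#' touch.
#'
#' @param mesh a [tri_mesh()].
#' @param mask_variants a single [sample_mask_nodes()] result or a list of
#'   them (one per design variant).
#' @param max_distance sanity bound (mm): error if a mask node is farther
#'   than this from the face.
#' @return sorted integer vector of master vertex indices.
#' @export
select_master_nodes <- function(mesh, mask_variants, max_distance = 50) {
  if (inherits(mask_variants, "mask_nodes")) mask_variants <- list(mask_variants)
  sel <- integer(0)
  worst <- 0
  for (mv in mask_variants) {
    nt <- nearest_triangles(mesh, mv$nodes)
    worst <- max(worst, max(nt$distance))
    sel <- union(sel, as.integer(mesh$triangles[nt$triangle, ]))
  }
  if (worst > max_distance)
    stop(sprintf("mask is far from the face (max node-to-surface distance %.1f mm)",
                 worst))
  sel <- sort(setdiff(sel, mesh$boundary_vertices))
  if (length(sel) == 0)
    stop("master set is empty; the mask does not face any free vertices")
  sel
}

# Nearest face triangle for each query point: exact point-to-triangle
# distances over a candidate set obtained from nearest-vertex proximity
# (a triangle closer than the nearest vertex must have a vertex within the
# nearest-vertex distance plus the longest edge).
nearest_triangles <- function(mesh, points) {
  v <- mesh$vertices; tr <- mesh$triangles
  np <- nrow(points)
  edges <- rbind(v[tr[, 2], ] - v[tr[, 1], ], v[tr[, 3], ] - v[tr[, 2], ],
                 v[tr[, 1], ] - v[tr[, 3], ])
  e_max <- sqrt(max(rowSums(edges^2)))
  # vertex -> incident triangle lists
  vt <- split(rep(seq_len(nrow(tr)), 3), as.integer(tr))
  tri_id <- integer(np); dist <- numeric(np)
  for (q in seq_len(np)) {
    p <- points[q, ]
    d2v <- (v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2
    dv <- sqrt(min(d2v))
    cand_v <- which(d2v <= (dv + e_max)^2)
    cand_t <- unique(unlist(vt[as.character(cand_v)], use.names = FALSE))
    d <- point_triangle_distances(p, v, tr[cand_t, , drop = FALSE])
    best <- which.min(d)
    tri_id[q] <- cand_t[best]
    dist[q] <- d[best]
  }
  list(triangle = tri_id, distance = dist)
}

# Exact distances from point p to each triangle in `tris` (rows of vertex
# indices into v); vectorized region classification on barycentric clamping.
point_triangle_distances <- function(p, v, tris) {
  a <- v[tris[, 1], , drop = FALSE]
  b <- v[tris[, 2], , drop = FALSE]
  c_ <- v[tris[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  ap <- rep(p, each = nrow(a)) - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- rep(p, each = nrow(a)) - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- rep(p, each = nrow(a)) - c_
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(a)
  closest <- matrix(0, n, 3)
  done <- logical(n)
  set_pt <- function(idx, pts) {
    closest[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  r1 <- !done & d1 <= 0 & d2 <= 0
  if (any(r1)) set_pt(r1, a[r1, , drop = FALSE])
  r2 <- !done & d3 >= 0 & d4 <= d3
  if (any(r2)) set_pt(r2, b[r2, , drop = FALSE])
  r3 <- !done & d6 >= 0 & d5 <= d6
  if (any(r3)) set_pt(r3, c_[r3, , drop = FALSE])
  r4 <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r4)) {
    t <- d1[r4] / (d1[r4] - d3[r4])
    set_pt(r4, a[r4, , drop = FALSE] + t * ab[r4, , drop = FALSE])
  }
  r5 <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r5)) {
    t <- d2[r5] / (d2[r5] - d6[r5])
    set_pt(r5, a[r5, , drop = FALSE] + t * ac[r5, , drop = FALSE])
  }
  r6 <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r6)) {
    t <- (d4[r6] - d3[r6]) / ((d4[r6] - d3[r6]) + (d5[r6] - d6[r6]))
    set_pt(r6, b[r6, , drop = FALSE] + t * (c_[r6, , drop = FALSE] - b[r6, , drop = FALSE]))
  }
  rin <- !done
  if (any(rin)) {
    denom <- va[rin] + vb[rin] + vc[rin]
    w2 <- vb[rin] / denom; w3 <- vc[rin] / denom
    set_pt(rin, a[rin, , drop = FALSE] + w2 * ab[rin, , drop = FALSE] +
             w3 * ac[rin, , drop = FALSE])
  }
  sqrt(rowSums((closest - rep(p, each = n))^2))
}

#' Statically condense the face model to its master nodes
#'
#' Partitions the free DOFs into master (all 6 DOFs of each master node) and
#' slave, and forms the reduced stiffness `K_r = K_m - K_c' K_slave^-1 K_c`
#' by one sparse Cholesky factorization of the slave block and multi-RHS
#' solves; the slave inverse is never formed. The factorization is kept for
#' exact slave-displacement recovery, so the reduced model reproduces the
#' full solve whenever no force acts on slave DOFs.
#'
#' @param model a [assemble_stiffness()] result.
#' @param master_nodes integer vertex indices; must be disjoint from the
#'   clamped boundary vertices.
#' @return object of class `reduced_model`: list with `master_nodes`,
#'   `master_dofs` (global DOF indices), dense symmetric `K_r`, `K_r_chol`,
#'   `n_master_dofs`, `n_slave_dofs`, `n_dofs`, `slave_dofs`, and the slave
#'   factorization handle.
#' @export
condense <- function(model, master_nodes) {
  master_nodes <- sort(unique(as.integer(master_nodes)))
  if (any(master_nodes %in% model$mesh$boundary_vertices))
    stop("master nodes must be disjoint from clamped boundary vertices")
  if (any(master_nodes < 1 | master_nodes > nrow(model$mesh$vertices)))
    stop("master node index out of range")
  master_dofs <- as.integer(outer(1:6, (master_nodes - 1L) * 6L, `+`))
  master_dofs <- sort(master_dofs)
  slave_dofs <- setdiff(model$free_dofs, master_dofs)
  Kmm <- as.matrix(model$K_f[master_dofs, master_dofs])
  if (length(slave_dofs) > 0) {
    Kss <- Matrix::forceSymmetric(model$K_f[slave_dofs, slave_dofs])
    Ksc <- model$K_f[slave_dofs, master_dofs, drop = FALSE]
    ch <- tryCatch(Matrix::Cholesky(Kss, LDL = FALSE),
                   error = function(e)
                     stop("slave stiffness block is singular; insufficient boundary conditions"))
    X <- as.matrix(Matrix::solve(ch, Ksc))   # K_slave^-1 K_c
    K_r <- Kmm - as.matrix(Matrix::crossprod(Ksc, X))
    K_r <- (K_r + t(K_r)) / 2
  } else {
    ch <- NULL
    K_r <- (Kmm + t(Kmm)) / 2
  }
  structure(list(master_nodes = master_nodes, master_dofs = master_dofs,
                 slave_dofs = slave_dofs, K_r = K_r,
                 K_r_chol = chol(K_r),
                 slave_chol = ch, n_master_dofs = length(master_dofs),
                 n_slave_dofs = length(slave_dofs), n_dofs = model$n_dofs,
                 model = model),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("Statically condensed face model\n")
  cat(sprintf("  master nodes: %d  master DOFs: %d  slave DOFs: %d\n",
              length(x$master_nodes), x$n_master_dofs, x$n_slave_dofs))
  cat(sprintf("  master fraction: %s%% of %d total DOFs\n",
              condensation_ratio(x$n_master_dofs, x$n_dofs), x$n_dofs))
  invisible(x)
}

#' Master-DOF fraction of a condensed model
#'
#' @param n_master_dofs,n_total_dofs partition sizes.
#' @return percentage of total DOFs retained as masters, rounded to 0.1.
#' @export
condensation_ratio <- function(n_master_dofs, n_total_dofs) {
  round(100 * n_master_dofs / n_total_dofs, 1)
}

#' Recover the full displacement field from a master solution
#'
#' The slave part is `-K_slave^-1 K_c u_m` (no slave forces), computed with
#' the stored factorization; fixed DOFs are zero.
#'
#' @param reduced a [condense()] result.
#' @param u_m numeric master displacement vector (length `n_master_dofs`).
#' @return full displacement vector of length `n_dofs`.
#' @export
recover_full_displacement <- function(reduced, u_m) {
  stopifnot(length(u_m) == reduced$n_master_dofs)
  u <- numeric(reduced$n_dofs)
  u[reduced$master_dofs] <- u_m
  if (reduced$n_slave_dofs > 0) {
    Ksc <- reduced$model$K_f[reduced$slave_dofs, reduced$master_dofs, drop = FALSE]
    u[reduced$slave_dofs] <- -as.numeric(Matrix::solve(reduced$slave_chol, Ksc %*% u_m))
  }
  u
}

#' Serialize / restore a reduced model for sweep reuse
#'
#' Writes the master indices and the dense reduced stiffness as a compressed
#' text archive. The slave factorization is not stored; restoring against
#' the same model rebuilds it on demand.
#'
#' @param reduced a [condense()] result.
#' @param path output file (gzip-compressed JSON).
#' @return `path` invisibly; `load_reduced_model()` returns a `reduced_model`.
#' @export
save_reduced_model <- function(reduced, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(
    master_nodes = reduced$master_nodes,
    n_dofs = reduced$n_dofs,
    K_r = reduced$K_r), digits = NA), con)
  invisible(path)
}

#' @rdname save_reduced_model
#' @param model the [assemble_stiffness()] result the archive was built from.
#' @export
load_reduced_model <- function(path, model) {
  obj <- jsonlite::fromJSON(readLines(gzfile(path)))
  red <- condense(model, obj$master_nodes)
  stopifnot(max(abs(red$K_r - obj$K_r)) < 1e-8 * max(abs(red$K_r)))
  red
}
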