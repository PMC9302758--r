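#' Build a node-to-node face-mask contact problem
#'
#' Pairs every mask contact node with its nearest master face vertex (when
#' several mask nodes map to one vertex the closest wins), measures the
#' initial clearance along the approach axis, and keeps the pairs that the
#' prescribed push depth actually closes. With `direction` the unit vector
#' from the face toward the mask (default `+Z`), the clearance of a pair is
#' `(mask - face) . direction` and the prescribed penetration is
#' `d_f = push_depth - clearance`; pairs with `d_f <= 0` never touch at this
#' push depth and are dropped (they are the zero-pressure regions of a badly
#' fitting design).
#'
#' @param mesh a [tri_mesh()].
#' @param reduced a [condense()] result for the same mesh.
#' @param mask_nodes a [sample_mask_nodes()] result.
#' @param push_depth how far the rigid mask is pushed toward the face (mm);
#'   > 0.
#' @param direction unit 3-vector from face toward mask (default `c(0,0,1)`).
#' @return object of class `contact_problem`: list with `pairs` (data frame:
#'   `face_vertex`, `mask_node`, `clearance`, `gap`), dropped pair count,
#'   `C_r` (master-DOF x pair sparse incidence, constraint
#'   `t(C_r) %*% u_m = gap`), `push_depth`, `direction`, `f_r`.
#' @export
build_contact_problem <- function(mesh, reduced, mask_nodes, push_depth = 3,
                                  direction = c(0, 0, 1)) {
  if (!is.finite(push_depth) || push_depth <= 0) stop("push_depth must be > 0")
  direction <- direction / sqrt(sum(direction^2))
  mv <- mesh$vertices[reduced$master_nodes, , drop = FALSE]
  pts <- mask_nodes$nodes
  # nearest master vertex per mask node
  nn <- vapply(seq_len(nrow(pts)), function(i)
    which.min((mv[, 1] - pts[i, 1])^2 + (mv[, 2] - pts[i, 2])^2 +
                (mv[, 3] - pts[i, 3])^2), integer(1))
  d2 <- rowSums((mv[nn, , drop = FALSE] - pts)^2)
  # one pair per face vertex: the closest mask node wins
  ord <- order(nn, d2)
  keep <- ord[!duplicated(nn[ord])]
  face_vertex <- reduced$master_nodes[nn[keep]]
  mask_node <- keep
  clearance <- as.numeric((pts[keep, , drop = FALSE] -
                             mesh$vertices[face_vertex, , drop = FALSE]) %*% direction)
  gap <- push_depth - clearance
  dropped <- sum(gap <= 0)
  sel <- gap > 0
  pairs <- data.frame(face_vertex = face_vertex[sel], mask_node = mask_node[sel],
                      clearance = clearance[sel], gap = gap[sel])
  if (nrow(pairs) == 0)
    stop("no contact at this push depth (all clearances exceed ", push_depth, " mm)")
  # constraint matrix on master DOFs: the displacement of the paired vertex
  # along -direction (into the face) equals the gap
  C_r <- contact_incidence(reduced, pairs$face_vertex, direction)
  structure(list(pairs = pairs, n_dropped = dropped, C_r = C_r,
                 push_depth = push_depth, direction = direction,
                 f_r = numeric(reduced$n_master_dofs),
                 all_candidates = data.frame(face_vertex = face_vertex,
                                             gap = gap)),
            class = "contact_problem")
}

# Sparse master-DOF x pair matrix whose column j holds -direction in the
# translation DOFs of paired vertex j: t(C) %*% u_m is the penetration of the
# face along the push axis.
contact_incidence <- function(reduced, face_vertices, direction) {
  npair <- length(face_vertices)
  pos <- match(face_vertices, reduced$master_nodes)
  base <- (pos - 1L) * 6L  # master-local DOF offset of the vertex
  i <- as.integer(outer(1:3, base, `+`))
  j <- rep(seq_len(npair), each = 3)
  x <- rep(-direction, npair)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(reduced$n_master_dofs, npair))
}

#' @export
print.contact_problem <- function(x, ...) {
  cat(sprintf("Face-mask contact problem: %d pairs (%d dropped, gap <= 0), push %.2g mm\n",
              nrow(x$pairs), x$n_dropped, x$push_depth))
  invisible(x)
}

#' Solve the reduced Lagrange-multiplier contact problem
#'
#' Solves the saddle-point system that constrains each paired face vertex to
#' the rigid mask surface, by block elimination through the reduced
#' stiffness: `S = t(C) K_r^-1 C`, `lambda = S^-1 (t(C) K_r^-1 f_r + d_f)`,
#' `u_m = K_r^-1 (f_r + C lambda)` with signs arranged so that compressive
#' contact forces are positive. Pairs whose multiplier comes out tensile
#' (negative) are removed and the system re-solved (active-set loop) until
#' every retained multiplier is non-negative.
#'
#' @param reduced a [condense()] result.
#' @param problem a [build_contact_problem()] result.
#' @param max_iters active-set iteration cap (default 50).
#' @param K_r_inv optional precomputed dense inverse of `K_r` (used by design
#'   sweeps to amortize the factorization).
#' @return object of class `contact_solution`: list with `u_m` (master
#'   displacements, mm), `lambda` (contact force per active pair, N),
#'   `active` (logical over `problem$pairs` rows), `iterations`,
#'   `constraint_residual` and `total_force`.
#' @export
solve_contact <- function(reduced, problem, max_iters = 50L, K_r_inv = NULL) {
  C_all <- problem$C_r
  gap <- problem$pairs$gap
  f_r <- problem$f_r
  npair <- length(gap)
  # K_r^-1 C and K_r^-1 f via the stored Cholesky (or a precomputed inverse)
  solve_K <- function(B) {
    if (!is.null(K_r_inv)) K_r_inv %*% B
    else backsolve(reduced$K_r_chol,
                   backsolve(reduced$K_r_chol, as.matrix(B), transpose = TRUE))
  }
  KiC <- as.matrix(solve_K(C_all))
  Kif <- if (any(f_r != 0)) as.numeric(solve_K(f_r)) else numeric(reduced$n_master_dofs)
  S_all <- as.matrix(Matrix::crossprod(C_all, KiC))
  rhs_all <- as.numeric(Matrix::crossprod(C_all, Kif)) + gap
  active <- rep(TRUE, npair)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    idx <- which(active)
    if (length(idx) == 0)
      stop("active set became empty; no compressive contact at this configuration")
    S <- S_all[idx, idx, drop = FALSE]
    lam <- tryCatch(solve(S, rhs_all[idx]), error = function(e)
      stop("singular contact Schur complement (duplicate constraints among pairs ",
           paste(utils::head(idx, 5), collapse = ", "), " ...)"))
    if (all(lam >= 0) || iter >= max_iters) break
    active[idx[lam < 0]] <- FALSE
  }
  lambda <- numeric(npair)
  lambda[idx] <- lam
  u_m <- as.numeric(Kif + KiC[, idx, drop = FALSE] %*% lam)
  resid <- as.numeric(Matrix::crossprod(C_all[, idx, drop = FALSE], u_m)) - gap[idx]
  structure(list(u_m = u_m, lambda = lambda, active = active,
                 iterations = iter,
                 constraint_residual = if (length(resid)) max(abs(resid)) else 0,
                 total_force = sum(lam)),
            class = "contact_solution")
}

#' @export
print.contact_solution <- function(x, ...) {
  cat(sprintf("Contact solution: %d active pairs, total force %.4g N, %d active-set iteration(s)\n",
              sum(x$active), x$total_force, x$iterations))
  cat(sprintf("  constraint residual: %.2e mm\n", x$constraint_residual))
  invisible(x)
}

#' Boundary reaction transmitted along the push axis
#'
#' Recovers the full displacement field, forms `K_f u`, and sums the
#' reaction force at the clamped boundary DOFs along the push direction. In
#' static equilibrium this balances the total contact force.
#'
#' @param reduced a [condense()] result.
#' @param solution a [solve_contact()] result.
#' @param direction unit push axis used in the contact problem.
#' @return scalar reaction force (N), positive toward the mask.
#' @export
boundary_reaction <- function(reduced, solution, direction = c(0, 0, 1)) {
  u <- recover_full_displacement(reduced, solution$u_m)
  r <- as.numeric(reduced$model$K_f %*% u)
  fixed <- reduced$model$fixed_dofs
  # translation DOFs of each fixed vertex, dotted with the push axis
  vert <- (fixed - 1L) %/% 6L
  comp <- (fixed - 1L) %% 6L + 1L
  tsel <- comp <= 3L
  sum(r[fixed[tsel]] * direction[comp[tsel]])
}
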