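# Shared fixtures, generated in code.

# flat rectangular grid in the xy plane, (n+1)^2 vertices over side `a`
grid_mesh <- function(n, a = 100, z = function(x, y) 0 * x) {
  xs <- seq(0, a, length.out = n + 1)
  g <- expand.grid(x = xs, y = xs, KEEP.OUT.ATTRS = FALSE)
  nc <- n + 1
  i <- rep(seq_len(n), n); j <- rep(seq_len(n), each = n)
  v00 <- (j - 1) * nc + i; v10 <- v00 + 1L; v01 <- v00 + nc; v11 <- v01 + 1L
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  tri_mesh(cbind(g$x, g$y, z(g$x, g$y)), tris)
}

# closed tetrahedron surface (no boundary)
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tri_mesh(v, rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# closed icosahedron surface
icosa_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  tri_mesh(v, f)
}

# small synthetic face (cached per size within a test run)
small_face <- local({
  cache <- list()
  function(n = 400, seed = 1) {
    key <- paste(n, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_synthetic_face(
        synthetic_face_spec(target_vertex_count = n, seed = seed))
    cache[[key]]
  }
})

# reference loop of n points on a circle of radius r in the xy plane
circle_loop <- function(n, r = 10, z = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th), z)
}

# sparse full-system contact oracle: augmented saddle solve (LU) on the
# unreduced free DOFs, scaling to a few thousand nodes
sparse_contact_oracle <- function(model, pairs_vertex, gaps, direction = c(0, 0, 1)) {
  free <- model$free_dofs
  nf <- length(free)
  Kff <- model$K_f[free, free]
  np <- length(pairs_vertex)
  dof_rows <- match(as.integer(outer(1:3, (pairs_vertex - 1L) * 6L, `+`)), free)
  C <- Matrix::sparseMatrix(i = dof_rows, j = rep(seq_len(np), each = 3),
                            x = rep(-direction, np), dims = c(nf, np))
  active <- rep(TRUE, np)
  repeat {
    idx <- which(active)
    Ca <- C[, idx, drop = FALSE]
    A <- rbind(cbind(Kff, -Ca),
               cbind(Matrix::t(Ca), Matrix::Matrix(0, length(idx), length(idx))))
    sol <- as.numeric(Matrix::solve(A, c(numeric(nf), gaps[idx])))
    lam <- sol[nf + seq_along(idx)]
    if (all(lam >= 0)) break
    active[idx[lam < 0]] <- FALSE
  }
  u <- numeric(model$n_dofs)
  u[free] <- sol[seq_len(nf)]
  lambda <- numeric(np)
  lambda[idx] <- lam
  list(u = u, lambda = lambda, active = active)
}

# brute-force full-system contact oracle: dense augmented saddle solve on the
# unreduced free DOFs (mask rigid, so only the face block and constraints)
dense_contact_oracle <- function(model, pairs_vertex, gaps, direction = c(0, 0, 1)) {
  free <- model$free_dofs
  K <- as.matrix(model$K_f[free, free])
  np <- length(pairs_vertex)
  C <- matrix(0, length(free), np)
  for (j in seq_len(np)) {
    dofs <- (pairs_vertex[j] - 1L) * 6L + 1:3
    C[match(dofs, free), j] <- -direction
  }
  active <- rep(TRUE, np)
  repeat {
    idx <- which(active)
    A <- rbind(cbind(K, -C[, idx, drop = FALSE]),
               cbind(t(C[, idx, drop = FALSE]), matrix(0, length(idx), length(idx))))
    sol <- solve(A, c(numeric(length(free)), gaps[idx]))
    lam <- sol[length(free) + seq_along(idx)]
    if (all(lam >= 0)) break
    active[idx[lam < 0]] <- FALSE
  }
  u <- numeric(model$n_dofs)
  u[free] <- sol[seq_along(free)]
  lambda <- numeric(np)
  lambda[idx] <- lam
  list(u = u, lambda = lambda, active = active)
}
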