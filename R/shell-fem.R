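#' Soft-tissue shell material
#'
#' Material record of the single-layer flat-shell face model. Units: MPa and
#' mm throughout (so stiffness entries come out in N/mm and N*mm). Defaults
#' are the soft-tissue constants used for facial skin: E = 0.03 MPa,
#' nu = 0.49, thickness 2 mm, with the standard Mindlin shear correction
#' kappa = 5/6 and a small artificial drilling stiffness that stabilizes the
#' in-plane rotation of the 6-DOF global assembly.
#'
#' @param E elastic modulus (MPa), > 0.
#' @param nu Poisson's ratio in `[0, 0.5)`; exactly 0.5 is singular.
#' @param h shell thickness (mm), > 0.
#' @param kappa shear correction factor in (0, 1].
#' @param drilling_factor scale of the artificial drilling stiffness relative
#'   to the largest bending diagonal; >= 0.
#' @return an object of class `shell_material`.
#' @export
shell_material <- function(E = 0.03, nu = 0.49, h = 2,
                           kappa = 5 / 6, drilling_factor = 1e-6) {
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("nu must be in [0, 0.5); nu = 0.5 makes the material singular")
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  if (!is.finite(kappa) || kappa <= 0 || kappa > 1) stop("kappa must be in (0, 1]")
  if (!is.finite(drilling_factor) || drilling_factor < 0)
    stop("drilling_factor must be >= 0")
  structure(list(E = E, nu = nu, h = h, kappa = kappa,
                 drilling_factor = drilling_factor),
            class = "shell_material")
}

#' @export
print.shell_material <- function(x, ...) {
  cat(sprintf("Shell material: E = %g MPa, nu = %g, h = %g mm, kappa = %g, drilling = %g\n",
              x$E, x$nu, x$h, x$kappa, x$drilling_factor))
  invisible(x)
}

#' Constitutive matrices of the flat shell
#'
#' Bending rigidity `D_b = E h^3 / (12 (1 - nu^2)) * M`, membrane rigidity per
#' unit thickness `D_p = E / (1 - nu^2) * M` (multiplied by `h` during
#' integration), and transverse shear rigidity `D_s = kappa * G * h` with
#' `G = E / (2 (1 + nu))`, where `M` is the plane-stress pattern
#' `[[1, nu, 0], [nu, 1, 0], [0, 0, (1 - nu)/2]]`.
#'
#' @param material a [shell_material()].
#' @return list with `D_b` (3x3, N*mm), `D_p` (3x3, MPa), `D_s` (scalar, N/mm)
#'   and the shear modulus `G` (MPa).
#' @export
elasticity_matrices <- function(material) {
  E <- material$E; nu <- material$nu; h <- material$h
  pattern <- matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  G <- E / (2 * (1 + nu))
  list(D_b = E * h^3 / (12 * (1 - nu^2)) * pattern,
       D_p = E / (1 - nu^2) * pattern,
       D_s = material$kappa * G * h,
       G = G)
}

# Local orthonormal frame of a triangle: e1 along the first edge, e3 the unit
# normal, e2 = e3 x e1. Rows of the returned 3x3 matrix are e1, e2, e3, so it
# maps global vectors to local components.
triangle_frame <- function(coords) {
  e1 <- coords[2, ] - coords[1, ]
  l1 <- sqrt(sum(e1^2))
  e1 <- e1 / l1
  n <- pracma_cross(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ])
  ln <- sqrt(sum(n^2))
  e3 <- n / ln
  e2 <- pracma_cross(e3, e1)
  rbind(e1, e2, e3, deparse.level = 0)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# 15-DOF local flat-shell stiffness: CST membrane + linear Mindlin plate
# triangle whose transverse shear uses the discrete-shear-gap (DSG)
# interpolation, which is free of shear locking in the thin limit. Local DOF
# order per node: (u, v, w, tx, ty); nodes 1..3. xy: 3x2 local in-plane
# coordinates (node 1 at the origin in the caller's frame).
local_shell_stiffness <- function(xy, Dm) {
  x <- xy[, 1]; y <- xy[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  A2 <- x[1] * b[1] + x[2] * b[2] + x[3] * b[3]  # 2*area (signed, positive here)
  A <- A2 / 2
  # membrane (CST): strain = Bp %*% (u1 v1 u2 v2 u3 v3)
  Bp <- matrix(0, 3, 6)
  Bp[1, c(1, 3, 5)] <- b / A2
  Bp[2, c(2, 4, 6)] <- c_ / A2
  Bp[3, c(1, 3, 5)] <- c_ / A2
  Bp[3, c(2, 4, 6)] <- b / A2
  Kp <- A * crossprod(Bp, Dm$D_p %*% Bp) * attr(Dm, "h")
  # bending: curvature = Bb %*% (w1 tx1 ty1 ...), section rotations
  # beta_x = ty, beta_y = -tx; gamma = (dw/dx + beta_x, dw/dy + beta_y)
  Bb <- matrix(0, 3, 9)
  Bb[1, c(3, 6, 9)] <- b / A2            # d(beta_x)/dx
  Bb[2, c(2, 5, 8)] <- -c_ / A2          # d(beta_y)/dy
  Bb[3, c(2, 5, 8)] <- -b / A2           # d(beta_y)/dx
  Bb[3, c(3, 6, 9)] <- c_ / A2           # d(beta_x)/dy
  Kb <- A * crossprod(Bb, Dm$D_b %*% Bb)
  # transverse shear by discrete shear gaps: the gap of node i relative to
  # node 1 is w_i - w_1 + edge-integral of the linearly interpolated beta;
  # differentiating the linearly interpolated gap field gives a constant
  # shear strain per element with no spurious thin-limit constraint.
  ea <- x[2] - x[1]; eb <- y[2] - y[1]   # edge 1->2
  ed <- x[3] - x[1]; ec <- y[3] - y[1]   # edge 1->3
  Bsb <- matrix(0, 2, 9)                 # columns (w, beta_x, beta_y) per node
  Bsb[1, ] <- c(eb - ec, A, 0,   ec, ea * ec / 2, eb * ec / 2,
                -eb, -eb * ed / 2, -eb * ec / 2) / A2
  Bsb[2, ] <- c(ed - ea, 0, A,   -ed, -ea * ed / 2, -eb * ed / 2,
                ea, ea * ed / 2, ea * ec / 2) / A2
  # express in nodal (w, tx, ty): beta_x = ty, beta_y = -tx
  Bs <- matrix(0, 2, 9)
  wi <- c(1, 4, 7); bxi <- c(2, 5, 8); byi <- c(3, 6, 9)
  Bs[, wi] <- Bsb[, wi]
  Bs[, bxi + 1] <- Bsb[, bxi]            # beta_x column -> ty slot
  Bs[, byi - 1] <- -Bsb[, byi]           # beta_y column -> tx slot (negated)
  Ks <- A * Dm$D_s * crossprod(Bs)
  # scatter into the 15-DOF local ordering
  K <- matrix(0, 15, 15)
  im <- c(1, 2, 6, 7, 11, 12)            # u, v per node
  ib <- c(3, 4, 5, 8, 9, 10, 13, 14, 15) # w, tx, ty per node
  K[im, im] <- K[im, im] + Kp
  K[ib, ib] <- K[ib, ib] + Kb + Ks
  list(K = K, A = A, Kb_diag_max = max(diag(Kb)))
}

#' Element stiffness of a triangular flat shell
#'
#' Builds the 15-DOF local stiffness (constant-strain-triangle membrane plus
#' a linear Mindlin plate triangle with centroid-evaluated transverse shear),
#' augments the drilling rotation with a small artificial stiffness, and
#' rotates the resulting 18x18 matrix (6 DOFs per node, order
#' `u_x, u_y, u_z, th_x, th_y, th_z`) into global axes.
#'
#' @param coords 3x3 numeric matrix, one vertex per row (mm).
#' @param material a [shell_material()].
#' @return object of class `element_stiffness`: list with `K` (18x18, global
#'   axes), `area` (mm^2), and `local_dofs` (15, the DOF count before the
#'   drilling augmentation).
#' @export
element_stiffness <- function(coords, material) {
  coords <- as.matrix(coords)
  Rf <- tryCatch(triangle_frame(coords), error = function(e) NULL)
  a2 <- pracma_cross(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ])
  area <- 0.5 * sqrt(sum(a2^2))
  if (!is.finite(area) || area <= 1e-9)
    stop("degenerate triangle (area ", signif(area, 3), " mm^2)")
  local <- (coords - rep(coords[1, ], each = 3)) %*% t(Rf)
  Dm <- elasticity_matrices(material)
  attr(Dm, "h") <- material$h
  ls <- local_shell_stiffness(local[, 1:2], Dm)
  K18 <- matrix(0, 18, 18)
  map15 <- c(1, 2, 3, 4, 5, 7, 8, 9, 10, 11, 13, 14, 15, 16, 17)  # skip th_z slots
  K18[map15, map15] <- ls$K
  k_drill <- material$drilling_factor * ls$Kb_diag_max
  drill <- c(6, 12, 18)
  K18[cbind(drill, drill)] <- k_drill
  # rotate local -> global: u_local = T u_global with T = blockdiag(Rf x 6)
  Tm <- matrix(0, 18, 18)
  for (blk in 0:5) Tm[blk * 3 + 1:3, blk * 3 + 1:3] <- Rf
  Kg <- crossprod(Tm, K18 %*% Tm)
  Kg <- (Kg + t(Kg)) / 2
  structure(list(K = Kg, area = ls$A, local_dofs = 15L), class = "element_stiffness")
}

#' Assemble the face stiffness matrix
#'
#' Sums element stiffnesses into the sparse global stiffness with node-major
#' DOF ordering (node `i` owns DOFs `6(i-1)+1 .. 6i`, in the order
#' `u_x, u_y, u_z, th_x, th_y, th_z`) and clamps all 6 DOFs of every open-edge
#' (boundary) vertex.
#'
#' @param mesh a [tri_mesh()] with a non-empty boundary for a well-posed model.
#' @param material a [shell_material()].
#' @return object of class `face_fem`: list with `mesh`, `material`, sparse
#'   symmetric `K_f`, `fixed_dofs`, `free_dofs`, `n_dofs` and
#'   `dofs_per_node = 6`.
#' @export
assemble_stiffness <- function(mesh, material = shell_material()) {
  if (!inherits(mesh, "tri_mesh")) stop("`mesh` must be a tri_mesh")
  nt <- nrow(mesh$triangles)
  if (nt == 0) stop("mesh has no triangles")
  nv <- nrow(mesh$vertices)
  n_dofs <- 6L * nv
  ii <- vector("list", nt); jj <- vector("list", nt); xx <- vector("list", nt)
  for (e in seq_len(nt)) {
    tri <- mesh$triangles[e, ]
    Ke <- element_stiffness(mesh$vertices[tri, , drop = FALSE], material)$K
    gdof <- as.integer(outer(1:6, (tri - 1L) * 6L, `+`))
    idx <- which(upper.tri(Ke, diag = TRUE), arr.ind = TRUE)
    ii[[e]] <- gdof[idx[, 1]]
    jj[[e]] <- gdof[idx[, 2]]
    xx[[e]] <- Ke[idx]
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  # accumulate both halves so the triplet matrix is fully symmetric
  off <- i != j
  K <- Matrix::sparseMatrix(i = c(i, j[off]), j = c(j, i[off]), x = c(x, x[off]),
                            dims = c(n_dofs, n_dofs))
  fixed <- as.integer(outer(1:6, (mesh$boundary_vertices - 1L) * 6L, `+`))
  structure(list(mesh = mesh, material = material,
                 K_f = Matrix::forceSymmetric(K),
                 fixed_dofs = sort(fixed),
                 free_dofs = setdiff(seq_len(n_dofs), fixed),
                 n_dofs = n_dofs, dofs_per_node = 6L),
            class = "face_fem")
}

#' @export
print.face_fem <- function(x, ...) {
  cat("Face flat-shell FE model\n")
  cat(sprintf("  nodes: %d  DOFs: %d (6 per node)\n", nrow(x$mesh$vertices), x$n_dofs))
  cat(sprintf("  fixed DOFs (clamped open edge): %d\n", length(x$fixed_dofs)))
  print(x$material)
  invisible(x)
}

#' Solve the linear static face problem
#'
#' Solves `K_ff u_free = f_free` by sparse Cholesky factorization, with zero
#' displacement on all fixed DOFs.
#'
#' @param model a [assemble_stiffness()] result.
#' @param loads numeric vector of length `n_dofs` (N for translations, N*mm
#'   for rotations); must be zero on fixed DOFs.
#' @return numeric displacement vector of length `n_dofs` (mm / rad).
#' @export
solve_static <- function(model, loads) {
  stopifnot(length(loads) == model$n_dofs)
  if (any(loads[model$fixed_dofs] != 0))
    stop("loads must be zero on fixed DOFs")
  if (length(model$fixed_dofs) == 0)
    stop("model has no fixed DOFs; clamp an open boundary first")
  free <- model$free_dofs
  Kff <- model$K_f[free, free]
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
                 error = function(e)
                   stop("free stiffness block is singular; check boundary conditions"))
  u <- numeric(model$n_dofs)
  u[free] <- as.numeric(Matrix::solve(ch, loads[free]))
  u
}
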