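test_that("elasticity matrices follow the plane-stress shell formulas", {
  mat <- shell_material(E = 0.03, nu = 0.49, h = 2)
  D <- elasticity_matrices(mat)
  # soft-tissue constants, evaluated independently: E h^3 / (12 (1 - nu^2))
  expect_equal(D$D_b[1, 1], 0.0263192525332, tolerance = 1e-10)
  expect_equal(D$G, 0.010067114094, tolerance = 1e-10)
  expect_equal(D$D_s, 5 / 6 * 0.010067114094 * 2, tolerance = 1e-10)
  expect_equal(D$D_b[1, 2] / D$D_b[1, 1], 0.49)
  # nu = 0: off-diagonals vanish, shear entry is E h^3 / 24
  D0 <- elasticity_matrices(shell_material(E = 1, nu = 0, h = 2))
  expect_equal(D0$D_b[1, 2], 0)
  expect_equal(D0$D_b[3, 3], 8 / 24)
  # incompressible limit is rejected
  expect_error(shell_material(nu = 0.5), "singular")
})

test_that("element stiffness has 15 local DOFs, symmetry, PSD, rigid modes", {
  mat <- shell_material()
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(2, 8, 0))
  ke <- element_stiffness(coords, mat)
  expect_identical(ke$local_dofs, 15L)
  K <- ke$K
  expect_equal(dim(K), c(18L, 18L))
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  # zero strain energy for the three rigid translations
  for (ax in 1:3) {
    u <- rep(0, 18); u[c(ax, ax + 6, ax + 12)] <- 1
    expect_lt(abs(crossprod(u, K %*% u)), 1e-10 * max(diag(K)))
  }
  # and for a rigid rotation of the (tilted) element about the z axis
  tilted <- rbind(c(0, 0, 0), c(10, 0, 3), c(2, 8, 5))
  Kt <- element_stiffness(tilted, mat)$K
  omega <- c(0, 0, 1)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  u <- unlist(lapply(1:3, function(i)
    c(cross3(omega, tilted[i, ]), omega)))
  expect_lt(abs(crossprod(u, Kt %*% u)),
            1e-6 * max(diag(Kt)) * sum(u^2))
  expect_error(element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), mat),
               "degenerate")
})

test_that("membrane block equals the textbook CST stiffness", {
  # right triangle with legs 1,1 in the xy plane: local frame == global frame
  mat <- shell_material(E = 5, nu = 0.3, h = 2, drilling_factor = 0)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  K <- element_stiffness(coords, mat)$K
  # oracle: independent B-matrix integration, K = A h B' D B
  x <- coords[, 1]; y <- coords[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  A <- 0.5
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b / (2 * A)
  B[2, c(2, 4, 6)] <- cc / (2 * A)
  B[3, c(1, 3, 5)] <- cc / (2 * A)
  B[3, c(2, 4, 6)] <- b / (2 * A)
  D <- 5 / (1 - 0.09) * matrix(c(1, 0.3, 0, 0.3, 1, 0, 0, 0, 0.35), 3, 3)
  K_cst <- A * mat$h * t(B) %*% D %*% B
  mdofs <- c(1, 2, 7, 8, 13, 14)  # global in-plane DOFs of the 3 nodes
  expect_lt(max(abs(K[mdofs, mdofs] - K_cst)), 1e-10)
})

test_that("assembly bookkeeping: DOF counts, symmetry, one-element identity", {
  mat <- shell_material()
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(2, 8, 0))
  single <- tri_mesh(v, matrix(1:3, 1))
  model <- assemble_stiffness(single, mat)
  expect_equal(model$n_dofs, 18L)
  expect_equal(as.matrix(model$K_f), element_stiffness(v, mat)$K,
               ignore_attr = TRUE, tolerance = 1e-14)

  face <- small_face(300)
  model <- assemble_stiffness(face, mat)
  expect_equal(model$n_dofs, 6L * nrow(face$vertices))
  K <- model$K_f
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
  expect_setequal(model$fixed_dofs,
                  as.integer(outer(1:6, (face$boundary_vertices - 1L) * 6L, `+`)))
})

test_that("free stiffness block is positive definite on a clamped model", {
  model <- assemble_stiffness(grid_mesh(4, a = 10), shell_material())
  Kff <- as.matrix(model$K_f[model$free_dofs, model$free_dofs])
  ev <- eigen((Kff + t(Kff)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("static solve: zero loads, linearity, modulus scaling", {
  face <- small_face(200)
  model <- assemble_stiffness(face, shell_material())
  expect_equal(solve_static(model, numeric(model$n_dofs)), numeric(model$n_dofs))

  set.seed(1)
  f <- numeric(model$n_dofs)
  free <- model$free_dofs
  f[sample(free, 30)] <- stats::rnorm(30, sd = 0.01)
  u <- solve_static(model, f)
  expect_lt(sqrt(sum((as.numeric(model$K_f %*% u) - f)[free]^2)) / sqrt(sum(f^2)), 1e-8)
  expect_equal(solve_static(model, 2.5 * f), 2.5 * u, tolerance = 1e-10)

  model2 <- assemble_stiffness(face, shell_material(E = 0.06))
  expect_equal(solve_static(model2, f), u / 2, tolerance = 1e-8)

  f[model$fixed_dofs[1]] <- 1
  expect_error(solve_static(model, f), "fixed")
})

test_that("clamped plate benchmark converges to the series solution", {
  # clamped square plate, side 100 mm, central point load; classical series
  # center deflection w = 0.00560 P a^2 / D
  mat <- shell_material(E = 0.03, nu = 0.3, h = 2)
  D <- 0.03 * 8 / (12 * (1 - 0.09))
  P <- 0.001
  w_ref <- 0.00560 * P * 100^2 / D
  errs <- vapply(c(8, 16, 32), function(n) {
    m <- grid_mesh(n, a = 100)
    model <- assemble_stiffness(m, mat)
    ctr <- which.min((m$vertices[, 1] - 50)^2 + (m$vertices[, 2] - 50)^2)
    f <- numeric(model$n_dofs)
    f[(ctr - 1) * 6 + 3] <- P
    u <- solve_static(model, f)
    abs(u[(ctr - 1) * 6 + 3] / w_ref - 1)
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(all(diff(errs) < 0))  # monotone refinement convergence
})
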