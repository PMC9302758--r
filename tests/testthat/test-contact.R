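# shared small contact setup
contact_setup <- function(n = 300, n_ref = 8, clearance = 0.5, spacing = 2) {
  face <- small_face(n)
  model <- assemble_stiffness(face, shell_material())
  des <- mask_design(mask_reference_points(face, n_ref, clearance = clearance),
                     spacing = spacing)
  mn <- sample_mask_nodes(des)
  red <- condense(model, select_master_nodes(face, mn))
  list(face = face, model = model, mn = mn, red = red)
}

test_that("gap screening implements push depth minus clearance", {
  s <- contact_setup()
  prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = 3)
  # d_f = push - clearance on every retained pair, all positive
  expect_equal(prob$pairs$gap, 3 - prob$pairs$clearance)
  expect_true(all(prob$pairs$gap > 0))
  # pairs are unique in face vertex
  expect_false(any(duplicated(prob$pairs$face_vertex)))
  # all paired face vertices are masters
  expect_true(all(prob$pairs$face_vertex %in% s$red$master_nodes))
  # a mask node 5 mm off the face is dropped at push 3 (gap -2)
  far_vertex <- s$red$master_nodes[1]
  fake <- structure(list(nodes = rbind(s$face$vertices[far_vertex, ] + c(0, 0, 5))),
                    class = "mask_nodes")
  expect_error(build_contact_problem(s$face, s$red, fake, push_depth = 3),
               "no contact")
  # the same node with zero clearance gets the full push as gap
  on_surface <- structure(list(nodes = rbind(s$face$vertices[far_vertex, ])),
                          class = "mask_nodes")
  p2 <- build_contact_problem(s$face, s$red, on_surface, push_depth = 3)
  expect_equal(p2$pairs$gap, 3)
})

test_that("pairing equals a brute-force nearest-master-vertex scan", {
  s <- contact_setup()
  prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = 3)
  mv <- s$face$vertices[s$red$master_nodes, ]
  # oracle: per mask node, nearest master vertex; per face vertex, closest wins
  nn <- apply(s$mn$nodes, 1, function(p)
    which.min(colSums((t(mv) - p)^2)))
  d <- sqrt(rowSums((mv[nn, ] - s$mn$nodes)^2))
  best <- tapply(seq_along(nn), nn, function(ix) ix[which.min(d[ix])])
  oracle_pairs <- data.frame(face_vertex = s$red$master_nodes[as.integer(names(best))],
                             mask_node = as.integer(best))
  got <- prob$all_candidates$face_vertex
  expect_setequal(got, oracle_pairs$face_vertex)
  m <- merge(prob$pairs, oracle_pairs, by = "face_vertex")
  expect_equal(m$mask_node.x, m$mask_node.y)
})

test_that("single-pair closed form: u = gap along push axis, lambda = k * gap", {
  # one-triangle-free model is overconstrained; use a 5x5 plate with one
  # interior master node and a single constraint instead
  g <- grid_mesh(4, a = 10)
  model <- assemble_stiffness(g, shell_material())
  vint <- setdiff(seq_len(25), g$boundary_vertices)[5]
  red <- condense(model, vint)
  fake <- structure(list(nodes = rbind(g$vertices[vint, ])), class = "mask_nodes")
  prob <- build_contact_problem(g, red, fake, push_depth = 2,
                                direction = c(0, 0, 1))
  sol <- solve_contact(red, prob)
  # the paired vertex moves by exactly the gap, into the face (-Z here)
  zdof_local <- (match(vint, red$master_nodes) - 1) * 6 + 3
  expect_equal(sol$u_m[zdof_local], -2, tolerance = 1e-10)
  # lambda equals the effective point stiffness times the gap
  Kinv <- chol2inv(red$K_r_chol)
  k_eff <- 1 / Kinv[zdof_local, zdof_local]
  expect_equal(sol$lambda[1], k_eff * 2, tolerance = 1e-8)
  expect_gt(sol$lambda[1], 0)
})

test_that("contact solution satisfies constraints, positivity, equilibrium", {
  s <- contact_setup()
  prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = 3)
  sol <- solve_contact(s$red, prob)
  # constraint residual on active pairs below 1e-8 mm
  expect_lt(sol$constraint_residual, 1e-8)
  # all retained multipliers non-negative
  expect_true(all(sol$lambda[sol$active] >= 0))
  # total contact force balances the boundary reaction along the push axis
  reaction <- boundary_reaction(s$red, sol)
  expect_equal(reaction, sol$total_force, tolerance = 1e-6 * sol$total_force)
})

test_that("multipliers scale linearly with uniform gap scaling", {
  s <- contact_setup()
  prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = 3)
  sol <- solve_contact(s$red, prob)
  prob2 <- prob
  prob2$pairs$gap <- 2 * prob$pairs$gap
  sol2 <- solve_contact(s$red, prob2)
  # same active set under scaling, multipliers exactly doubled
  expect_identical(sol2$active, sol$active)
  expect_equal(sol2$lambda, 2 * sol$lambda, tolerance = 1e-10)
})

test_that("reduced contact solve equals the dense full-system oracle", {
  s <- contact_setup(300)
  prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = 3)
  sol <- solve_contact(s$red, prob)
  oracle <- dense_contact_oracle(s$model, prob$pairs$face_vertex, prob$pairs$gap)
  expect_identical(sol$active, oracle$active)
  expect_lt(max(abs(sol$lambda - oracle$lambda)) / max(oracle$lambda), 1e-8)
  u_rec <- recover_full_displacement(s$red, sol$u_m)
  expect_lt(max(abs(u_rec - oracle$u)) / max(abs(oracle$u)), 1e-8)
})

test_that("complementarity: released pairs would be tensile if re-added", {
  s <- contact_setup()
  prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = 3)
  sol <- solve_contact(s$red, prob)
  released <- which(!sol$active)
  expect_gt(length(released), 0)  # this configuration does release pairs
  j <- released[1]
  # re-solve with pair j forced into the active set alongside the final one
  idx <- c(which(sol$active), j)
  C <- prob$C_r[, idx, drop = FALSE]
  Kinv <- chol2inv(s$red$K_r_chol)
  S <- as.matrix(Matrix::crossprod(C, Kinv %*% C))
  lam <- solve(S, prob$pairs$gap[idx])
  expect_lt(lam[length(idx)], 0)
})

test_that("total contact force is monotone in push depth", {
  s <- contact_setup()
  forces <- vapply(c(2, 3, 4), function(pd) {
    prob <- build_contact_problem(s$face, s$red, s$mn, push_depth = pd)
    solve_contact(s$red, prob)$total_force
  }, numeric(1))
  expect_true(all(diff(forces) > 0))
})
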