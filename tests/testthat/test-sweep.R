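base_loop <- function() circle_loop(8, r = 20)

test_that("candidate enumeration is the full Cartesian offset grid", {
  des <- mask_design(base_loop())
  # 4 points x 5 steps -> 625 candidates
  s625 <- sweep_spec(des, c(2, 4, 6, 8), n_steps = 5, step_magnitude = 3)
  expect_equal(s625$n_candidates, 625L)
  t0 <- proc.time()[3]
  cands <- enumerate_candidates(s625)
  expect_lt(proc.time()[3] - t0, 1)
  expect_length(cands, 625)
  offs <- t(vapply(cands, attr, numeric(4), "offsets"))
  expect_equal(nrow(unique(offs)), 625)
  expect_true(all(offs %in% c(-6, -3, 0, 3, 6)))
  # lexicographic ordering, first point most significant
  expect_equal(offs[1, ], rep(-6, 4))
  expect_equal(offs[625, ], rep(6, 4))
  expect_true(!is.unsorted(offs[, 1]))

  # 1 point x 1 step -> the base design itself
  s1 <- sweep_spec(des, 2, n_steps = 1)
  c1 <- enumerate_candidates(s1)
  expect_length(c1, 1)
  expect_equal(c1[[1]]$reference_points, des$reference_points)

  # 2 points x 3 steps -> exactly {-m, 0, m}^2, against brute-force product
  s9 <- sweep_spec(des, c(3, 5), n_steps = 3, step_magnitude = 2)
  offs9 <- t(vapply(enumerate_candidates(s9), attr, numeric(2), "offsets"))
  oracle <- as.matrix(expand.grid(c(-2, 0, 2), c(-2, 0, 2)))
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), ]
  expect_equal(offs9, oracle, ignore_attr = TRUE)

  expect_error(sweep_spec(des, c(2, 4), n_steps = 4), "odd")
  expect_error(sweep_spec(des, c(2, 4), n_steps = 101, max_candidates = 100),
               "exceeds")
})

sweep_setup <- function(n_steps = 3, pts = c(3, 7), step = 2) {
  face <- small_face(300)
  model <- assemble_stiffness(face, shell_material())
  base <- mask_design(mask_reference_points(face, clearance = 0.5), spacing = 2)
  spec <- sweep_spec(base, pts, n_steps = n_steps, step_magnitude = step,
                     push_depth = 3)
  variants <- lapply(enumerate_candidates(spec), sample_mask_nodes)
  red <- condense(model, select_master_nodes(face, variants))
  list(face = face, model = model, spec = spec, red = red)
}

test_that("shared-reduction sweep equals independent end-to-end runs", {
  s <- sweep_setup()
  sw <- run_sweep(s$model, s$red, s$spec)
  expect_equal(nrow(sw$results), 9L)
  # oracle: fresh full pipeline per candidate (own condensation)
  for (i in c(1, 5, 9)) {
    cand <- enumerate_candidates(s$spec)[[i]]
    fit <- maskfit(s$face, cand, push_depth = 3, model = s$model)
    expect_equal(sw$results$mean_MPa[i], fit$pressure$summary$mean,
                 tolerance = 1e-8)
    expect_equal(sw$results$sd_MPa[i], fit$pressure$summary$sd, tolerance = 1e-8)
    expect_equal(sw$results$max_MPa[i], fit$pressure$summary$max, tolerance = 1e-8)
    expect_equal(sw$results$zero_pressure_count[i], fit$pressure$zero_pressure_count)
  }
})

test_that("identical candidates tie and break deterministically", {
  s <- sweep_setup(n_steps = 1, pts = 2)  # single candidate
  sw <- run_sweep(s$model, s$red, s$spec)
  expect_equal(sw$best_id, sw$worst_id)
  expect_equal(sw$best_id, sw$results$design_id[1])
})

test_that("master-coverage violations are detected and named", {
  s <- sweep_setup()
  # remove some masters so a candidate's footprint is uncovered
  crippled <- condense(s$model, s$red$master_nodes[-(1:15)])
  expect_error(run_sweep(s$model, crippled, s$spec), "outside the master set")
})

test_that("ranking prefers dominated-on-both candidates and is scale-free", {
  res <- data.frame(design_id = c("a", "b", "c"),
                    mean_MPa = c(0.010, 0.014, 0.012),
                    sd_MPa = c(0.002, 0.004, 0.003))
  rk <- rank_candidates(res)
  expect_equal(rk$best_id, "a")   # dominates on both mean and SD
  expect_equal(rk$worst_id, "b")
  # affine rescaling of all pressures leaves the ranking unchanged
  res2 <- res
  res2$mean_MPa <- res$mean_MPa * 7
  res2$sd_MPa <- res$sd_MPa * 7
  rk2 <- rank_candidates(res2)
  expect_equal(rk2$best_id, rk$best_id)
  expect_equal(rk2$score, rk$score, tolerance = 1e-12)
  # single candidate: best = worst
  rk1 <- rank_candidates(res[1, ])
  expect_equal(rk1$best_id, "a")
  expect_equal(rk1$worst_id, "a")
  # degenerate spread contributes 0 rather than NaN
  res3 <- res; res3$sd_MPa <- 0.002
  expect_false(any(is.nan(rank_candidates(res3)$score)))
})

test_that("adding reference points at high-curvature regions does not add zero-pressure nodes", {
  face <- small_face(500)
  model <- assemble_stiffness(face, shell_material())
  zero_count <- function(n_ref) {
    des <- mask_design(mask_reference_points(face, n_ref, clearance = 0.5))
    fit <- maskfit(face, des, push_depth = 3, model = model)
    fit$pressure$zero_pressure_count
  }
  # 12-point loop adds points at the nasal-root and lip sides
  expect_lte(zero_count(12), zero_count(8))
})

test_that("sweep outputs are written", {
  s <- sweep_setup()
  sw <- run_sweep(s$model, s$red, s$spec)
  dir <- withr::local_tempdir()
  write_sweep_results(sw, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "best_mask.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_candidates, 9L)
  expect_equal(js$best_id, sw$best_id)
})
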