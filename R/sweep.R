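#' Specification of a mask design sweep
#'
#' Describes the Cartesian grid of reference-point adjustments to enumerate:
#' each adjustable point moves through `n_steps` symmetric offsets
#' `{-k m, ..., 0, ..., +k m}` (with `k = (n_steps - 1) / 2` and `m` the step
#' magnitude) along one axis, and every combination is a candidate. Four
#' points with five steps give the classic 5^4 = 625-candidate study.
#'
#' @param base_design a [mask_design()].
#' @param adjustable_point_indices reference points to move (e.g. the cheek
#'   points).
#' @param axis `"x"` (default), `"y"` or `"z"`.
#' @param n_steps odd integer >= 1 (symmetric about zero; default 5).
#' @param step_magnitude step size (mm; default 3).
#' @param push_depth contact push depth for candidate evaluation (mm).
#' @param max_candidates guard against accidental combinatorial blow-up.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(base_design, adjustable_point_indices, axis = "x",
                       n_steps = 5L, step_magnitude = 3, push_depth = 3,
                       max_candidates = 1e6) {
  if (!inherits(base_design, "mask_design")) stop("`base_design` must be a mask_design")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L || n_steps %% 2L == 0L) stop("`n_steps` must be an odd integer >= 1")
  idx <- as.integer(adjustable_point_indices)
  if (any(idx < 1L | idx > nrow(base_design$reference_points)))
    stop("adjustable point index out of range")
  n_cand <- n_steps^length(idx)
  if (n_cand > max_candidates)
    stop("candidate count ", n_cand, " exceeds the cap of ", max_candidates)
  structure(list(base_design = base_design, adjustable_point_indices = idx,
                 axis = tolower(axis), n_steps = n_steps,
                 step_magnitude = step_magnitude, push_depth = push_depth,
                 n_candidates = n_cand),
            class = "sweep_spec")
}

#' Enumerate the design candidates of a sweep
#'
#' @param spec a [sweep_spec()].
#' @return list of [mask_design()] objects in lexicographic offset order;
#'   each carries its offsets tuple as attribute `"offsets"` and a
#'   `design_id` of the form `"cand_<i>"`.
#' @export
enumerate_candidates <- function(spec) {
  k <- (spec$n_steps - 1L) / 2L
  steps <- (-k:k) * spec$step_magnitude
  npts <- length(spec$adjustable_point_indices)
  combos <- as.matrix(expand.grid(rep(list(steps), npts), KEEP.OUT.ATTRS = FALSE))
  dimnames(combos) <- NULL
  # lexicographic in offsets, first adjustable point most significant
  combos <- combos[do.call(order, as.data.frame(combos)), , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i) {
    d <- spec$base_design
    for (j in seq_len(npts)) {
      if (combos[i, j] != 0)
        d <- adjust_reference_points(d, spec$adjustable_point_indices[j],
                                     spec$axis, combos[i, j])
    }
    d$design_id <- sprintf("cand_%04d", i)
    attr(d, "offsets") <- as.numeric(combos[i, ])
    d
  })
}

#' Run a design sweep on a shared condensed model
#'
#' Evaluates every candidate of the sweep on the same [condense()] result:
#' sample mask nodes, build the contact problem, solve with the reused
#' reduced factorization (the dense inverse of `K_r` is formed once), and
#' summarize the pressure field. Errors if any candidate pairs to a face
#' vertex outside the master set (the condensation must have been built over
#' all candidates of this spec).
#'
#' @param model a [assemble_stiffness()] result.
#' @param reduced a [condense()] result whose master set covers the sweep.
#' @param spec a [sweep_spec()].
#' @return object of class `sweep_result`: data frame `results` (one row per
#'   candidate: `design_id`, offsets, `mean_MPa`, `sd_MPa`, `max_MPa`,
#'   `zero_pressure_count`, `n_pairs`, `solve_time_s`), plus `best_id`,
#'   `worst_id` and `ranking` scores.
#' @export
run_sweep <- function(model, reduced, spec) {
  candidates <- enumerate_candidates(spec)
  K_r_inv <- chol2inv(reduced$K_r_chol)
  master_set <- reduced$master_nodes
  rows <- vector("list", length(candidates))
  fields <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    t0 <- proc.time()[3]
    mn <- sample_mask_nodes(candidates[[i]])
    check_master_coverage(model$mesh, master_set, mn, candidates[[i]]$design_id)
    prob <- build_contact_problem(model$mesh, reduced, mn, spec$push_depth)
    sol <- solve_contact(reduced, prob, K_r_inv = K_r_inv)
    field <- pressures_from_solution(model$mesh, sol, prob)
    dt <- proc.time()[3] - t0
    off <- attr(candidates[[i]], "offsets")
    rows[[i]] <- data.frame(design_id = candidates[[i]]$design_id,
                            t(stats::setNames(off, paste0("offset_", seq_along(off)))),
                            mean_MPa = field$summary$mean,
                            sd_MPa = field$summary$sd,
                            max_MPa = field$summary$max,
                            zero_pressure_count = field$zero_pressure_count,
                            n_pairs = field$summary$n,
                            solve_time_s = dt)
    fields[[i]] <- field
  }
  results <- do.call(rbind, rows)
  rk <- rank_candidates(results)
  structure(list(results = results, best_id = rk$best_id, worst_id = rk$worst_id,
                 ranking = rk$score, spec = spec, fields = fields),
            class = "sweep_result")
}

# A candidate violates master coverage when a mask node's nearest face
# triangle has a free vertex outside the master set.
check_master_coverage <- function(mesh, master_set, mask_nodes, design_id) {
  nt <- nearest_triangles(mesh, mask_nodes$nodes)
  touched <- setdiff(unique(as.integer(mesh$triangles[nt$triangle, ])),
                     mesh$boundary_vertices)
  missing <- setdiff(touched, master_set)
  if (length(missing))
    stop("candidate ", design_id, " touches ", length(missing),
         " face vertices outside the master set; re-condense over all candidates")
  invisible(TRUE)
}

#' Rank sweep candidates by mean and spread of contact pressure
#'
#' A design with both a lower average pressure and a lower pressure spread
#' fits better. Candidates are scored by the sum of the z-standardized mean
#' and z-standardized SD (population SD across candidates; a statistic with
#' zero spread contributes 0); the lowest score is best. Ties break by lower
#' mean, then by lexicographic offsets (row order).
#'
#' @param results the `results` data frame of [run_sweep()] (needs columns
#'   `design_id`, `mean_MPa`, `sd_MPa`).
#' @param weights length-2 weights of (mean, SD); default equal.
#' @return list with `best_id`, `worst_id`, `score`.
#' @export
rank_candidates <- function(results, weights = c(1, 1)) {
  stopifnot(nrow(results) >= 1)
  zscore <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  score <- weights[1] * zscore(results$mean_MPa) + weights[2] * zscore(results$sd_MPa)
  ord <- order(score, results$mean_MPa, seq_len(nrow(results)))
  list(best_id = results$design_id[ord[1]],
       worst_id = results$design_id[ord[length(ord)]],
       score = score)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Design sweep: %d candidates (%d steps^%d points, %s-axis, %.2g mm push)\n",
              nrow(x$results), x$spec$n_steps,
              length(x$spec$adjustable_point_indices), x$spec$axis,
              x$spec$push_depth))
  cat(sprintf("  mean pressure range: %.4g - %.4g MPa\n",
              min(x$results$mean_MPa), max(x$results$mean_MPa)))
  cat(sprintf("  best: %s   worst: %s\n", x$best_id, x$worst_id))
  cat(sprintf("  total solve time: %.2f s (%.4g s/design)\n",
              sum(x$results$solve_time_s), mean(x$results$solve_time_s)))
  invisible(x)
}

#' Write sweep outputs
#'
#' Writes `results.csv` (one row per candidate), the best and worst mask node
#' sets (CSV + OBJ point clouds) and `summary.json`.
#'
#' @param sweep a [run_sweep()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_results <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sweep$results, file.path(dir, "results.csv"), row.names = FALSE)
  candidates <- enumerate_candidates(sweep$spec)
  ids <- vapply(candidates, function(d) d$design_id, "")
  for (which in c("best", "worst")) {
    id <- if (which == "best") sweep$best_id else sweep$worst_id
    mn <- sample_mask_nodes(candidates[[match(id, ids)]])
    write_mask_nodes(mn, file.path(dir, paste0(which, "_mask.csv")), "csv")
    write_mask_nodes(mn, file.path(dir, paste0(which, "_mask.obj")), "obj")
  }
  jsonlite::write_json(list(n_candidates = nrow(sweep$results),
                            best_id = sweep$best_id, worst_id = sweep$worst_id,
                            mean_pressure_range = range(sweep$results$mean_MPa)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
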