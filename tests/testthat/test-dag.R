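# Stage-graph construction, convergence rule, determinism, and the
# brute-force equivalence of the full pipeline on a tiny problem.

test_that("a single-residue loop yields only the start node and 1-gap closures", {
  dag <- build_dag(c(5, 5), "full")
  expect_equal(nrow(dag$nodes), 1L)
  expect_equal(unlist(dag$nodes[1, ]), c(i = 4, j = 6))
  expect_true(all(dag$edges$type %in% c("close-first")))
})

test_that("full-mode node count matches the combinatorial enumeration", {
  dag <- build_dag(c(10, 15), "full")  # N = 6
  # oracle: all (a, b) with a + b <= N - 1
  N <- 6
  cnt <- 0L
  for (a in 0:N) for (b in 0:N) if (a + b <= N - 1) cnt <- cnt + 1L
  expect_equal(nrow(dag$nodes), cnt)
  expect_equal(cnt, 21L)
})

test_that("linear-mode node count grows linearly with loop length", {
  n_nodes <- function(N) nrow(build_dag(c(10, 10 + N - 1), "linear")$nodes)
  d1 <- n_nodes(8) - n_nodes(4)
  d2 <- n_nodes(12) - n_nodes(8)
  expect_equal(d1, d2)
  # and full mode grows quadratically: second difference constant
  f <- function(N) nrow(build_dag(c(10, 10 + N - 1), "full")$nodes)
  expect_equal(f(6) - 2 * f(5) + f(4), f(8) - 2 * f(7) + f(6))
})

test_that("the 1 kBT gap defines convergence", {
  expect_true(converged(list(energies = c(-10, -8.5))))
  expect_false(converged(list(energies = c(-10, -9.7))))
  expect_true(converged(list(energies = -3)))
  expect_error(converged(list(energies = numeric(0))), "empty")
})

test_that("the pipeline matches brute-force enumeration on a 2-residue loop", {
  fx <- tiny_problem(seq1 = "AAGAAA", loop = c(3, 4),
                     phi = c(NA, rep(-63, 5)), psi = rep(-43, 6))
  cfg <- test_config(torsion_step = 60, keep_fine = 10000,
                     stage_pool = 10000, stage_keep = 10000,
                     fine_radius = 1e-9, stage_radius = 1e-9,
                     closure_parents = Inf, max_pairs = 10000,
                     min_iter = 10, mode = "full")
  res <- swa_run(fx$problem, fx$loop, cfg, rng_seed = 1)
  # oracle: compose the same moves directly, bypassing the DAG bookkeeping
  pre <- res$prepacked
  start <- list(stage = c(2L, 5L), models = list(pre),
                energies = score(pre)$total)
  closed_E <- numeric(0)
  # route 1: close the 2-gap directly from the start node (both variants)
  for (v in c("first", "last")) {
    cs <- close_from_stage(start, v, cfg, stage_seed(1, 2, 5,
                                                     if (v == "first") 4L else 5L))
    closed_E <- c(closed_E, cs$energies)
  }
  # routes 2/3: grow one residue then close the single gap
  gN <- grow_step(start, "N", cfg, stage_seed(1, 3, 5, 1L))
  ensN <- list(stage = c(3L, 5L), models = gN$models, energies = gN$energies)
  csN <- close_from_stage(ensN, "first", cfg, stage_seed(1, 3, 5, 4L))
  closed_E <- c(closed_E, csN$energies)
  gC <- grow_step(start, "C", cfg, stage_seed(1, 2, 4, 2L))
  ensC <- list(stage = c(2L, 4L), models = gC$models, energies = gC$energies)
  csC <- close_from_stage(ensC, "first", cfg, stage_seed(1, 2, 4, 4L))
  closed_E <- c(closed_E, csC$energies)
  # (no recombination routes exist for a 2-residue loop: the combined
  # fragments would leave no gap to close)
  dag <- build_dag(fx$loop, "full")
  expect_false(any(dag$edges$type == "recombine"))
  expect_equal(min(res$predictions$energies), min(closed_E),
               tolerance = 1e-3)
})

test_that("identical seeds reproduce the final score table exactly", {
  fx <- tiny_problem(seq1 = "AAGAA", loop = c(3, 3))
  cfg <- test_config(torsion_step = 60, min_iter = 10, mode = "linear")
  r1 <- swa_run(fx$problem, fx$loop, cfg, rng_seed = 4)
  r2 <- swa_run(fx$problem, fx$loop, cfg, rng_seed = 4)
  expect_identical(r1$predictions$energies, r2$predictions$energies)
  expect_identical(r1$predictions$models[[1]]$xyz,
                   r2$predictions$models[[1]]$xyz)
})

test_that("final predictions are capped at five and separated by 1 A", {
  fx <- tiny_problem(seq1 = "AAGAAA", loop = c(3, 4))
  cfg <- test_config(torsion_step = 60, min_iter = 10, mode = "linear")
  res <- swa_run(fx$problem, fx$loop, cfg, rng_seed = 2)
  np <- length(res$predictions$models)
  expect_lte(np, 5L)
  if (np > 1) {
    for (a in 1:(np - 1)) for (b in (a + 1):np)
      expect_gte(ca_rmsd(res$predictions$models[[a]],
                         res$predictions$models[[b]], fx$loop), 1.0)
  }
  # the simplified graph explores a subset of the full graph
  cfg_full <- cfg; cfg_full$mode <- "full"
  res_full <- swa_run(fx$problem, fx$loop, cfg_full, rng_seed = 2)
  expect_lte(min(res_full$predictions$energies),
             min(res$predictions$energies) + 1e-3)
})

test_that("the pipeline escalates to the full graph when unconverged", {
  fx <- tiny_problem(seq1 = "AAGAAA", loop = c(3, 4))
  cfg <- test_config(torsion_step = 60, min_iter = 5, mode = "auto",
                     final_radius = 0.01,    # keep several final models
                     convergence_gap = 1e9)  # force the escalation branch
  res <- swa_run(fx$problem, fx$loop, cfg, rng_seed = 1)
  expect_gt(length(res$predictions$models), 1L)
  expect_equal(res$mode_used, "full")
  cfg2 <- test_config(torsion_step = 60, min_iter = 5, mode = "auto",
                      final_radius = 0.01,
                      convergence_gap = 0)   # always converged: stay linear
  res2 <- swa_run(fx$problem, fx$loop, cfg2, rng_seed = 1)
  expect_equal(res2$mode_used, "linear")
})
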