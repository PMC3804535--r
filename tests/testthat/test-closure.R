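# Cyclic coordinate descent closure, the 1.5 A screen, and fragment
# recombination.

# a mid-build conformation with an open cutpoint for CCD tests
closure_case <- function(perturb = 0) {
  fx <- tiny_problem(seq1 = "AAGAAAA", loop = c(3, 5))
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  conf <- prepend_capped_residue(conf, 5, phi = -63, psi = -43)
  conf <- append_residue(conf, 4, phi = -63, psi = -43)
  conf <- swaloop:::add_cutpoint(conf, 4)
  if (perturb != 0)
    conf <- set_torsion(conf, 4, "psi", get_torsion(conf, 4, "psi") + perturb)
  conf
}

test_that("an already-closed chain is left untouched at zero deviation", {
  # native chain cut formally: virtual atoms coincide with real ones
  fx <- tiny_problem(seq1 = "AAGAAAA", loop = c(3, 5))
  nat <- fx$native
  nat$built[3:4] <- "nfrag"; nat$built[5] <- "cfrag"
  conf <- swaloop:::add_cutpoint(nat, 4)
  expect_lt(swaloop:::closure_deviation(conf), 1e-9)
  tors <- data.frame(res = 4L, name = c("phi", "psi"))
  before <- c(get_torsion(conf, 4, "phi"), get_torsion(conf, 4, "psi"))
  cc <- ccd_close(conf, tors)
  expect_lt(cc$deviation, 1e-9)
  after <- c(get_torsion(cc$conf, 4, "phi"), get_torsion(cc$conf, 4, "psi"))
  expect_equal(after, before, tolerance = 1e-9)
})

test_that("a single perturbed torsion is recovered exactly by CCD", {
  conf0 <- closure_case()
  val0 <- get_torsion(conf0, 4, "psi")
  conf <- closure_case(perturb = 15)
  cc <- ccd_close(conf, data.frame(res = 4L, name = "psi"),
                  max_cycles = 1000, tol = 1e-5)
  expect_lt(cc$deviation, 1e-3)
  expect_lt(abs(wrap_angle(get_torsion(cc$conf, 4, "psi") - val0)), 0.5)
})

test_that("the analytic per-torsion update matches a fine grid scan", {
  conf <- closure_case(perturb = 40)
  mv <- swaloop:::build_move_set(conf, data.frame(res = 4L, name = "psi"))[[1]]
  prs <- swaloop:::chainbreak_pairs(conf)
  devfun <- function(xyz)
    sqrt(mean(rowSums((xyz[prs[, 1], , drop = FALSE] -
                       xyz[prs[, 2], , drop = FALSE])^2)))
  # oracle: scan this torsion's deviation profile at 0.01 degrees
  angles <- seq(-180, 179.99, by = 0.01)
  cur <- get_torsion(conf, 4, "psi")
  u <- swaloop:::.vhat(conf$xyz[mv$C, ] - conf$xyz[mv$B, ])
  best <- Inf; best_ang <- NA
  for (a in seq(-180, 179, by = 1)) {  # coarse pass
    xyz <- swaloop:::rotate_about_axis(conf$xyz, mv$moving,
                                       conf$xyz[mv$C, ], u, a)
    d <- devfun(xyz)
    if (d < best) { best <- d; best_ang <- a }
  }
  fine <- seq(best_ang - 1.5, best_ang + 1.5, by = 0.01)
  for (a in fine) {
    xyz <- swaloop:::rotate_about_axis(conf$xyz, mv$moving,
                                       conf$xyz[mv$C, ], u, a)
    d <- devfun(xyz)
    if (d < best) { best <- d; best_ang <- a }
  }
  cc <- ccd_close(conf, data.frame(res = 4L, name = "psi"),
                  max_cycles = 1, tol = 0)
  expect_equal(cc$deviation, best, tolerance = 1e-4)
})

test_that("closure from a stage screens at 1.5 A and coincides at gap 1", {
  fx <- tiny_problem(seq1 = "AAGAAAA", loop = c(3, 5))
  cfg <- test_config(keep_fine = 20, min_iter = 15)
  pre <- prepack(fx$problem, rng_seed = 1, anneal_sweeps = 2)
  ens <- list(stage = c(2L, 6L), models = list(pre),
              energies = score(pre)$total)
  g1 <- grow_step(ens, "N", cfg, 1)
  ens1 <- list(stage = c(3L, 6L), models = g1$models, energies = g1$energies)
  g2 <- grow_step(ens1, "C", cfg, 2)
  ens2 <- list(stage = c(3L, 5L), models = g2$models, energies = g2$energies)
  a <- close_from_stage(ens2, "first", cfg, 7)
  b <- close_from_stage(ens2, "last", cfg, 7)
  expect_identical(lapply(a$models, `[[`, "xyz"),
                   lapply(b$models, `[[`, "xyz"))
  expect_gt(length(a$models), 0L)
  # no survivor carries a pre-optimization deviation at or above 1.5 A
  expect_true(all(a$deviations < 1.5))
  # a 2-residue gap (more bridge freedom) closes to tight final geometry
  g2b <- close_from_stage(ens1, "first", cfg, 7)
  expect_gt(length(g2b$models), 0L)
  expect_lt(swaloop:::closure_deviation(g2b$models[[1]]), 0.01)
})

test_that("recombination over a tiny pairing matches the exhaustive oracle", {
  fx <- tiny_problem(seq1 = "AAGAAAA", loop = c(3, 5))
  cfg <- test_config(keep_fine = 2, min_iter = 10)
  pre <- prepack(fx$problem, rng_seed = 1, anneal_sweeps = 2)
  ens <- list(stage = c(2L, 6L), models = list(pre),
              energies = score(pre)$total)
  gN <- grow_step(ens, "N", cfg, 1)   # (3, 6): N fragment only
  gC <- grow_step(ens, "C", cfg, 2)   # (2, 5): C fragment only
  nN <- min(2L, length(gN$models)); nC <- min(2L, length(gC$models))
  ensN <- list(stage = c(3L, 6L), models = gN$models[seq_len(nN)],
               energies = gN$energies[seq_len(nN)])
  ensC <- list(stage = c(2L, 5L), models = gC$models[seq_len(nC)],
               energies = gC$energies[seq_len(nC)])
  out <- recombine_fragments(ensN, ensC, cfg, rng_seed = 9)
  # oracle: enumerate the pairs independently
  best <- Inf
  for (a in seq_len(nN)) for (b in seq_len(nC)) {
    merged <- swaloop:::graft_fragment(ensN$models[[a]], ensC$models[[b]])
    one <- close_from_stage(list(stage = c(3L, 5L), models = list(merged),
                                 energies = 0), "first", cfg, rng_seed = 9)
    if (length(one$energies)) best <- min(best, min(one$energies))
  }
  expect_gt(length(out$models), 0L)
  expect_equal(min(out$energies), best, tolerance = 1e-6)
})
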