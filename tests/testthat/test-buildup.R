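# Grid enumeration arithmetic, fine clustering against a scratch oracle,
# and the growth step contracts.

test_that("the 20-degree grid has 18 samples per torsion", {
  expect_length(grid_values(20), 18L)
  expect_equal(grid_values(20)[1], -180)
  expect_false(180 %in% grid_values(20))
  expect_error(grid_values(23), "divide")
})

test_that("two-residue enumeration without filtering is the full product", {
  spec <- list(torsion_step = 20, rama_cutoff = Inf, omega_values = 180)
  rdf <- data.frame(res = c(3L, 4L), type = c("ALA", "ALA"),
                    next_type = c("ALA", "ALA"), stringsAsFactors = FALSE)
  out <- enumerate_backbone_grid(spec, rdf)
  expect_equal(nrow(out), 18^4)
})

test_that("pre-proline omega sampling doubles the assignment count", {
  spec1 <- list(torsion_step = 20, rama_cutoff = 0.8, omega_values = 180)
  spec2 <- list(torsion_step = 20, rama_cutoff = 0.8,
                omega_values = c(180, 0))
  rdf <- data.frame(res = 3L, type = "ALA", next_type = "PRO",
                    stringsAsFactors = FALSE)
  n1 <- nrow(enumerate_backbone_grid(spec1, rdf))
  n2 <- nrow(enumerate_backbone_grid(spec2, rdf))
  expect_equal(n2, 2L * n1)
  expect_gt(n1, 0L)
})

test_that("every enumerated assignment passes its own rama filter", {
  spec <- list(torsion_step = 20, rama_cutoff = 0.8, omega_values = 180)
  rdf <- data.frame(res = 3L, type = "GLY", next_type = "ALA",
                    stringsAsFactors = FALSE)
  out <- enumerate_backbone_grid(spec, rdf)
  ok <- mapply(function(p, q) rama_score("gly", p, q) <= 0.8,
               out[[1]], out[[2]])
  expect_true(all(ok))
})

test_that("fine clustering matches an independent leader-clustering oracle", {
  fx <- tiny_problem()
  base <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  set.seed(3)
  models <- list(); energies <- numeric(0)
  for (q in 1:50) {
    m <- set_torsion(base, 3, "phi", runif(1, -180, 179))
    m <- set_torsion(m, 3, "psi", runif(1, -180, 179))
    models[[q]] <- m
    energies[q] <- runif(1, -5, 5)
  }
  cl <- cluster_fine(models, energies, radius = 1.0, keep = 20)
  coords <- do.call(rbind, lapply(models, swaloop:::.cluster_coords, 3L))
  want <- oracle_leader(coords, energies, 1.0, 20)
  expect_equal(cl$index, want)
  expect_equal(cl$energies, energies[want])
  # energy-sorted, capped, lowest-energy model always first
  expect_true(!is.unsorted(cl$energies))
  expect_equal(cl$index[1], which.min(energies))
})

test_that("near-duplicate models collapse at the 0.10 A fine radius", {
  fx <- tiny_problem()
  base <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  near <- set_torsion(base, 3, "phi", -63.5)  # well under 0.10 A apart
  cl <- cluster_fine(list(base, near), c(-1, -0.5), radius = 0.10)
  expect_length(cl$models, 1L)
  identical_cl <- cluster_fine(list(base, base, base), c(1, 2, 3))
  expect_length(identical_cl$models, 1L)
})

test_that("growing from an empty ensemble yields an empty output", {
  out <- grow_step(list(stage = c(2L, 6L), models = list(),
                        energies = numeric(0)), "N", test_config(), 1)
  expect_length(out$models, 0L)
})

test_that("a grow step retains the exhaustive grid optimum on a 1-residue loop", {
  fx <- tiny_problem(seq1 = "AAAAA", loop = c(3, 3))
  cfg <- test_config(torsion_step = 60, min_iter = 0, keep_fine = 1000,
                     fine_radius = 1e-9)
  pre <- prepack(fx$problem, rng_seed = 1, anneal_sweeps = 2)
  ens <- list(stage = c(2L, 4L), models = list(pre),
              energies = score(pre)$total)
  out <- grow_step(ens, "N", cfg, rng_seed = 1)
  # oracle: explicit enumeration of the same grid with direct scoring
  spec <- list(torsion_step = 60, rama_cutoff = cfg$rama_cutoff,
               omega_values = 180)
  rdf <- data.frame(res = 3L, type = "ALA", next_type = "ALA",
                    stringsAsFactors = FALSE)
  grid <- enumerate_backbone_grid(spec, rdf)
  base <- append_capped_residue(pre, 3, phi = grid[1, 1], psi = grid[1, 2])
  wm <- energy_weights("minimization")
  best <- Inf
  for (a in seq_len(nrow(grid))) {
    m <- set_torsion(base, 3, "phi", grid[a, 1])
    m <- set_torsion(m, 3, "psi", grid[a, 2])
    best <- min(best, score(m, wm)$total)
  }
  expect_equal(min(out$energies), best, tolerance = 1e-9)
  # retained models' sampled torsions all pass the rama filter
  for (m in out$models)
    expect_lte(rama_score("ALA", m$bb_tor[3, "phi"], m$bb_tor[3, "psi"]),
               cfg$rama_cutoff + 1e-9)
  # ensemble ordering and cap
  expect_true(!is.unsorted(out$energies))
})
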