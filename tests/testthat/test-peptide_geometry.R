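# Internal-coordinate construction, capping groups, and torsion editing.

test_that("empty sequence builds a conformation with zero atoms", {
  conf <- build_from_torsions(character(0), list(phi = numeric(0),
                                                 psi = numeric(0)))
  expect_s3_class(conf, "Conformation")
  expect_equal(nrow(conf$xyz), 0L)
})

test_that("poly-alanine CA-CA spacing matches an independent builder", {
  n <- 4
  phi <- c(NA, -57, -57, -57); psi <- rep(-47, n)
  conf <- build_from_torsions(strrep("A", n),
                              list(phi = phi, psi = psi, omega = rep(180, n)))
  ca <- vapply(1:n, function(i) swaloop:::aidx(conf, i, "CA"), integer(1))
  d_pkg <- sqrt(rowSums(diff(conf$xyz[ca, ])^2))
  P <- oracle_bb_build(phi, psi, n)
  ca_o <- seq(2, 4 * n, by = 4)
  d_orc <- sqrt(rowSums(diff(P[ca_o, ])^2))
  expect_equal(d_pkg, d_orc, tolerance = 1e-9)
  # all consecutive CA-CA distances equal one constant for trans bonds
  expect_lt(max(d_pkg) - min(d_pkg), 1e-6)
})

test_that("torsion measurement round-trips through reconstruction", {
  set.seed(42)
  n <- 6
  phi <- c(NA, runif(n - 1, -180, 179))
  psi <- runif(n, -180, 179)
  conf <- build_from_torsions("ASGLTV",
                              list(phi = phi, psi = psi, omega = rep(180, n)))
  m <- measure_torsions(conf)
  expect_equal(m$bb[-1, "phi"], phi[-1], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(abs(m$bb[-1, "omega"]), rep(180, n - 1), tolerance = 1e-4,
               ignore_attr = TRUE)
  rebuilt <- build_from_torsions("ASGLTV",
                                 list(phi = m$bb[, "phi"], psi = m$bb[, "psi"],
                                      omega = c(NA, rep(180, n - 1)),
                                      chi = m$chi))
  expect_lt(max(abs(rebuilt$xyz[1:4, ] - conf$xyz[1:4, ])), 1e-6)
  # same atoms by (res, name): compare via lookup
  for (r in 1:n) for (a in c("N", "CA", "C", "O")) {
    i1 <- swaloop:::aidx(conf, r, a); i2 <- swaloop:::aidx(rebuilt, r, a)
    expect_lt(max(abs(conf$xyz[i1, ] - rebuilt$xyz[i2, ])), 1e-6)
  }
})

test_that("bond lengths and angles stay ideal after torsion edits", {
  fx <- tiny_problem()
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  conf <- set_torsion(conf, 3, "phi", -100)
  conf <- set_torsion(conf, 3, "psi", 40)
  N <- swaloop:::axyz(conf, 3, "N"); CA <- swaloop:::axyz(conf, 3, "CA")
  C <- swaloop:::axyz(conf, 3, "C")
  expect_equal(sqrt(sum((CA - N)^2)), 1.458, tolerance = 1e-6)
  expect_equal(sqrt(sum((C - CA)^2)), 1.525, tolerance = 1e-6)
  expect_equal(bond_angle(N, CA, C), 111.2, tolerance = 1e-6)
})

test_that("append adds a methylamide cap with a trans peptide bond", {
  fx <- tiny_problem()
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  expect_equal(conf$built[3], "nfrag")
  expect_equal(conf$caps$n, 3L)
  expect_gt(swaloop:::aidx(conf, 3, "NM"), 0L)
  expect_equal(abs(get_torsion(conf, 3, "omega")), 180, tolerance = 1e-6)
  # cap atoms are removed when the next residue is appended
  conf2 <- append_capped_residue(conf, 4, phi = -63, psi = -43)
  expect_equal(swaloop:::aidx(conf2, 3, "NM"), 0L)
  expect_equal(conf2$caps$n, 4L)
})

test_that("prepend adds an acetyl cap and matches batch construction", {
  fx <- tiny_problem()
  c1 <- prepend_capped_residue(fx$problem, 5, phi = -70, psi = 150)
  expect_equal(c1$built[5], "cfrag")
  expect_equal(c1$caps$c, 5L)
  expect_gt(swaloop:::aidx(c1, 5, "CP"), 0L)
  c2 <- prepend_capped_residue(c1, 4, phi = -63, psi = -43)
  # same torsions applied in one go on a fresh problem
  d1 <- prepend_capped_residue(fx$problem, 5, phi = -70, psi = 150)
  d2 <- prepend_capped_residue(d1, 4, phi = -63, psi = -43)
  for (r in 4:5) for (a in c("N", "CA", "C", "O")) {
    i1 <- swaloop:::aidx(c2, r, a); i2 <- swaloop:::aidx(d2, r, a)
    expect_lt(max(abs(c2$xyz[i1, ] - d2$xyz[i2, ])), 1e-9)
  }
})

test_that("set_torsion is local, last-write-wins, and guards the scaffold", {
  fx <- tiny_problem()
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  up <- which(conf$atoms$res %in% c(1, 2))
  c2 <- set_torsion(conf, 3, "phi", -100)
  expect_equal(get_torsion(c2, 3, "phi"), -100, tolerance = 1e-6)
  expect_equal(max(abs(c2$xyz[up, ] - conf$xyz[up, ])), 0)
  c3 <- set_torsion(set_torsion(conf, 3, "phi", -80), 3, "phi", -100)
  expect_lt(max(abs(c3$xyz - c2$xyz)), 1e-9)
  expect_error(set_torsion(conf, 2, "phi", 10), "fixed scaffold")
})

test_that("rotations respect the cutpoint boundary", {
  fx <- tiny_problem(seq1 = "AAGAAAA", loop = c(3, 5))
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  conf <- prepend_capped_residue(conf, 5, phi = -70, psi = 150)
  conf <- append_residue(conf, 4, phi = -63, psi = -43)
  conf <- swaloop:::add_cutpoint(conf, 4)
  beyond <- which(conf$atoms$res >= 5 & !conf$atoms$virtual)
  c2 <- set_torsion(conf, 3, "psi", 60)
  expect_equal(max(abs(c2$xyz[beyond, ] - conf$xyz[beyond, ])), 0)
})

test_that("construction errors are informative", {
  expect_error(aa_three("AXB"), "unknown residue")
  expect_error(build_from_torsions("AAA",
                                   list(phi = c(NA, -60, -60),
                                        psi = rep(130, 3)),
                                   anchor_frame = rbind(c(0, 0, 0),
                                                        c(1, 0, 0),
                                                        c(2, 0, 0))),
               "collinear")
})

test_that("L-amino-acid chirality is preserved by the side-chain template", {
  conf <- tiny_chain()
  i <- 2
  v1 <- swaloop:::axyz(conf, i, "N") - swaloop:::axyz(conf, i, "CA")
  v2 <- swaloop:::axyz(conf, i, "C") - swaloop:::axyz(conf, i, "CA")
  v3 <- swaloop:::axyz(conf, i, "CB") - swaloop:::axyz(conf, i, "CA")
  expect_gt(det(cbind(v1, v2, v3)), 0)
})
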