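# Surrogate energy: weight dialects, pairwise terms against a brute-force
# oracle, hydrogen-bond geometry, Ramachandran tables, chainbreak and fade
# constraint, and the scoring invariants.

test_that("weight presets carry the two sampling dialects", {
  ws <- energy_weights("sampling")
  wm <- energy_weights("minimization")
  expect_equal(unname(ws["fa_rep"]), 0.10)
  expect_equal(unname(wm["fa_rep"]), 0.44)
  expect_equal(unname(ws["hbond_sc"]), 3.1)
  expect_equal(unname(wm["hbond_sc"]), 1.1)
  expect_error(energy_weights("sampling", fa_rep = -1), "non-negative")
  expect_error(energy_weights("sampling", nonsense = 1), "unknown")
})

# independent scalar oracle for the pairwise terms (plain R loops)
oracle_pair_terms <- function(conf, cutoff = 6, eps = 0.15) {
  excl <- swaloop:::conf_exclusions(conf)
  ek <- paste(pmin(excl[, 1], excl[, 2]), pmax(excl[, 1], excl[, 2]))
  n <- nrow(conf$xyz)
  at <- conf$atoms
  atr <- rep_ <- hb_bb <- hb_sc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (at$virtual[i] || at$virtual[j]) next
    if (paste(i, j) %in% ek) next
    r <- sqrt(sum((conf$xyz[i, ] - conf$xyz[j, ])^2))
    if (r >= cutoff) next
    rmin <- at$radius[i] + at$radius[j]
    r0 <- 0.6 * rmin
    lj <- function(x) eps * ((rmin / x)^12 - 2 * (rmin / x)^6)
    v <- if (r >= r0) lj(r) else {
      s0 <- eps * (-12 * (rmin / r0)^12 + 12 * (rmin / r0)^6) / r0
      lj(r0) + s0 * (r - r0)
    }
    if (r < rmin) {
      rep_ <- rep_ + v + eps
      atr <- atr - eps
    } else {
      sw <- if (r > cutoff - 0.5) {
        t <- (cutoff - r) / 0.5; t^2 * (3 - 2 * t)
      } else 1
      atr <- atr + v * sw
    }
    hp <- NULL
    if (at$hclass[i] == 1 && at$hclass[j] == 2) hp <- c(i, j)
    if (at$hclass[j] == 1 && at$hclass[i] == 2) hp <- c(j, i)
    if (!is.null(hp)) {
      d <- at$hparent[hp[1]]
      if (d > 0 && !(paste(min(d, hp[2]), max(d, hp[2])) %in% ek)) {
        e <- hbond_term(conf$xyz[d, ], conf$xyz[hp[1], ], conf$xyz[hp[2], ])
        if (at$bb[hp[1]] && at$bb[hp[2]]) hb_bb <- hb_bb + e
        else hb_sc <- hb_sc + e
      }
    }
  }
  c(fa_atr = atr, fa_rep = rep_, hbond_bb = hb_bb, hbond_sc = hb_sc)
}

test_that("pair terms equal a brute-force scalar oracle", {
  conf <- tiny_chain()
  got <- score(conf, energy_weights("sampling"))$terms
  want <- oracle_pair_terms(conf)
  expect_equal(got[c("fa_atr", "fa_rep", "hbond_bb", "hbond_sc")],
               want, tolerance = 1e-9)
})

test_that("overlapping atoms score a finite capped repulsion", {
  conf <- tiny_chain()
  n <- nrow(conf$xyz)
  # duplicate an oxygen right on top of a distant nitrogen
  i <- swaloop:::aidx(conf, 1, "O")
  j <- swaloop:::aidx(conf, 5, "N")
  conf$xyz[i, ] <- conf$xyz[j, ]
  br <- score(conf, energy_weights("minimization"))
  expect_true(is.finite(br$total))
  expect_gt(br$terms["fa_rep"], 10)
})

test_that("hydrogen bond geometry follows the 3.2 A hard cutoff", {
  D <- c(0, 0, 0); H <- c(1.0, 0, 0)
  A29 <- c(2.9, 0, 0); A35 <- c(3.5, 0, 0)
  expect_lt(hbond_term(D, H, A29), 0)
  expect_equal(hbond_term(D, H, A35), 0)
  eps <- 1e-7
  expect_lt(abs(hbond_term(D, H, c(3.2 - eps, 0, 0))), 1e-6)
  # perpendicular approach gains nothing
  expect_equal(hbond_term(D, c(0, 1, 0), c(2.9, 0, 0)), 0)
})

test_that("ramachandran tables separate residue classes", {
  # canonical alpha helix must pass the 0.8 filter for alanine
  expect_lte(rama_score("ALA", -60, -45), 0.8)
  # left-handed glycine region: gly passes where the generic table rejects
  expect_lte(rama_score("gly", 80, 10), 0.8)
  expect_gt(rama_score("generic", 80, 10), 0.8)
  # bilinear interpolation reproduces the node value exactly
  tab <- read.delim(system.file("extdata", "rama_generic.tsv",
                                package = "swaloop"))
  row <- tab[tab$phi == -60 & tab$psi == -40, ]
  expect_equal(rama_score("generic", -60, -40), row$score, tolerance = 1e-9)
  # tables are shifted so the minimum is at most 0
  expect_lte(min(tab$score), 1e-9)
})

test_that("linear chainbreak sums the three virtual-atom deviations", {
  fx <- tiny_problem(seq1 = "AAGAAAA", loop = c(3, 5))
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  conf <- prepend_capped_residue(conf, 5, phi = -63, psi = -43)
  conf <- append_residue(conf, 4, phi = -63, psi = -43)
  conf <- swaloop:::add_cutpoint(conf, 4)
  prs <- swaloop:::chainbreak_pairs(conf)
  # oracle: direct distance sum
  want <- sum(sqrt(rowSums((conf$xyz[prs[, 1], ] - conf$xyz[prs[, 2], ])^2)))
  expect_equal(linear_chainbreak(conf), want, tolerance = 1e-12)
  # translating the C side rigidly by 1 A adds exactly 3.0 when starting
  # from perfect closure
  closed <- conf
  closed$xyz[prs[, 1], ] <- closed$xyz[prs[, 2], ]  # force exact closure
  expect_equal(linear_chainbreak(closed), 0)
  cside <- which(closed$atoms$res >= 5 | closed$atoms$name == "OVU1")
  shifted <- closed
  shifted$xyz[prs[, 2][1:2], ] <-
    sweep(shifted$xyz[prs[, 2][1:2], , drop = FALSE], 2, c(1, 0, 0), "+")
  shifted$xyz[prs[, 1][3], ] <- shifted$xyz[prs[, 1][3], ] + c(1, 0, 0)
  expect_equal(linear_chainbreak(shifted), 3.0, tolerance = 1e-12)
  expect_error(linear_chainbreak(fx$problem), "cutpoint")
})

test_that("the fade constraint is the Hermite cubic between its knots", {
  conf <- tiny_chain()
  ref <- conf$xyz[swaloop:::aidx(conf, 3, "CA"), , drop = FALSE]
  rownames(ref) <- 3
  shift <- function(d) {
    c2 <- conf
    i <- swaloop:::aidx(conf, 3, "CA")
    c2$xyz[i, ] <- c2$xyz[i, ] + c(d, 0, 0)
    c2
  }
  expect_equal(ca_fade_constraint(shift(1.0), ref), 0)
  expect_equal(ca_fade_constraint(shift(5.0), ref), 10.0)
  expect_equal(ca_fade_constraint(shift(3.0), ref), 5.0, tolerance = 1e-9)
  # derived check of the unique zero-end-slope cubic at an off-center point
  t <- (2.5 - 2) / 2
  expect_equal(ca_fade_constraint(shift(2.5), ref), 10 * (3 * t^2 - 2 * t^3),
               tolerance = 1e-9)
  expect_error(ca_fade_constraint(conf, ref, r_lo = 4, r_hi = 2), "r_lo")
})

test_that("energy is invariant under rigid-body motion", {
  conf <- tiny_chain()
  e0 <- score(conf, energy_weights("sampling"))$total
  set.seed(7)
  for (rep in 1:3) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -pi, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    c2 <- conf
    c2$xyz <- conf$xyz %*% t(R) +
      matrix(rnorm(3, sd = 5), nrow(conf$xyz), 3, byrow = TRUE)
    expect_lt(abs(score(c2, energy_weights("sampling"))$total - e0), 1e-6)
  }
})

test_that("incremental scoring with a cache matches a full recompute", {
  fx <- tiny_problem()
  conf <- append_capped_residue(fx$problem, 3, phi = -63, psi = -43)
  movable <- which(conf$atoms$res == 3)
  full <- score(conf, energy_weights("sampling"))$total
  incr <- score(conf, energy_weights("sampling"), movable = movable)$total
  expect_lt(abs(full - incr), 1e-6)
})

test_that("doubling all weights doubles the total", {
  conf <- tiny_chain()
  w1 <- energy_weights("minimization")
  w2 <- structure(unclass(w1) * 2, class = "EnergyWeights",
                  names = names(w1))
  expect_equal(score(conf, w2)$total, 2 * score(conf, w1)$total,
               tolerance = 1e-9)
  br <- score(conf, w1)
  expect_equal(br$total, sum(unclass(w1) * br$terms), tolerance = 1e-9)
})
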