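# Shared builders for the test suite.  Everything is generated in code; no
# stored fixtures.

# small mixed-sequence chain built from canonical torsions
tiny_chain <- function(seq1 = "AASGA",
                       phi = c(NA, -63, -63, -120, -70),
                       psi = c(140, -43, -43, 130, 150)) {
  build_from_torsions(seq1, list(phi = phi, psi = psi,
                                 omega = rep(180, nchar(seq1))))
}

# a loop problem on an all-small-residue chain: full native built first,
# then stripped to a scaffold with the loop unbuilt
tiny_problem <- function(seq1 = "AAGAAAA", loop = c(3, 5),
                         phi = NULL, psi = NULL) {
  n <- nchar(seq1)
  if (is.null(phi)) phi <- c(NA, rep(-63, n - 1))
  if (is.null(psi)) psi <- rep(-43, n)
  native <- build_from_torsions(seq1, list(phi = phi, psi = psi,
                                           omega = rep(180, n)))
  native$loop <- loop
  prob <- swaloop:::make_problem_from_native(native)
  list(problem = prob, native = native, loop = loop)
}

# independent NeRF-style backbone builder (scratch oracle, N/CA/C/O only)
oracle_bb_build <- function(phi, psi, n) {
  P <- matrix(NA_real_, 4 * n, 3)
  idx <- function(r, a) (r - 1) * 4 + a
  P[1, ] <- c(0, 0, 0)
  P[2, ] <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  P[3, ] <- P[2, ] + 1.525 * c(cos(th), sin(th), 0)
  P[4, ] <- oracle_place(P[1, ], P[2, ], P[3, ], 1.231, 120.8, psi[1] - 180)
  for (r in 2:n) {
    Np <- P[idx(r - 1, 1), ]; CAp <- P[idx(r - 1, 2), ]; Cp <- P[idx(r - 1, 3), ]
    N <- oracle_place(Np, CAp, Cp, 1.329, 116.2, psi[r - 1])
    CA <- oracle_place(CAp, Cp, N, 1.458, 121.7, 180)
    C <- oracle_place(Cp, N, CA, 1.525, 111.2, phi[r])
    O <- oracle_place(N, CA, C, 1.231, 120.8, psi[r] - 180)
    P[idx(r, 1), ] <- N; P[idx(r, 2), ] <- CA
    P[idx(r, 3), ] <- C; P[idx(r, 4), ] <- O
  }
  P
}

# scratch internal-coordinate placement written independently of the
# package implementation (quaternion-free, rotation-matrix route)
oracle_place <- function(A, B, C, bond, ang, tors) {
  d2r <- pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  th <- ang * d2r; ta <- tors * d2r
  C + (-bond * cos(th)) * bc + (bond * sin(th) * cos(ta)) * m +
    (-bond * sin(th) * sin(ta)) * n
}

# scratch signed dihedral (independent formula: atan2 of projections)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
  c23 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
           b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(c12 * c23)
  y <- sum(b1 * c23) * sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

# deterministic coarse config for pipeline tests
test_config <- function(...) {
  swa_config("coarse", ...)
}

# scratch greedy leader clustering (independent implementation)
oracle_leader <- function(coords, energies, radius, keep) {
  ord <- order(energies)
  kept <- integer(0)
  m <- ncol(coords) / 3
  for (o in ord) {
    if (length(kept) >= keep) break
    close_to_leader <- FALSE
    for (k in kept) {
      rmsd <- sqrt(sum((coords[o, ] - coords[k, ])^2) / m)
      if (rmsd < radius) { close_to_leader <- TRUE; break }
    }
    if (!close_to_leader) kept <- c(kept, o)
  }
  kept
}

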