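# The Conformation object: an all-atom model of scaffold + partially built
# loop.  Atoms live in a flat table (parallel to an n x 3 coordinate matrix)
# carrying a bonded-parent pointer, so the molecule is a tree (forest while
# the loop gap is open).  All loop atoms are placed from ideal internal
# coordinates; scaffold backbone atoms never move.  Caps (methylamide after
# the N-fragment terminus, acetyl before the C-fragment terminus) and the
# three virtual closure atoms at a cutpoint are ordinary rows flagged
# appropriately.

.CAP_N_ATOMS <- c("NM", "CM", "HM")     # methylamide cap (C-terminal of N fragment)
.CAP_C_ATOMS <- c("CP", "OP", "CMP")    # acetyl cap (N-terminal of C fragment)
.VIRTUAL_ATOMS <- c("OVL1", "OVL2", "OVU1")
.BB_NAMES <- c("N", "CA", "C", "O", "H")

# ring-closure bonds absent from the build tree; needed for the nonbonded
# exclusion graph so ring atoms are not scored against each other
.RING_BONDS <- list(
  PRO = list(c("N", "CD")),
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")))

.atom_radii <- function() {
  if (is.null(.swa_cache$radii)) {
    tab <- .swa_table("atom_radii.tsv")
    .swa_cache$radii <- setNames(tab$radius, tab$elem)
  }
  .swa_cache$radii
}

# ---- construction ---------------------------------------------------------

new_conformation <- function(seq3, loop = NULL) {
  n <- length(seq3)
  structure(list(
    seq = seq3,
    nres = n,
    xyz = matrix(numeric(0), ncol = 3),
    atoms = data.frame(res = integer(0), name = character(0),
                       elem = character(0), bb = logical(0),
                       virtual = logical(0), hclass = integer(0),
                       hparent = integer(0), radius = numeric(0),
                       parent = integer(0), stringsAsFactors = FALSE),
    built = rep("unbuilt", n),
    bb_tor = matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega"))),
    chi = vector("list", n),
    loop = loop,
    cutpoint = NA_integer_,
    caps = list(n = NA_integer_, c = NA_integer_),
    offset = 0L,
    excl = NULL),
    class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  cat("Conformation:", x$nres, "residues,", nrow(x$xyz), "atoms\n")
  cat("  sequence:", paste(aa_one(x$seq), collapse = ""), "\n")
  cat("  built:   ", paste(substr(x$built, 1, 1), collapse = ""),
      " (s=scaffold n=N-fragment c=C-fragment u=unbuilt)\n", sep = "")
  if (!is.null(x$loop)) cat("  loop:", x$loop[1], "-", x$loop[2], "\n")
  if (!is.na(x$cutpoint)) cat("  cutpoint after residue", x$cutpoint, "\n")
  invisible(x)
}

# index of atom `name` in residue `res` (0 if absent)
aidx <- function(conf, res, name) {
  hit <- which(conf$atoms$res == res & conf$atoms$name == name)
  if (length(hit)) hit[1] else 0L
}

axyz <- function(conf, res, name) {
  i <- aidx(conf, res, name)
  if (!i) stop("missing atom ", name, " in residue ", res)
  conf$xyz[i, ]
}

add_atom <- function(conf, res, name, elem, pos, parent, bb, virtual = FALSE) {
  rad <- .atom_radii()
  hclass <- if (elem == "H") 1L
            else if (elem == "O" || (name == "ND1" && conf$seq[res] == "HIS")) 2L
            else 0L
  conf$atoms <- rbind(conf$atoms, data.frame(
    res = as.integer(res), name = name, elem = elem, bb = bb,
    virtual = virtual, hclass = hclass,
    hparent = if (hclass == 1L) as.integer(parent) else 0L,
    radius = unname(rad[elem]), parent = as.integer(parent),
    stringsAsFactors = FALSE))
  conf$xyz <- rbind(conf$xyz, matrix(pos, 1, 3))
  conf$excl <- NULL
  conf
}

remove_atoms <- function(conf, idx) {
  if (!length(idx)) return(conf)
  keep <- setdiff(seq_len(nrow(conf$xyz)), idx)
  map <- integer(nrow(conf$xyz)); map[keep] <- seq_along(keep)
  if (any(conf$atoms$parent[keep] %in% idx))
    stop("cannot remove atoms that still have bonded children")
  conf$atoms <- conf$atoms[keep, , drop = FALSE]
  rownames(conf$atoms) <- NULL
  map0 <- c(0L, map)  # index 0 (no parent) maps to 0
  conf$atoms$parent <- map0[conf$atoms$parent + 1L]
  conf$atoms$hparent <- map0[conf$atoms$hparent + 1L]
  conf$xyz <- conf$xyz[keep, , drop = FALSE]
  conf$excl <- NULL
  conf
}

# ---- side chains ----------------------------------------------------------

# default chi: first canonical rotamer of the library (180s fallback)
default_chi <- function(res3) {
  n <- n_chi(res3)
  if (n == 0L) return(numeric(0))
  lib <- rotamer_library(res3)
  if (nrow(lib)) as.numeric(lib[1, seq_len(n)]) else rep(180, n)
}

add_sidechain <- function(conf, i, chi = NULL) {
  res3 <- conf$seq[i]
  if (res3 == "GLY") { conf$chi[[i]] <- numeric(0); return(conf) }
  rows <- residue_topology(res3)
  if (is.null(chi)) chi <- default_chi(res3)
  for (r in seq_len(nrow(rows))) {
    rr <- rows[r, ]
    tors <- if (rr$ttype == "fix") rr$tors else {
      k <- as.integer(sub("chi", "", rr$ttype))
      chi[k] + rr$tors
    }
    A <- axyz(conf, i, rr$a1); B <- axyz(conf, i, rr$a2); C <- axyz(conf, i, rr$a3)
    pos <- place_atom(A, B, C, rr$bond, rr$ang, tors)
    conf <- add_atom(conf, i, rr$atom, rr$elem, pos,
                     parent = aidx(conf, i, rr$a3), bb = FALSE)
  }
  conf$chi[[i]] <- chi
  conf
}

remove_sidechain <- function(conf, i) {
  sel <- which(conf$atoms$res == i & !conf$atoms$bb & !conf$atoms$virtual)
  conf <- remove_atoms(conf, rev(sel))
  conf$chi[i] <- list(numeric(0))
  conf
}

# replace the side chain of residue i with the given chi vector
set_sidechain <- function(conf, i, chi) {
  conf <- remove_sidechain(conf, i)
  add_sidechain(conf, i, chi)
}

# re-place existing side-chain atoms for a new chi vector without touching
# the atom table (keeps caches valid); atoms must already be present
set_sidechain_chi <- function(conf, i, chi) {
  rows <- residue_topology(conf$seq[i])
  for (r in seq_len(nrow(rows))) {
    rr <- rows[r, ]
    tors <- if (rr$ttype == "fix") rr$tors else {
      k <- as.integer(sub("chi", "", rr$ttype))
      chi[k] + rr$tors
    }
    idx <- aidx(conf, i, rr$atom)
    if (!idx) stop("missing side-chain atom ", rr$atom, " in residue ", i)
    conf$xyz[idx, ] <- place_atom(axyz(conf, i, rr$a1), axyz(conf, i, rr$a2),
                                  axyz(conf, i, rr$a3), rr$bond, rr$ang, tors)
  }
  conf$chi[[i]] <- chi
  conf
}

# ---- backbone growth ------------------------------------------------------

# Append residue i forward onto residue i-1 (which must have N/CA/C placed).
append_residue <- function(conf, i, phi, psi, omega = 180, chi = NULL) {
  if (conf$built[i] != "unbuilt") stop("residue ", i, " already built")
  p <- i - 1L
  if (p < 1L || !aidx(conf, p, "C"))
    stop("residue ", i, " is not adjacent to a built N-terminal fragment")
  if (!is.na(conf$caps$n) && conf$caps$n == p) conf <- remove_cap_n(conf)
  Np <- axyz(conf, p, "N"); CAp <- axyz(conf, p, "CA"); Cp <- axyz(conf, p, "C")
  psip <- conf$bb_tor[p, "psi"]
  if (is.na(psip)) {  # anchor residue: psi implied by its carbonyl O
    psip <- wrap_angle(dihedral(Np, CAp, Cp, axyz(conf, p, "O")) + 180)
    conf$bb_tor[p, "psi"] <- psip
  }
  N <- place_atom(Np, CAp, Cp, .BB$b_CN, .BB$a_CACN, psip)
  conf <- add_atom(conf, i, "N", "N", N, parent = aidx(conf, p, "C"), bb = TRUE)
  CA <- place_atom(CAp, Cp, N, .BB$b_NCA, .BB$a_CNCA, omega)
  conf <- add_atom(conf, i, "CA", "C", CA, parent = aidx(conf, i, "N"), bb = TRUE)
  C <- place_atom(Cp, N, CA, .BB$b_CAC, .BB$a_NCAC, phi)
  conf <- add_atom(conf, i, "C", "C", C, parent = aidx(conf, i, "CA"), bb = TRUE)
  O <- place_atom(N, CA, C, .BB$b_CO, .BB$a_CACO, wrap_angle(psi - 180))
  conf <- add_atom(conf, i, "O", "O", O, parent = aidx(conf, i, "C"), bb = TRUE)
  if (conf$seq[i] != "PRO") {
    H <- place_atom(CA, Cp, N, .BB$b_NH, .BB$a_CNH, 180)
    conf <- add_atom(conf, i, "H", "H", H, parent = aidx(conf, i, "N"), bb = TRUE)
  }
  conf <- add_sidechain(conf, i, chi)
  conf$bb_tor[i, ] <- c(phi, psi, omega)
  conf$built[i] <- "nfrag"
  conf
}

# Prepend residue j backward onto residue j+1 (which must have N/CA/C).
prepend_residue <- function(conf, j, phi, psi, omega = 180, chi = NULL) {
  if (conf$built[j] != "unbuilt") stop("residue ", j, " already built")
  nx <- j + 1L
  if (nx > conf$nres || !aidx(conf, nx, "N"))
    stop("residue ", j, " is not adjacent to a built C-terminal fragment")
  if (!is.na(conf$caps$c) && conf$caps$c == nx) conf <- remove_cap_c(conf)
  Nn <- axyz(conf, nx, "N"); CAn <- axyz(conf, nx, "CA"); Cn <- axyz(conf, nx, "C")
  phin <- conf$bb_tor[nx, "phi"]
  if (is.na(phin)) {  # anchor residue: phi implied by its amide H if present
    hi <- aidx(conf, nx, "H")
    phin <- if (hi) wrap_angle(dihedral(conf$xyz[hi, ], Nn, CAn, Cn) + 180) else -120
    conf$bb_tor[nx, "phi"] <- phin
  }
  omn <- conf$bb_tor[nx, "omega"]
  if (is.na(omn)) { omn <- 180; conf$bb_tor[nx, "omega"] <- omn }
  C <- place_atom(Cn, CAn, Nn, .BB$b_CN, .BB$a_CNCA, phin)
  conf <- add_atom(conf, j, "C", "C", C, parent = aidx(conf, nx, "N"), bb = TRUE)
  CA <- place_atom(CAn, Nn, C, .BB$b_CAC, .BB$a_CACN, omn)
  conf <- add_atom(conf, j, "CA", "C", CA, parent = aidx(conf, j, "C"), bb = TRUE)
  N <- place_atom(Nn, C, CA, .BB$b_NCA, .BB$a_NCAC, psi)
  conf <- add_atom(conf, j, "N", "N", N, parent = aidx(conf, j, "CA"), bb = TRUE)
  O <- place_atom(N, CA, C, .BB$b_CO, .BB$a_CACO, wrap_angle(psi - 180))
  conf <- add_atom(conf, j, "O", "O", O, parent = aidx(conf, j, "C"), bb = TRUE)
  conf <- add_sidechain(conf, j, chi)
  conf$bb_tor[j, ] <- c(phi, psi, omega)
  conf$built[j] <- "cfrag"
  conf
}

# ---- caps -----------------------------------------------------------------

add_cap_n <- function(conf, i) {
  if (!is.na(conf$caps$n)) stop("N-fragment cap already present")
  N <- axyz(conf, i, "N"); CA <- axyz(conf, i, "CA"); C <- axyz(conf, i, "C")
  psi <- conf$bb_tor[i, "psi"]
  NM <- place_atom(N, CA, C, .BB$b_CN, .BB$a_CACN, psi)
  conf <- add_atom(conf, i, "NM", "N", NM, parent = aidx(conf, i, "C"), bb = TRUE)
  CM <- place_atom(CA, C, NM, .BB$b_NCA, .BB$a_CNCA, 180)
  conf <- add_atom(conf, i, "CM", "C", CM, parent = aidx(conf, i, "NM"), bb = TRUE)
  HM <- place_atom(CM, C, NM, .BB$b_NH, .BB$a_CNH, 180)
  conf <- add_atom(conf, i, "HM", "H", HM, parent = aidx(conf, i, "NM"), bb = TRUE)
  conf$caps$n <- as.integer(i)
  conf
}

remove_cap_n <- function(conf) {
  i <- conf$caps$n
  sel <- which(conf$atoms$res == i & conf$atoms$name %in% .CAP_N_ATOMS)
  conf <- remove_atoms(conf, sel[order(-sel)])
  conf$caps$n <- NA_integer_
  conf
}

add_cap_c <- function(conf, j) {
  if (!is.na(conf$caps$c)) stop("C-fragment cap already present")
  N <- axyz(conf, j, "N"); CA <- axyz(conf, j, "CA"); C <- axyz(conf, j, "C")
  phi <- conf$bb_tor[j, "phi"]
  om <- conf$bb_tor[j, "omega"]
  CP <- place_atom(C, CA, N, .BB$b_CN, .BB$a_CNCA, phi)
  conf <- add_atom(conf, j, "CP", "C", CP, parent = aidx(conf, j, "N"), bb = TRUE)
  CMP <- place_atom(CA, N, CP, .BB$b_CAC, .BB$a_CACN, om)
  conf <- add_atom(conf, j, "CMP", "C", CMP, parent = aidx(conf, j, "CP"), bb = TRUE)
  OP <- place_atom(CA, N, CP, .BB$b_CO, .BB$a_NCO, 0)
  conf <- add_atom(conf, j, "OP", "O", OP, parent = aidx(conf, j, "CP"), bb = TRUE)
  if (conf$seq[j] != "PRO" && !aidx(conf, j, "H")) {
    H <- place_atom(CA, CP, N, .BB$b_NH, .BB$a_CNH, 180)
    conf <- add_atom(conf, j, "H", "H", H, parent = aidx(conf, j, "N"), bb = TRUE)
  }
  conf$caps$c <- as.integer(j)
  conf
}

remove_cap_c <- function(conf) {
  j <- conf$caps$c
  sel <- which(conf$atoms$res == j & conf$atoms$name %in% .CAP_C_ATOMS)
  conf <- remove_atoms(conf, sel[order(-sel)])
  conf$caps$c <- NA_integer_
  conf
}

# convenience wrappers matching the build-up protocol ----------------------

#' Append a capped residue to the N-terminal loop fragment
#'
#' Adds residue \code{pos} with ideal geometry and a methylamide cap
#' presenting the next peptide unit's amide group, removing the previous
#' cap if one is present.
#'
#' @param conf a \code{Conformation}.
#' @param pos residue index (1-based) to add; must be the next unbuilt
#'   residue after the N-fragment terminus.
#' @param phi,psi,omega backbone torsions for the new residue (degrees).
#' @param chi optional side-chain chi vector.
#' @return the updated \code{Conformation}.
#' @export
append_capped_residue <- function(conf, pos, phi = -120, psi = 130,
                                  omega = 180, chi = NULL) {
  conf <- append_residue(conf, pos, phi, psi, omega, chi)
  add_cap_n(conf, pos)
}

#' Prepend a capped residue to the C-terminal loop fragment
#'
#' Mirror of \code{\link{append_capped_residue}}: adds residue \code{pos}
#' with an acetyl cap presenting the preceding peptide unit's carbonyl.
#' \code{omega} is the torsion of the (future) bond to residue
#' \code{pos - 1}; it may be 0 for a cis peptide bond at proline.
#'
#' @inheritParams append_capped_residue
#' @return the updated \code{Conformation}.
#' @export
prepend_capped_residue <- function(conf, pos, phi = -120, psi = 130,
                                   omega = 180, chi = NULL) {
  conf <- prepend_residue(conf, pos, phi, psi, omega, chi)
  add_cap_c(conf, pos)
}

# ---- cutpoint / virtual closure atoms ------------------------------------

# Install a formal chainbreak between residues c and c+1: removes any caps
# and adds the three virtual atoms whose deviation from their real
# counterparts measures closure error.
add_cutpoint <- function(conf, c) {
  if (!is.na(conf$cutpoint)) stop("cutpoint already set")
  if (!aidx(conf, c, "C") || !aidx(conf, c + 1L, "N"))
    stop("both sides of the cutpoint must be built")
  if (!is.na(conf$caps$n)) conf <- remove_cap_n(conf)
  if (!is.na(conf$caps$c)) conf <- remove_cap_c(conf)
  # break the build-tree bond across the cut (present when the chain was
  # built intact), so torsion rotations propagate toward the cutpoint
  ni <- aidx(conf, c + 1L, "N")
  if (ni && conf$atoms$parent[ni] == aidx(conf, c, "C")) {
    conf$atoms$parent[ni] <- 0L
    conf$excl <- NULL
  }
  N <- axyz(conf, c, "N"); CA <- axyz(conf, c, "CA"); C <- axyz(conf, c, "C")
  psi <- conf$bb_tor[c, "psi"]
  if (is.na(psi))
    psi <- wrap_angle(dihedral(N, CA, C, axyz(conf, c, "O")) + 180)
  ovl1 <- place_atom(N, CA, C, .BB$b_CN, .BB$a_CACN, psi)
  conf <- add_atom(conf, c, "OVL1", "N", ovl1, parent = aidx(conf, c, "C"),
                   bb = TRUE, virtual = TRUE)
  ovl2 <- place_atom(CA, C, ovl1, .BB$b_NCA, .BB$a_CNCA, 180)
  conf <- add_atom(conf, c, "OVL2", "C", ovl2, parent = aidx(conf, c, "OVL1"),
                   bb = TRUE, virtual = TRUE)
  cu <- c + 1L
  Nn <- axyz(conf, cu, "N"); CAn <- axyz(conf, cu, "CA"); Cn <- axyz(conf, cu, "C")
  phin <- conf$bb_tor[cu, "phi"]
  if (is.na(phin)) { phin <- -120; conf$bb_tor[cu, "phi"] <- phin }
  ovu1 <- place_atom(Cn, CAn, Nn, .BB$b_CN, .BB$a_CNCA, phin)
  conf <- add_atom(conf, cu, "OVU1", "C", ovu1, parent = aidx(conf, cu, "N"),
                   bb = TRUE, virtual = TRUE)
  if (conf$seq[cu] != "PRO" && !aidx(conf, cu, "H")) {
    H <- place_atom(CAn, ovu1, Nn, .BB$b_NH, .BB$a_CNH, 180)
    conf <- add_atom(conf, cu, "H", "H", H, parent = aidx(conf, cu, "N"),
                     bb = TRUE)
  }
  conf$cutpoint <- as.integer(c)
  conf
}

# the three virtual/real atom index pairs at the cutpoint
chainbreak_pairs <- function(conf) {
  c <- conf$cutpoint
  if (is.na(c)) stop("no cutpoint set")
  cbind(c(aidx(conf, c, "OVL1"), aidx(conf, c, "OVL2"), aidx(conf, c + 1L, "OVU1")),
        c(aidx(conf, c + 1L, "N"), aidx(conf, c + 1L, "CA"), aidx(conf, c, "C")))
}

# ---- nonbonded exclusions -------------------------------------------------

# atom pairs within 3 bonds (plus ring-closure and cutpoint pseudo-bonds),
# cached on the conformation until the atom table changes
conf_exclusions <- function(conf) {
  if (!is.null(conf$excl)) return(conf$excl)
  n <- nrow(conf$xyz)
  adj <- vector("list", n)
  addedge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b); adj[[b]] <<- c(adj[[b]], a)
  }
  for (k in seq_len(n)) {
    p <- conf$atoms$parent[k]
    if (p > 0L) addedge(k, p)
  }
  for (i in unique(conf$atoms$res)) {
    rb <- .RING_BONDS[[conf$seq[i]]]
    if (!is.null(rb)) for (pr in rb) {
      a <- aidx(conf, i, pr[1]); b <- aidx(conf, i, pr[2])
      if (a && b) addedge(a, b)
    }
  }
  if (!is.na(conf$cutpoint)) {
    a <- aidx(conf, conf$cutpoint, "C")
    b <- aidx(conf, conf$cutpoint + 1L, "N")
    if (a && b) addedge(a, b)
  }
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (s in seq_len(n)) {
    # BFS to depth 3
    dist <- rep(-1L, n); dist[s] <- 0L
    frontier <- s
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dist[nxt] < 0L]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    hit <- which(dist > 0L)
    hit <- hit[hit > s]
    pairs_a <- c(pairs_a, rep.int(s, length(hit)))
    pairs_b <- c(pairs_b, hit)
  }
  cbind(pairs_a, pairs_b)
}

# ---- whole-chain construction --------------------------------------------

#' Build a conformation from a torsion specification
#'
#' Constructs a full chain by sequential internal-coordinate placement with
#' ideal bond lengths and angles, starting from an anchor frame for the
#' first residue.
#'
#' @param sequence amino-acid sequence (one-letter string or vector of
#'   three-letter codes).
#' @param torsions list with numeric vectors \code{phi}, \code{psi},
#'   \code{omega} (degrees, one per residue; \code{omega[i]} is the torsion
#'   of the bond between residues i-1 and i) and optionally a list
#'   \code{chi} of per-residue chi vectors.
#' @param anchor_frame 3 x 3 matrix of points defining the placement of the
#'   first residue's N (row 1), the N-to-CA direction (row 2) and the
#'   build plane (row 3); defaults to a canonical frame at the origin.
#' @return a \code{Conformation} with all residues marked as scaffold.
#' @export
build_from_torsions <- function(sequence, torsions, anchor_frame = NULL) {
  seq3 <- if (all(sequence %in% .AA3)) sequence else aa_three(sequence)
  conf <- new_conformation(seq3)
  n <- length(seq3)
  if (n == 0L) return(conf)
  if (is.null(anchor_frame))
    anchor_frame <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  N1 <- anchor_frame[1, ]
  u <- anchor_frame[2, ] - N1
  w <- anchor_frame[3, ] - N1
  if (.vnorm(u) < 1e-8 || .vnorm(.vcross(u, w)) < 1e-8)
    stop("degenerate (collinear) anchor frame")
  u <- .vhat(u)
  v <- .vhat(w - sum(w * u) * u)
  CA1 <- N1 + .BB$b_NCA * u
  # C of residue 1 in the anchor plane at the ideal N-CA-C angle
  th <- (180 - .BB$a_NCAC) * .d2r
  C1 <- CA1 + .BB$b_CAC * (cos(th) * u + sin(th) * v)
  phi <- torsions$phi; psi <- torsions$psi; omega <- torsions$omega
  if (is.null(omega)) omega <- rep(180, n)
  chi <- torsions$chi
  conf <- add_atom(conf, 1L, "N", "N", N1, parent = 0L, bb = TRUE)
  conf <- add_atom(conf, 1L, "CA", "C", CA1, parent = aidx(conf, 1L, "N"), bb = TRUE)
  conf <- add_atom(conf, 1L, "C", "C", C1, parent = aidx(conf, 1L, "CA"), bb = TRUE)
  O1 <- place_atom(N1, CA1, C1, .BB$b_CO, .BB$a_CACO, wrap_angle(psi[1] - 180))
  conf <- add_atom(conf, 1L, "O", "O", O1, parent = aidx(conf, 1L, "C"), bb = TRUE)
  conf <- add_sidechain(conf, 1L, if (is.null(chi)) NULL else chi[[1]])
  conf$bb_tor[1, ] <- c(NA, psi[1], NA)
  conf$built[1] <- "scaffold"
  for (i in seq_len(n)[-1]) {
    conf <- append_residue(conf, i, phi[i], psi[i], omega[i],
                           chi = if (is.null(chi)) NULL else chi[[i]])
    conf$built[i] <- "scaffold"
  }
  conf
}

# measure all defined torsions from coordinates (degrees)
measure_torsions <- function(conf) {
  bb <- conf$bb_tor
  chi <- conf$chi
  for (i in seq_len(conf$nres)) {
    if (conf$built[i] == "unbuilt") next
    for (nm in c("phi", "psi", "omega")) {
      t <- torsion_atoms(conf, i, nm)
      if (!is.null(t))
        bb[i, nm] <- wrap_angle(dihedral(conf$xyz[t$A, ], conf$xyz[t$B, ],
                                         conf$xyz[t$C, ], conf$xyz[t$D, ]) + t$off)
    }
    nk <- length(conf$chi[[i]])
    if (nk) {
      tup <- chi_atoms(conf$seq[i])
      v <- numeric(nk)
      for (k in seq_len(nk)) {
        id <- vapply(tup[[k]], function(a) aidx(conf, i, a), integer(1))
        v[k] <- if (all(id > 0)) dihedral(conf$xyz[id[1], ], conf$xyz[id[2], ],
                                          conf$xyz[id[3], ], conf$xyz[id[4], ])
                else NA_real_
      }
      chi[[i]] <- v
    }
  }
  list(bb = bb, chi = chi)
}
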