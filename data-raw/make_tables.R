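# Generates the versioned plain-text data tables shipped in inst/extdata:
#   residue_topology.tsv  ideal internal coordinates for side-chain / polar-H atoms
#   rotamer_library.tsv   coarse backbone-independent chi rotamers
#   atom_radii.tsv        per-element packing radii
#   rama_<class>.tsv      Ramachandran log-odds tables (generic/gly/pro/prepro)
# Run from the package root: Rscript data-raw/make_tables.R
# The tables are constructed procedurally (Engh-Huber-like ideal geometry,
# Gaussian-mixture Ramachandran basins); they are not fit to external data.

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- residue topology ----------------------------------------------------
# One row per non-backbone atom (backbone N/CA/C/O/H placement rules live in
# the builder, which also places CB from this table's first row per residue).
# Placement: atom D bonded to a3; dihedral(a1,a2,a3,D) = tors (+ chi offset),
# angle(a2,a3,D) = ang, |a3-D| = bond.  ttype: "fix" or "chi1".."chi4"
# (tors is then an offset added to that chi).
rows <- list()
add <- function(res, atom, a1, a2, a3, bond, ang, tors, ttype, elem) {
  rows[[length(rows) + 1L]] <<- data.frame(
    res = res, atom = atom, a1 = a1, a2 = a2, a3 = a3,
    bond = bond, ang = ang, tors = tors, ttype = ttype, elem = elem,
    stringsAsFactors = FALSE)
}
# CB improper: dihedral(C, N, CA, CB) = +122.6 deg gives L-chirality with the
# builder's dihedral convention (verified by the chirality test).
cb <- function(res) add(res, "CB", "C", "N", "CA", 1.530, 110.5, 122.6, "fix", "C")

cb("ALA")

cb("SER")
add("SER", "OG",  "N",  "CA", "CB", 1.417, 110.8, 0,    "chi1", "O")
add("SER", "HG",  "CA", "CB", "OG", 0.960, 109.5, 0,    "chi2", "H")

cb("CYS")
add("CYS", "SG",  "N",  "CA", "CB", 1.808, 113.8, 0,    "chi1", "S")
add("CYS", "HG",  "CA", "CB", "SG", 1.330,  96.0, 0,    "chi2", "H")

cb("THR")
add("THR", "OG1", "N",  "CA", "CB", 1.433, 109.6, 0,    "chi1", "O")
add("THR", "CG2", "N",  "CA", "CB", 1.521, 110.5, -120, "chi1", "C")
add("THR", "HG1", "CA", "CB", "OG1", 0.960, 109.5, 0,   "chi2", "H")

cb("VAL")
add("VAL", "CG1", "N",  "CA", "CB", 1.521, 110.5, 0,    "chi1", "C")
add("VAL", "CG2", "N",  "CA", "CB", 1.521, 110.5, 122,  "chi1", "C")

cb("LEU")
add("LEU", "CG",  "N",  "CA", "CB", 1.530, 116.3, 0,    "chi1", "C")
add("LEU", "CD1", "CA", "CB", "CG", 1.521, 110.7, 0,    "chi2", "C")
add("LEU", "CD2", "CA", "CB", "CG", 1.521, 110.7, 122,  "chi2", "C")

cb("ILE")
add("ILE", "CG1", "N",  "CA", "CB", 1.530, 110.4, 0,    "chi1", "C")
add("ILE", "CG2", "N",  "CA", "CB", 1.521, 110.5, -122, "chi1", "C")
add("ILE", "CD1", "CA", "CB", "CG1", 1.513, 113.8, 0,   "chi2", "C")

cb("MET")
add("MET", "CG",  "N",  "CA", "CB", 1.520, 114.1, 0,    "chi1", "C")
add("MET", "SD",  "CA", "CB", "CG", 1.803, 112.7, 0,    "chi2", "S")
add("MET", "CE",  "CB", "CG", "SD", 1.791, 100.9, 0,    "chi3", "C")

cb("PRO")  # rigid ring template, single pucker; no sampled chi
add("PRO", "CG",  "N",  "CA", "CB", 1.492, 104.5, 25,   "fix", "C")
add("PRO", "CD",  "CA", "CB", "CG", 1.503, 106.1, -35,  "fix", "C")

cb("ASP")
add("ASP", "CG",  "N",  "CA", "CB", 1.516, 112.6, 0,    "chi1", "C")
add("ASP", "OD1", "CA", "CB", "CG", 1.249, 118.4, 0,    "chi2", "O")
add("ASP", "OD2", "CA", "CB", "CG", 1.249, 118.4, 180,  "chi2", "O")

cb("ASN")
add("ASN", "CG",  "N",  "CA", "CB", 1.516, 112.6, 0,    "chi1", "C")
add("ASN", "OD1", "CA", "CB", "CG", 1.231, 120.8, 0,    "chi2", "O")
add("ASN", "ND2", "CA", "CB", "CG", 1.328, 116.4, 180,  "chi2", "N")
add("ASN", "HD21", "CB", "CG", "ND2", 1.010, 120.0, 0,   "fix", "H")
add("ASN", "HD22", "CB", "CG", "ND2", 1.010, 120.0, 180, "fix", "H")

cb("GLU")
add("GLU", "CG",  "N",  "CA", "CB", 1.520, 114.1, 0,    "chi1", "C")
add("GLU", "CD",  "CA", "CB", "CG", 1.516, 112.6, 0,    "chi2", "C")
add("GLU", "OE1", "CB", "CG", "CD", 1.249, 118.4, 0,    "chi3", "O")
add("GLU", "OE2", "CB", "CG", "CD", 1.249, 118.4, 180,  "chi3", "O")

cb("GLN")
add("GLN", "CG",  "N",  "CA", "CB", 1.520, 114.1, 0,    "chi1", "C")
add("GLN", "CD",  "CA", "CB", "CG", 1.516, 112.6, 0,    "chi2", "C")
add("GLN", "OE1", "CB", "CG", "CD", 1.231, 120.8, 0,    "chi3", "O")
add("GLN", "NE2", "CB", "CG", "CD", 1.328, 116.4, 180,  "chi3", "N")
add("GLN", "HE21", "CG", "CD", "NE2", 1.010, 120.0, 0,   "fix", "H")
add("GLN", "HE22", "CG", "CD", "NE2", 1.010, 120.0, 180, "fix", "H")

cb("LYS")
add("LYS", "CG",  "N",  "CA", "CB", 1.520, 114.1, 0,    "chi1", "C")
add("LYS", "CD",  "CA", "CB", "CG", 1.520, 111.3, 0,    "chi2", "C")
add("LYS", "CE",  "CB", "CG", "CD", 1.520, 111.3, 0,    "chi3", "C")
add("LYS", "NZ",  "CG", "CD", "CE", 1.489, 111.9, 0,    "chi4", "N")
add("LYS", "HZ1", "CD", "CE", "NZ", 1.010, 109.5, 180,  "fix", "H")
add("LYS", "HZ2", "CD", "CE", "NZ", 1.010, 109.5, 60,   "fix", "H")
add("LYS", "HZ3", "CD", "CE", "NZ", 1.010, 109.5, -60,  "fix", "H")

cb("ARG")
add("ARG", "CG",  "N",  "CA", "CB", 1.520, 114.1, 0,    "chi1", "C")
add("ARG", "CD",  "CA", "CB", "CG", 1.520, 111.3, 0,    "chi2", "C")
add("ARG", "NE",  "CB", "CG", "CD", 1.460, 112.0, 0,    "chi3", "N")
add("ARG", "CZ",  "CG", "CD", "NE", 1.329, 124.2, 0,    "chi4", "C")
add("ARG", "NH1", "CD", "NE", "CZ", 1.326, 120.0, 0,    "fix", "N")
add("ARG", "NH2", "CD", "NE", "CZ", 1.326, 120.0, 180,  "fix", "N")
add("ARG", "HE",  "NH1", "CZ", "NE", 1.010, 118.0, 180, "fix", "H")
add("ARG", "HH11", "NE", "CZ", "NH1", 1.010, 120.0, 0,   "fix", "H")
add("ARG", "HH12", "NE", "CZ", "NH1", 1.010, 120.0, 180, "fix", "H")
add("ARG", "HH21", "NE", "CZ", "NH2", 1.010, 120.0, 0,   "fix", "H")
add("ARG", "HH22", "NE", "CZ", "NH2", 1.010, 120.0, 180, "fix", "H")

cb("HIS")
add("HIS", "CG",  "N",  "CA", "CB", 1.497, 113.8, 0,    "chi1", "C")
add("HIS", "ND1", "CA", "CB", "CG", 1.371, 122.7, 0,    "chi2", "N")
add("HIS", "CD2", "CA", "CB", "CG", 1.356, 129.1, 180,  "chi2", "C")
add("HIS", "CE1", "CB", "CG", "ND1", 1.319, 109.0, 180, "fix", "C")
add("HIS", "NE2", "CB", "CG", "CD2", 1.374, 107.2, 180, "fix", "N")
add("HIS", "HE2", "CG", "CD2", "NE2", 1.010, 125.0, 180, "fix", "H")

cb("PHE")
add("PHE", "CG",  "N",  "CA", "CB", 1.502, 113.8, 0,    "chi1", "C")
add("PHE", "CD1", "CA", "CB", "CG", 1.390, 120.8, 0,    "chi2", "C")
add("PHE", "CD2", "CA", "CB", "CG", 1.390, 120.8, 180,  "chi2", "C")
add("PHE", "CE1", "CB", "CG", "CD1", 1.390, 120.0, 180, "fix", "C")
add("PHE", "CE2", "CB", "CG", "CD2", 1.390, 120.0, 180, "fix", "C")
add("PHE", "CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0,  "fix", "C")

cb("TYR")
add("TYR", "CG",  "N",  "CA", "CB", 1.502, 113.8, 0,    "chi1", "C")
add("TYR", "CD1", "CA", "CB", "CG", 1.390, 120.8, 0,    "chi2", "C")
add("TYR", "CD2", "CA", "CB", "CG", 1.390, 120.8, 180,  "chi2", "C")
add("TYR", "CE1", "CB", "CG", "CD1", 1.390, 120.0, 180, "fix", "C")
add("TYR", "CE2", "CB", "CG", "CD2", 1.390, 120.0, 180, "fix", "C")
add("TYR", "CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0,  "fix", "C")
add("TYR", "OH",  "CD1", "CE1", "CZ", 1.376, 119.9, 180, "fix", "O")
add("TYR", "HH",  "CE1", "CZ", "OH", 0.960, 109.5, 180, "fix", "H")

cb("TRP")
add("TRP", "CG",  "N",  "CA", "CB", 1.498, 113.6, 0,    "chi1", "C")
add("TRP", "CD1", "CA", "CB", "CG", 1.365, 126.9, 0,    "chi2", "C")
add("TRP", "CD2", "CA", "CB", "CG", 1.433, 126.6, 180,  "chi2", "C")
add("TRP", "NE1", "CD2", "CG", "CD1", 1.374, 110.2, 0,  "fix", "N")
add("TRP", "CE2", "CD1", "CG", "CD2", 1.409, 107.2, 0,  "fix", "C")
add("TRP", "CE3", "CD1", "CG", "CD2", 1.400, 133.9, 180, "fix", "C")
add("TRP", "CZ2", "CG", "CD2", "CE2", 1.400, 122.4, 180, "fix", "C")
add("TRP", "CZ3", "CG", "CD2", "CE3", 1.390, 118.6, 180, "fix", "C")
add("TRP", "CH2", "CD2", "CE2", "CZ2", 1.370, 117.5, 0, "fix", "C")
add("TRP", "HE1", "CG", "CD1", "NE1", 1.010, 125.0, 180, "fix", "H")

topo <- do.call(rbind, rows)
write.table(topo, file.path(out, "residue_topology.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- rotamer library -----------------------------------------------------
# Coarse backbone-independent library: gauche+/trans/gauche- at sp3 chis,
# +/-90 at aromatic chi2; sigma 10 deg per chi (used by the +/-1-sigma
# chi1/chi2 expansion).  chi3/chi4 held at trans to keep candidate counts low.
nchi <- c(SER = 2, CYS = 2, THR = 2, VAL = 1, LEU = 2, ILE = 2, MET = 3,
          ASP = 2, ASN = 2, GLU = 3, GLN = 3, LYS = 4, ARG = 4, HIS = 2,
          PHE = 2, TYR = 2, TRP = 2)
aromatic2 <- c("HIS", "PHE", "TYR", "TRP")
g3 <- c(-60, 60, 180)
lib <- list()
for (res in names(nchi)) {
  n <- nchi[[res]]
  c1 <- g3
  c2 <- if (n >= 2) { if (res %in% aromatic2) c(-90, 90) else g3 } else NA
  grid <- expand.grid(chi1 = c1, chi2 = c2)
  grid$chi3 <- if (n >= 3) 180 else NA
  grid$chi4 <- if (n >= 4) 180 else NA
  grid$res <- res
  lib[[res]] <- grid
}
lib <- do.call(rbind, lib)
lib <- lib[, c("res", "chi1", "chi2", "chi3", "chi4")]
lib$sigma <- 10
write.table(lib, file.path(out, "rotamer_library.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

## ---- atomic radii --------------------------------------------------------
rad <- data.frame(elem = c("C", "N", "O", "S", "H"),
                  radius = c(1.75, 1.55, 1.40, 1.80, 0.95))
write.table(rad, file.path(out, "atom_radii.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- Ramachandran tables -------------------------------------------------
# -s*ln(mixture of wrapped Gaussian basins + floor), shifted so each table's
# minimum is 0.  The build-up filter (0.8 units) then retains roughly the
# +/-1.8-sigma core of each basin.
grid <- seq(-180, 160, by = 20)
mix <- function(phi, psi, basins, floor = 0.0035, scale = 0.5) {
  p <- floor
  for (b in basins) {
    dphi <- ((phi - b$mu[1] + 180) %% 360) - 180
    dpsi <- ((psi - b$mu[2] + 180) %% 360) - 180
    p <- p + b$w * exp(-0.5 * ((dphi / b$s[1])^2 + (dpsi / b$s[2])^2))
  }
  -scale * log(p)
}
basins <- list(
  generic = list(
    list(mu = c(-63, -43), s = c(16, 14), w = 0.40),
    list(mu = c(-118, 130), s = c(28, 22), w = 0.32),
    list(mu = c(-65, 145), s = c(16, 18), w = 0.20),
    list(mu = c(57, 42), s = c(13, 13), w = 0.07)),
  gly = list(
    list(mu = c(-63, -41), s = c(18, 16), w = 0.22),
    list(mu = c(63, 41), s = c(18, 16), w = 0.22),
    list(mu = c(80, 5), s = c(20, 20), w = 0.18),
    list(mu = c(-80, -5), s = c(20, 20), w = 0.18),
    list(mu = c(-100, 160), s = c(30, 25), w = 0.10),
    list(mu = c(100, -160), s = c(30, 25), w = 0.10)),
  pro = list(
    list(mu = c(-61, -35), s = c(11, 14), w = 0.50),
    list(mu = c(-63, 150), s = c(11, 16), w = 0.50)),
  prepro = list(
    list(mu = c(-63, -43), s = c(14, 12), w = 0.25),
    list(mu = c(-118, 132), s = c(26, 20), w = 0.40),
    list(mu = c(-65, 145), s = c(15, 16), w = 0.25),
    list(mu = c(55, 40), s = c(14, 14), w = 0.10)))
for (cls in names(basins)) {
  m <- outer(grid, grid, function(phi, psi) mix(phi, psi, basins[[cls]]))
  m <- m - min(m)
  tab <- data.frame(phi = rep(grid, times = length(grid)),
                    psi = rep(grid, each = length(grid)),
                    score = as.vector(m))
  write.table(format(tab, digits = 8, trim = TRUE),
              file.path(out, paste0("rama_", cls, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("tables written to", out, "\n")
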