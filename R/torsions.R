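# Torsion access and editing.  A torsion edit rotates exactly the atoms on
# the free-fragment (or cutpoint) side of the bond; scaffold backbone heavy
# atoms never move.  Move descriptors can be precomputed for hot loops
# (minimization, CCD) since the moving atom sets are purely topological.

# Atom tuple (A,B,C,D indices) defining a named torsion, plus an additive
# offset so that dihedral(A,B,C,D) + off equals the torsion value.
# Returns NULL when the torsion is undefined for this residue.
torsion_atoms <- function(conf, i, name) {
  at <- function(r, n) aidx(conf, r, n)
  if (name == "phi") {
    B <- at(i, "N"); C <- at(i, "CA"); D <- at(i, "C")
    # prefer a same-fragment reference: acetyl cap or virtual C across a
    # cutpoint, then the real preceding carbonyl carbon
    A <- at(i, "CP")
    if (!A) A <- at(i, "OVU1")
    if (!A && i > 1L) A <- at(i - 1L, "C")
    if (!(A && B && C && D)) return(NULL)
    return(list(A = A, B = B, C = C, D = D, off = 0))
  }
  if (name == "psi") {
    A <- at(i, "N"); B <- at(i, "CA"); C <- at(i, "C")
    off <- 0
    # prefer a same-fragment reference: methylamide cap or virtual N
    # across a cutpoint, then the real next amide nitrogen
    D <- at(i, "NM")
    if (!D) D <- at(i, "OVL1")
    if (!D && i < conf$nres) D <- at(i + 1L, "N")
    if (!D) { D <- at(i, "O"); off <- 180 }
    if (!(A && B && C && D)) return(NULL)
    return(list(A = A, B = B, C = C, D = D, off = off))
  }
  if (name == "omega") {
    D <- at(i, "CA"); C <- at(i, "N")
    B <- if (i > 1L) at(i - 1L, "C") else 0L
    A <- if (i > 1L) at(i - 1L, "CA") else 0L
    if (!B) { B <- at(i, "CP"); A <- at(i, "CMP") }
    if (!(A && B && C && D)) return(NULL)
    return(list(A = A, B = B, C = C, D = D, off = 0))
  }
  if (grepl("^chi[1-4]$", name)) {
    k <- as.integer(sub("chi", "", name))
    tup <- chi_atoms(conf$seq[i])
    if (k > length(tup)) return(NULL)
    id <- vapply(tup[[k]], function(a) aidx(conf, i, a), integer(1))
    if (any(id == 0L)) return(NULL)
    return(list(A = id[1], B = id[2], C = id[3], D = id[4], off = 0))
  }
  stop("unknown torsion name: ", name)
}

# adjacency list of the build tree (parent pointers only; the cutpoint and
# ring closures are deliberately absent so rotations propagate correctly)
.tree_adjacency <- function(conf) {
  n <- nrow(conf$xyz)
  adj <- vector("list", n)
  for (k in seq_len(n)) {
    p <- conf$atoms$parent[k]
    if (p > 0L) { adj[[k]] <- c(adj[[k]], p); adj[[p]] <- c(adj[[p]], k) }
  }
  adj
}

.component_from <- function(adj, start, forbid_edge) {
  seen <- logical(length(adj))
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      for (nb in adj[[f]]) {
        if ((f == forbid_edge[1] && nb == forbid_edge[2]) ||
            (f == forbid_edge[2] && nb == forbid_edge[1])) next
        if (!seen[nb]) { seen[nb] <- TRUE; nxt <- c(nxt, nb) }
      }
    }
    frontier <- nxt
  }
  which(seen)
}

# Moving-set descriptor for one torsion: axis atom indices, the atom indices
# that rotate, and the rotation sense (+1 when the D side moves).
torsion_move_info <- function(conf, i, name, adj = NULL) {
  t <- torsion_atoms(conf, i, name)
  if (is.null(t)) stop("torsion ", name, " undefined for residue ", i)
  if (is.null(adj)) adj <- .tree_adjacency(conf)
  fixed_heavy <- which(conf$built[conf$atoms$res] == "scaffold" &
                       conf$atoms$name %in% c("N", "CA", "C", "O"))
  comp <- .component_from(adj, t$C, c(t$B, t$C))
  moving <- setdiff(comp, c(t$B, t$C))
  sense <- 1
  if (any(moving %in% fixed_heavy) || !(t$D %in% comp)) {
    comp <- .component_from(adj, t$B, c(t$B, t$C))
    moving <- setdiff(comp, c(t$B, t$C))
    sense <- -1
    if (any(moving %in% fixed_heavy))
      stop("attempt to move a fixed scaffold torsion (", name,
           " of residue ", i, ")")
    if (!(t$A %in% comp))
      stop("torsion ", name, " of residue ", i, " has no movable side")
  }
  list(res = i, name = name, A = t$A, B = t$B, C = t$C, D = t$D,
       off = t$off, moving = moving, sense = sense)
}

# current value of the torsion described by a move descriptor
.move_value <- function(xyz, mv) {
  wrap_angle(dihedral(xyz[mv$A, ], xyz[mv$B, ], xyz[mv$C, ], xyz[mv$D, ]) + mv$off)
}

# rotate the moving block so the torsion takes `value`; returns new xyz
.apply_move <- function(xyz, mv, value) {
  cur <- .move_value(xyz, mv)
  delta <- wrap_angle(value - cur)
  if (abs(delta) < 1e-12) return(xyz)
  u <- .vhat(xyz[mv$C, ] - xyz[mv$B, ])
  rotate_about_axis(xyz, mv$moving, xyz[mv$C, ], u, -mv$sense * delta)
}

#' Set a named backbone or side-chain torsion
#'
#' Rotates only the atoms downstream of the bond (toward the free fragment
#' end, or toward the cutpoint when one is set); scaffold backbone atoms are
#' never moved and attempting to do so is an error.
#'
#' @param conf a \code{Conformation}.
#' @param residue residue index.
#' @param name one of \code{"phi"}, \code{"psi"}, \code{"omega"},
#'   \code{"chi1"} .. \code{"chi4"}.
#' @param value target angle in degrees.
#' @return the updated \code{Conformation}.
#' @export
set_torsion <- function(conf, residue, name, value) {
  mv <- torsion_move_info(conf, residue, name)
  conf$xyz <- .apply_move(conf$xyz, mv, value)
  value <- wrap_angle(value)
  if (name %in% c("phi", "psi", "omega")) {
    conf$bb_tor[residue, name] <- value
  } else {
    k <- as.integer(sub("chi", "", name))
    conf$chi[[residue]][k] <- value
  }
  conf
}

#' Read a named torsion (degrees)
#' @inheritParams set_torsion
#' @export
get_torsion <- function(conf, residue, name) {
  t <- torsion_atoms(conf, residue, name)
  if (is.null(t)) return(NA_real_)
  wrap_angle(dihedral(conf$xyz[t$A, ], conf$xyz[t$B, ],
                      conf$xyz[t$C, ], conf$xyz[t$D, ]) + t$off)
}

# Precompute descriptors for a move set given as a data.frame/list of
# (res, name); used by minimize and CCD.
build_move_set <- function(conf, moves) {
  adj <- .tree_adjacency(conf)
  lapply(seq_len(nrow(moves)), function(r)
    torsion_move_info(conf, moves$res[r], moves$name[r], adj))
}

# Apply target values (degrees) for a precomputed move set to a coordinate
# matrix.  Descriptors are applied in order; axis positions are taken from
# the current coordinates so nested rotations compose correctly.
apply_move_set <- function(xyz, mvs, values) {
  if (!length(mvs)) return(xyz)
  .cpp_apply_moves(xyz,
                   vapply(mvs, function(m) as.integer(m$A), integer(1)),
                   vapply(mvs, function(m) as.integer(m$B), integer(1)),
                   vapply(mvs, function(m) as.integer(m$C), integer(1)),
                   vapply(mvs, function(m) as.integer(m$D), integer(1)),
                   vapply(mvs, function(m) as.numeric(m$off), numeric(1)),
                   vapply(mvs, function(m) as.integer(m$sense), integer(1)),
                   lapply(mvs, function(m) as.integer(m$moving)),
                   as.numeric(values))
}

move_set_values <- function(xyz, mvs)
  vapply(mvs, function(mv) .move_value(xyz, mv), numeric(1))
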