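# Surrogate all-atom energy.  One energy unit is treated as one kBT
# throughout (retention windows, convergence gap).  Two weight dialects
# mirror the pack vs score weighting used during sampling and minimization:
# sampling softens repulsion (fa_rep 0.10 vs 0.44) and strengthens
# side-chain hydrogen bonds (hbond_sc 3.1 vs 1.1).  Hydrogen-bond strength
# is never attenuated by burial in either dialect.

.ENERGY_TERMS <- c("fa_atr", "fa_rep", "hbond_bb", "hbond_sc",
                   "rama", "rotamer", "linear_chainbreak",
                   "coordinate_constraint")

#' Energy term weights
#'
#' Named presets: \code{"sampling"} (fa_rep = 0.10, hbond_sc = 3.1) used
#' during grid sampling and rotamer optimization, and \code{"minimization"}
#' (fa_rep = 0.44, hbond_sc = 1.1) used during continuous minimization and
#' final ranking.  \code{linear_chainbreak} and
#' \code{coordinate_constraint} default to 0 and are switched on by the
#' closure and native-constrained protocols.
#'
#' @param preset \code{"sampling"} or \code{"minimization"}.
#' @param ... named weight overrides (must be non-negative).
#' @return named numeric vector of class \code{EnergyWeights}.
#' @export
energy_weights <- function(preset = c("minimization", "sampling"), ...) {
  preset <- match.arg(preset)
  w <- c(fa_atr = 0.8, fa_rep = 0.44, hbond_bb = 1.17, hbond_sc = 1.1,
         rama = 0.2, rotamer = 0.4, linear_chainbreak = 0,
         coordinate_constraint = 0)
  if (preset == "sampling") {
    w["fa_rep"] <- 0.10
    w["hbond_sc"] <- 3.1
  }
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% .ENERGY_TERMS) stop("unknown energy term: ", nm)
    w[nm] <- ov[[nm]]
  }
  if (any(w < 0)) stop("energy weights must be non-negative")
  structure(w[.ENERGY_TERMS], class = "EnergyWeights")
}

# ---- Ramachandran term ----------------------------------------------------

.rama_matrix <- function(class) {
  key <- paste0("rama_", class)
  if (is.null(.swa_cache[[key]])) {
    tab <- .swa_table(paste0("rama_", class, ".tsv"))
    g <- sort(unique(tab$phi))
    m <- matrix(NA_real_, length(g), length(g))
    m[cbind(match(tab$phi, g), match(tab$psi, g))] <- tab$score
    .swa_cache[[key]] <- list(grid = g, m = m)
  }
  .swa_cache[[key]]
}

# residue class for the rama table: generic / gly / pro / prepro
rama_class <- function(res3, next3 = NA) {
  if (res3 == "GLY") "gly"
  else if (res3 == "PRO") "pro"
  else if (!is.na(next3) && next3 == "PRO") "prepro"
  else "generic"
}

#' Ramachandran backbone-torsion score
#'
#' Bilinear interpolation (with periodic wrap) of the shipped 20-degree
#' log-odds table for the residue class.  The build-up filter discards
#' samples scoring above 0.8 units.
#'
#' @param residue_type three-letter code, or one of \code{"generic"},
#'   \code{"gly"}, \code{"pro"}, \code{"prepro"}.
#' @param phi,psi backbone torsions in degrees.
#' @param next_type three-letter code of the following residue (to detect
#'   pre-proline); ignored when \code{residue_type} is already a class.
#' @return score in energy units (table minimum is 0).
#' @export
rama_score <- function(residue_type, phi, psi, next_type = NA) {
  cls <- if (residue_type %in% c("generic", "gly", "pro", "prepro"))
    residue_type else rama_class(residue_type, next_type)
  tab <- .rama_matrix(cls)
  g <- tab$grid; step <- g[2] - g[1]; ng <- length(g)
  fx <- (wrap_angle(phi) - g[1]) / step
  fy <- (wrap_angle(psi) - g[1]) / step
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  i1 <- (ix %% ng) + 1; i2 <- (ix + 1) %% ng + 1
  j1 <- (iy %% ng) + 1; j2 <- (iy + 1) %% ng + 1
  (1 - tx) * (1 - ty) * tab$m[i1, j1] + tx * (1 - ty) * tab$m[i2, j1] +
    (1 - tx) * ty * tab$m[i1, j2] + tx * ty * tab$m[i2, j2]
}

# ---- rotamer preference term ---------------------------------------------

# deviation of a chi vector from the nearest canonical rotamer:
# min over library rows of sum_k (1 - cos(chi_k - rot_k))
rotamer_dev <- function(res3, chi) {
  if (!length(chi)) return(0)
  key <- paste0("rotmat_", res3)
  m <- .swa_cache[[key]]
  if (is.null(m)) {
    m <- as.matrix(rotamer_library(res3)[, 1:4])
    .swa_cache[[key]] <- m
  }
  if (!nrow(m)) return(0)
  k <- seq_along(chi)
  dev <- 1 - cos(sweep(m[, k, drop = FALSE], 2, chi) * .d2r)
  min(rowSums(dev, na.rm = TRUE))
}

# ---- hydrogen bond (standalone form, mirrors the compiled kernel) --------

#' Hydrogen-bond energy for one donor/acceptor geometry
#'
#' Smooth well on the donor/acceptor heavy-atom distance, exactly zero at
#' and beyond 3.2 Angstroms, modulated by the squared cosine of the
#' D-H...A deviation from linearity.  Unweighted (multiply by
#' \code{hbond_bb} or \code{hbond_sc}).
#'
#' @param donor 3-vector, donor heavy atom (N or O).
#' @param hydrogen 3-vector, the attached polar hydrogen (NULL: returns 0).
#' @param acceptor 3-vector, acceptor heavy atom.
#' @param dmax hard zero distance (default 3.2 A).
#' @param dflat distance below which the radial well is flat (default 2.9 A).
#' @return energy in [-1, 0].
#' @export
hbond_term <- function(donor, hydrogen, acceptor, dmax = 3.2, dflat = 2.9) {
  if (is.null(hydrogen)) return(0)
  d <- .vnorm(donor - acceptor)
  if (d >= dmax) return(0)
  f <- if (d <= dflat) -1 else {
    t <- (dmax - d) / (dmax - dflat)
    -(t * t * (3 - 2 * t))
  }
  u <- donor - hydrogen; v <- acceptor - hydrogen
  cosdev <- -sum(u * v) / (.vnorm(u) * .vnorm(v))
  if (cosdev <= 0) return(0)
  f * cosdev^2
}

# ---- chainbreak and coordinate constraint --------------------------------

#' Linear chainbreak pseudo-energy
#'
#' Sum over the three virtual/real atom pairs at the cutpoint of their
#' Euclidean deviations (Angstroms); zero iff closure is exact.  Apply with
#' weight 150.0 during chain closure.
#'
#' @param conf a \code{Conformation} with a cutpoint.
#' @return the (unweighted) deviation sum.
#' @export
linear_chainbreak <- function(conf) {
  p <- chainbreak_pairs(conf)
  sum(sqrt(rowSums((conf$xyz[p[, 1], , drop = FALSE] -
                    conf$xyz[p[, 2], , drop = FALSE])^2)))
}

# RMS closure deviation over the three virtual/real pairs (the 1.5 A screen
# and reported closure metric)
closure_deviation <- function(conf) {
  p <- chainbreak_pairs(conf)
  sqrt(mean(rowSums((conf$xyz[p[, 1], , drop = FALSE] -
                     conf$xyz[p[, 2], , drop = FALSE])^2)))
}

#' Fade-spline coordinate constraint on loop C-alpha positions
#'
#' Per-residue penalty p(d) on the deviation d of each constrained C-alpha
#' from its reference: 0 up to \code{r_lo}, rising as the unique cubic with
#' zero slope at both knots to \code{max_penalty} at \code{r_hi}.
#'
#' @param conf a \code{Conformation}.
#' @param reference matrix of reference C-alpha coordinates (one row per
#'   constrained residue) with rownames giving residue indices, or a
#'   \code{Conformation} to take them from.
#' @param residues residue indices to constrain (default: the loop).
#' @param r_lo,r_hi fade knots in Angstroms.
#' @param max_penalty plateau penalty (energy units).
#' @return summed (unweighted) penalty.
#' @export
ca_fade_constraint <- function(conf, reference, residues = NULL,
                               r_lo = 2.0, r_hi = 4.0, max_penalty = 10.0) {
  if (r_lo >= r_hi) stop("r_lo must be < r_hi")
  if (inherits(reference, "Conformation")) {
    if (is.null(residues)) residues <- seq(conf$loop[1], conf$loop[2])
    reference <- do.call(rbind, lapply(residues, function(r)
      axyz(reference, r, "CA")))
    rownames(reference) <- residues
  }
  if (is.null(residues)) residues <- as.integer(rownames(reference))
  tot <- 0
  for (k in seq_along(residues)) {
    ca <- aidx(conf, residues[k], "CA")
    if (!ca) next
    d <- .vnorm(conf$xyz[ca, ] - reference[k, ])
    tot <- tot + if (d <= r_lo) 0 else if (d >= r_hi) max_penalty else {
      t <- (d - r_lo) / (r_hi - r_lo)
      max_penalty * (3 * t^2 - 2 * t^3)
    }
  }
  tot
}

# ---- full score -----------------------------------------------------------

# cached fixed-fixed pairwise terms for incremental scoring: terms over
# pairs where both atoms are outside `movable`
energy_cache <- function(conf, movable) {
  mov <- logical(nrow(conf$xyz)); mov[movable] <- TRUE
  excl <- if (!is.null(conf$excl)) conf$excl else conf_exclusions(conf)
  .cpp_pair_terms(conf$xyz, conf$atoms$radius, conf$atoms$hclass,
                  conf$atoms$hparent - 1L, conf$atoms$bb,
                  !conf$atoms$virtual & !mov, mov, FALSE,
                  excl[, 1] - 1L, excl[, 2] - 1L,
                  6.0, 0.15, 3.2, 2.9)
}

#' Score a conformation
#'
#' Computes the surrogate energy breakdown: pairwise packing and
#' hydrogen-bond terms (6 A cutoff), Ramachandran and rotamer preference
#' terms from the stored torsions, the linear chainbreak deviation when a
#' cutpoint is set, and an optional C-alpha fade constraint.  With
#' \code{movable}, pair terms are restricted to pairs involving at least
#' one movable atom and \code{cache} supplies the frozen remainder.
#'
#' @param conf a \code{Conformation}.
#' @param weights an \code{\link{energy_weights}} vector.
#' @param movable optional integer vector of movable atom indices.
#' @param cache fixed-fixed pair terms from \code{energy_cache} (required
#'   with \code{movable}).
#' @param constraint optional list with \code{reference} (and optionally
#'   \code{residues}, \code{r_lo}, \code{r_hi}, \code{max_penalty}) for the
#'   coordinate constraint.
#' @return an \code{EnergyBreakdown}: list with \code{terms} (unweighted),
#'   \code{weights} and \code{total}.
#' @export
score <- function(conf, weights = energy_weights(), movable = NULL,
                  cache = NULL, constraint = NULL) {
  if (anyNA(conf$xyz)) stop("NaN/NA coordinates")
  excl <- if (!is.null(conf$excl)) conf$excl else conf_exclusions(conf)
  n <- nrow(conf$xyz)
  if (is.null(movable)) {
    pt <- .cpp_pair_terms(conf$xyz, conf$atoms$radius, conf$atoms$hclass,
                          conf$atoms$hparent - 1L, conf$atoms$bb,
                          !conf$atoms$virtual, logical(n), FALSE,
                          excl[, 1] - 1L, excl[, 2] - 1L, 6.0, 0.15, 3.2, 2.9)
  } else {
    if (is.null(cache)) cache <- energy_cache(conf, movable)
    mov <- logical(n); mov[movable] <- TRUE
    pt <- .cpp_pair_terms(conf$xyz, conf$atoms$radius, conf$atoms$hclass,
                          conf$atoms$hparent - 1L, conf$atoms$bb,
                          !conf$atoms$virtual, mov, TRUE,
                          excl[, 1] - 1L, excl[, 2] - 1L, 6.0, 0.15, 3.2, 2.9)
    pt <- pt + cache
  }
  rama <- 0; rot <- 0
  for (i in seq_len(conf$nres)) {
    if (conf$built[i] == "unbuilt") next
    ph <- conf$bb_tor[i, "phi"]; ps <- conf$bb_tor[i, "psi"]
    if (!is.na(ph) && !is.na(ps))
      rama <- rama + unname(rama_score(conf$seq[i], unname(ph), unname(ps),
                                if (i < conf$nres) conf$seq[i + 1] else NA))
    if (length(conf$chi[[i]]) && !anyNA(conf$chi[[i]]))
      rot <- rot + rotamer_dev(conf$seq[i], conf$chi[[i]])
  }
  cb <- if (!is.na(conf$cutpoint)) linear_chainbreak(conf) else 0
  cst <- if (!is.null(constraint))
    do.call(ca_fade_constraint, c(list(conf = conf), constraint)) else 0
  terms <- c(fa_atr = unname(pt["fa_atr"]), fa_rep = unname(pt["fa_rep"]),
             hbond_bb = unname(pt["hbond_bb"]),
             hbond_sc = unname(pt["hbond_sc"]),
             rama = rama, rotamer = rot, linear_chainbreak = cb,
             coordinate_constraint = cst)
  structure(list(terms = terms, weights = weights,
                 total = sum(unclass(weights) * terms)),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("EnergyBreakdown (total", format(x$total, digits = 6), "units)\n")
  tab <- data.frame(term = names(x$terms), raw = x$terms,
                    weight = as.numeric(x$weights),
                    weighted = x$terms * as.numeric(x$weights))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

# convenience: weighted total only
score_total <- function(conf, weights, ...) score(conf, weights, ...)$total
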