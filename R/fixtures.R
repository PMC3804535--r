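# Synthetic test scaffolds with planted-optimum loops.  The "native" loop
# of a recovery problem is a polished local optimum of this package's own
# energy function, so recovery is a pure test of the sampling algorithm:
# failures where sampling finds a lower-energy non-native loop diagnose the
# energy surface, failures to reach the native diagnose sampling.

# remove the virtual closure atoms and restore the chain bond
remove_cutpoint <- function(conf) {
  c <- conf$cutpoint
  if (is.na(c)) return(conf)
  for (nm in c("OVL2", "OVL1")) {
    id <- aidx(conf, c, nm)
    if (id) conf <- remove_atoms(conf, id)
  }
  id <- aidx(conf, c + 1L, "OVU1")
  if (id) conf <- remove_atoms(conf, id)
  ni <- aidx(conf, c + 1L, "N")
  ci <- aidx(conf, c, "C")
  if (ni && ci && conf$atoms$parent[ni] == 0L) conf$atoms$parent[ni] <- ci
  conf$cutpoint <- NA_integer_
  conf$excl <- NULL
  conf
}

# minimum nonbonded heavy-atom distance (clash diagnostic)
.min_nonbonded_dist <- function(conf) {
  heavy <- which(conf$atoms$elem != "H" & !conf$atoms$virtual)
  excl <- conf_exclusions(conf)
  ek <- paste(excl[, 1], excl[, 2])
  x <- conf$xyz[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  for (r in seq_len(nrow(excl))) {
    a <- match(excl[r, 1], heavy); b <- match(excl[r, 2], heavy)
    if (!is.na(a) && !is.na(b)) { d[a, b] <- Inf; d[b, a] <- Inf }
  }
  min(d)
}

# whole-chain torsional relaxation of a freshly built template: everything
# beyond residue 1 is treated as movable, clashes are relieved and backbone
# hydrogen bonds form under the minimization weights
.relax_chain <- function(conf, max_iter = 80) {
  built0 <- conf$built
  conf$built[] <- "nfrag"
  conf$built[1] <- "scaffold"
  mv <- NULL
  for (r in 2:conf$nres)
    mv <- rbind(mv, data.frame(res = r, name = c("phi", "psi")))
  for (r in seq_len(conf$nres)) if (length(conf$chi[[r]]))
    mv <- rbind(mv, data.frame(res = r,
                               name = paste0("chi", seq_along(conf$chi[[r]]))))
  conf <- torsion_minimize(conf, mv, energy_weights("minimization"),
                           max_iter = max_iter)
  conf$built <- built0
  conf
}

# torsion/sequence templates for the two scaffold topologies
.scaffold_plan <- function(n_residues, topology) {
  if (topology == "hairpin") {
    ns <- floor((n_residues - 2) / 2)
    nturn <- n_residues - 2 * ns
    seqs <- c(rep(c("ALA", "THR", "ALA", "VAL"), length.out = ns),
              rep("GLY", nturn),
              rep(c("ALA", "VAL", "ALA", "THR"), length.out = ns))
    # antiparallel strands joined by a two-glycine turn; torsions chosen so
    # the ideal-geometry build places the cross-strand H-bond ladder at
    # ~2.95 A (see data-raw notes on the template calibration)
    phi <- c(rep(-148.5, ns), c(37.2, 52.4, 60)[seq_len(nturn)],
             rep(-136.8, ns))
    psi <- c(rep(153.4, ns), c(85.3, 37.0, 30)[seq_len(nturn)],
             rep(141.1, ns))
  } else {  # helix_turn
    nh <- floor((n_residues - 4) * 0.55)
    nturn <- 4
    ns <- n_residues - nh - nturn
    seqs <- c(rep(c("ALA", "ALA", "SER", "LEU"), length.out = nh),
              c("GLY", "ASP", "GLY", "GLY")[seq_len(nturn)],
              rep(c("ALA", "THR", "ALA", "VAL"), length.out = ns))
    phi <- c(rep(-63, nh), c(60, -90, 90, -80)[seq_len(nturn)],
             rep(-125, ns))
    psi <- c(rep(-43, nh), c(30, 0, 0, 130)[seq_len(nturn)],
             rep(135, ns))
  }
  list(seq = seqs, phi = phi, psi = psi)
}

#' Generate a synthetic scaffold structure
#'
#' Builds a closed, clash-free all-atom chain from canonical secondary
#' structure torsions plus seeded jitter; deterministic per seed.  On a
#' clash the construction retries with a derived seed (error after the
#' retry budget).
#'
#' @param n_residues chain length (15 to 60).
#' @param topology \code{"hairpin"} (two strands joined by a glycine turn)
#'   or \code{"helix_turn"} (helix, turn, strand).
#' @param seed integer seed.
#' @param jitter torsion jitter amplitude in degrees (default 8).
#' @param retries clash-retry budget (default 20).
#' @return a \code{Conformation} (all residues scaffold).
#' @export
make_scaffold <- function(n_residues, topology = c("hairpin", "helix_turn"),
                          seed = 1, jitter = 5, retries = 20) {
  topology <- match.arg(topology)
  if (n_residues < 15 || n_residues > 60)
    stop("n_residues must be within 15..60")
  plan <- .scaffold_plan(n_residues, topology)
  for (try in seq_len(retries)) {
    s <- stage_seed(seed, try, 0L)
    jit <- with_seed(s, matrix(runif(2 * n_residues, -jitter, jitter),
                               ncol = 2))
    tor <- list(phi = plan$phi + jit[, 1], psi = plan$psi + jit[, 2],
                omega = rep(180, n_residues))
    tor$phi[1] <- NA
    conf <- build_from_torsions(plan$seq, tor)
    chires <- which(n_chi(conf$seq) > 0L)
    if (length(chires))
      conf <- rotamer_trials(conf, chires, energy_weights("sampling"),
                             rng_seed = s, sweeps = 2)
    conf <- .relax_chain(conf)
    if (.min_nonbonded_dist(conf) > 2.2 &&
        is.finite(score(conf, energy_weights("minimization"))$total))
      return(conf)
  }
  stop("clash-free construction failed after ", retries, " retries; reseed")
}

#' Build a planted-optimum loop recovery problem
#'
#' Polishes the loop region of a scaffold into a strong local optimum of
#' the minimization-dialect energy (side-chain trials + full-loop
#' torsional minimization around a mid-loop cutpoint with the chainbreak
#' penalty active), records the result as the native answer, then strips
#' the loop atoms and all side chains to form the benchmark-style problem
#' input.
#'
#' @param scaffold a \code{Conformation} from \code{\link{make_scaffold}}.
#' @param loop_range integer c(k, l), interior to the chain.
#' @param polish_iters optimization rounds (default 3).
#' @param seed integer seed.
#' @return list with \code{problem} (stripped scaffold, loop unbuilt),
#'   \code{native} (polished full model), \code{loop}.
#' @export
make_recovery_problem <- function(scaffold, loop_range, polish_iters = 3,
                                  seed = 1) {
  k <- loop_range[1]; l <- loop_range[2]
  if (k <= 1L || l >= scaffold$nres) stop("loop at chain terminus")
  conf <- scaffold
  conf$loop <- c(k, l)
  cut <- k + (l - k) %/% 2
  conf$built[k:cut] <- "nfrag"
  conf$built[(cut + 1L):l] <- "cfrag"
  conf <- add_cutpoint(conf, cut)
  cfg <- swa_config("coarse")
  wm <- energy_weights("minimization", linear_chainbreak = 150)
  ws <- energy_weights("sampling", linear_chainbreak = 150)
  nb <- neighbor_list(conf, k:l, cfg$neighbor_cutoff)
  mv <- .loop_bb_moves(conf, k:l)
  for (r in nb) if (length(conf$chi[[r]]))
    mv <- rbind(mv, data.frame(res = r,
                               name = paste0("chi", seq_along(conf$chi[[r]]))))
  for (it in seq_len(polish_iters)) {
    conf <- rotamer_trials(conf, nb, ws, rng_seed = stage_seed(seed, it, 1L),
                           sweeps = 2)
    conf <- torsion_minimize(conf, mv, wm, max_iter = 150)
  }
  native <- remove_cutpoint(conf)
  native$built[] <- "scaffold"
  # strip: loop atoms entirely, side chains everywhere, keep backbone + H
  prob <- new_conformation(native$seq, loop = c(k, l))
  prob$offset <- native$offset
  for (r in seq_len(native$nres)) {
    if (r >= k && r <= l) next
    for (nm in c("N", "CA", "C", "O", "H")) {
      id <- aidx(native, r, nm)
      if (!id) next
      par <- native$atoms$parent[id]
      pidx <- if (par > 0L && !(native$atoms$res[par] %in% k:l) &&
                  !(native$atoms$res[par] == r - 1L && r == l + 1L && FALSE))
        aidx(prob, native$atoms$res[par], native$atoms$name[par]) else 0L
      prob <- add_atom(prob, r, nm, native$atoms$elem[id], native$xyz[id, ],
                       parent = pidx, bb = TRUE)
    }
    prob$built[r] <- "scaffold"
    prob$chi[r] <- list(numeric(0))
  }
  mt <- measure_torsions(prob)
  prob$bb_tor <- mt$bb
  list(problem = prob, native = native, loop = c(k, l))
}
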