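# Metrics and reference protocols: RMSD in the fixed scaffold frame, loop
# environment descriptors, native-loop optimization baselines, and
# energy-vs-RMSD reporting.

#' C-alpha RMSD over the loop, in the fixed scaffold frame
#'
#' No superposition is applied: the scaffold is rigidly fixed, so model
#' and reference frames coincide.
#'
#' @param model,reference \code{Conformation}s with aligned residue
#'   numbering.
#' @param loop_range integer c(k, l); defaults to the model's loop.
#' @return RMSD in Angstroms.
#' @export
ca_rmsd <- function(model, reference, loop_range = model$loop) {
  res <- seq(loop_range[1], loop_range[2])
  dx <- vapply(res, function(r) {
    a <- aidx(model, r, "CA"); b <- aidx(reference, r, "CA")
    if (!a || !b) stop("missing CA at residue ", r)
    sum((model$xyz[a, ] - reference$xyz[b, ])^2)
  }, numeric(1))
  sqrt(mean(dx))
}

# backbone (N, CA, C, O) RMSD over given residues, fixed frame
bb_rmsd <- function(model, reference, residues) {
  x <- .cluster_coords(model, residues)
  y <- .cluster_coords(reference, residues)
  sqrt(mean((x - y)^2) * 3)
}

#' Loop environment descriptors
#'
#' Per-loop-residue averages over non-hydrogen atoms, excluding residues
#' within two sequence positions of each loop residue (strict thresholds):
#' \code{N_contact} (residues with any atom-atom contact < 4.0 A),
#' \code{N_out} (contacting residues outside the loop), \code{N_SC}
#' (contacting residues where the contact involves an atom beyond the
#' N/C/CA/CB/O set), and \code{N_HB} (donor/acceptor pairs < 3.2 A).
#'
#' @param conf a full-atom \code{Conformation}.
#' @param loop_range integer c(k, l); defaults to the conformation's loop.
#' @return named numeric vector.
#' @export
loop_descriptors <- function(conf, loop_range = conf$loop) {
  loopres <- seq(loop_range[1], loop_range[2])
  at <- conf$atoms
  heavy <- !at$virtual & at$elem != "H"
  sc_atom <- heavy & !(at$name %in% c("N", "C", "CA", "CB", "O"))
  # distance-only donor/acceptor sets: acceptors are O (and His ND1);
  # donors are nitrogens carrying hydrogens and hydroxyl oxygens
  acc <- heavy & at$hclass == 2L
  don <- heavy & ((at$elem == "N" & at$name %in%
                   c("N", "ND2", "NE2", "NZ", "NE", "NH1", "NH2", "NE1")) |
                  at$name %in% c("OG", "OG1", "OH"))
  ncont <- nout <- nsc <- nhb <- numeric(length(loopres))
  for (q in seq_along(loopres)) {
    r <- loopres[q]
    mine <- which(at$res == r & heavy)
    others <- setdiff(unique(at$res[heavy]), (r - 2L):(r + 2L))
    for (o in others) {
      oat <- which(at$res == o & heavy)
      if (!length(oat) || !length(mine)) next
      d <- sqrt(outer(rowSums(conf$xyz[mine, , drop = FALSE]^2), rep(1, length(oat))) +
                outer(rep(1, length(mine)), rowSums(conf$xyz[oat, , drop = FALSE]^2)) -
                2 * conf$xyz[mine, , drop = FALSE] %*% t(conf$xyz[oat, , drop = FALSE]))
      contact <- d < 4.0
      if (any(contact)) {
        ncont[q] <- ncont[q] + 1
        if (o < loop_range[1] || o > loop_range[2]) nout[q] <- nout[q] + 1
        scpair <- contact & (outer(sc_atom[mine], rep(TRUE, length(oat))) |
                             outer(rep(TRUE, length(mine)), sc_atom[oat]))
        if (any(scpair)) nsc[q] <- nsc[q] + 1
      }
      hb <- d < 3.2 & (outer(don[mine], acc[oat], "&") |
                       outer(acc[mine], don[oat], "&"))
      nhb[q] <- nhb[q] + sum(hb)
    }
  }
  c(N_contact = mean(ncont), N_out = mean(nout), N_SC = mean(nsc),
    N_HB = mean(nhb))
}

#' Optimize the crystallographic (native) loop
#'
#' Two baseline strategies for estimating the energy of the native loop
#' under the package energy function: \code{"idealize_optimize"} rebuilds
#' the loop with ideal internal coordinates from the measured native
#' torsions, then repacks and fully minimizes around each possible
#' chainbreak placement over several seeds; \code{"native_constrained_swa"}
#' runs the full pipeline with a 2.0 A backbone-RMSD screen at every
#' retention step and the C-alpha fade constraint active.
#'
#' @param conf_native a full \code{Conformation} containing the loop.
#' @param strategy \code{"idealize_optimize"} or
#'   \code{"native_constrained_swa"}.
#' @param config an \code{\link{swa_config}}.
#' @param rng_seed integer seed.
#' @param n_seeds optimization restarts per chainbreak placement
#'   (idealize strategy; default 20).
#' @return a StageEnsemble (list with \code{models}, \code{energies},
#'   energy-sorted).
#' @export
optimize_native <- function(conf_native,
                            strategy = c("idealize_optimize",
                                         "native_constrained_swa"),
                            config = swa_config(), rng_seed = 1,
                            n_seeds = 20) {
  strategy <- match.arg(strategy)
  k <- conf_native$loop[1]; l <- conf_native$loop[2]
  if (is.null(k)) stop("native conformation carries no loop definition")
  for (r in k:l) if (!aidx(conf_native, r, "CA"))
    stop("reference missing loop atoms at residue ", r)
  if (strategy == "native_constrained_swa") {
    cfg <- config
    cfg$rmsd_screen <- 2.0
    cfg$native <- conf_native
    cfg$constrain_native <- TRUE
    prob <- make_problem_from_native(conf_native)
    res <- swa_run(prob, c(k, l), cfg, rng_seed)
    return(res$final_pool)
  }
  # idealize-and-optimize: rebuild the loop from measured torsions with
  # ideal geometry, then repack + full-loop minimize per cutpoint x seed
  mt <- measure_torsions(conf_native)
  models <- list(); energies <- numeric(0)
  wm <- energy_weights("minimization",
                       linear_chainbreak = config$chainbreak_weight)
  ws <- energy_weights("sampling",
                       linear_chainbreak = config$chainbreak_weight)
  for (cut in k:(l - 1L)) {
    base <- conf_native
    base$loop <- c(k, l)
    base <- remove_loop_atoms(base, k:l)
    for (r in k:cut)
      base <- append_residue(base, r, mt$bb[r, "phi"], mt$bb[r, "psi"],
                             mt$bb[r, "omega"], chi = mt$chi[[r]])
    for (r in rev((cut + 1L):l))
      base <- prepend_residue(base, r, mt$bb[r, "phi"], mt$bb[r, "psi"],
                              mt$bb[r, "omega"], chi = mt$chi[[r]])
    ideal <- add_cutpoint(base, cut)
    nb <- neighbor_list(ideal, k:l, config$neighbor_cutoff)
    mv <- .loop_bb_moves(ideal, k:l)
    for (r in nb) if (length(ideal$chi[[r]]))
      mv <- rbind(mv, data.frame(res = r,
                                 name = paste0("chi",
                                               seq_along(ideal$chi[[r]]))))
    for (s in seq_len(n_seeds)) {
      m <- rotamer_trials(ideal, nb, ws,
                          rng_seed = stage_seed(rng_seed, cut, s),
                          sweeps = config$rt_sweeps)
      m <- torsion_minimize(m, mv, wm, max_iter = config$min_iter)
      models[[length(models) + 1L]] <- .slim(m)
      energies <- c(energies, score(m, wm)$total)
    }
  }
  ord <- order(energies)
  list(stage = c(k, l), models = models[ord], energies = energies[ord])
}

# remove all atoms of the given loop residues (leaf-first), marking them
# unbuilt; the bond into the following residue is unlinked first
remove_loop_atoms <- function(conf, rs) {
  ni <- if (max(rs) < conf$nres) aidx(conf, max(rs) + 1L, "N") else 0L
  if (ni && conf$atoms$parent[ni] > 0L &&
      conf$atoms$res[conf$atoms$parent[ni]] %in% rs)
    conf$atoms$parent[ni] <- 0L
  repeat {
    sel <- which(conf$atoms$res %in% rs & !conf$atoms$virtual)
    if (!length(sel)) break
    drop <- sel[!(sel %in% conf$atoms$parent)]
    if (!length(drop)) stop("cannot excise loop atoms: dangling children")
    conf <- remove_atoms(conf, sort(drop, decreasing = TRUE))
  }
  conf$built[rs] <- "unbuilt"
  conf$bb_tor[rs, ] <- NA_real_
  conf$chi[rs] <- list(NULL)
  conf$caps <- list(n = NA_integer_, c = NA_integer_)
  conf
}

# strip a native model to a benchmark-style problem (loop + side chains out)
make_problem_from_native <- function(native) {
  k <- native$loop[1]; l <- native$loop[2]
  prob <- new_conformation(native$seq, loop = c(k, l))
  prob$offset <- native$offset
  for (r in seq_len(native$nres)) {
    if (r >= k && r <= l) next
    for (nm in c("N", "CA", "C", "O", "H")) {
      id <- aidx(native, r, nm)
      if (!id) next
      par <- native$atoms$parent[id]
      pidx <- if (par > 0L && !(native$atoms$res[par] %in% k:l))
        aidx(prob, native$atoms$res[par], native$atoms$name[par]) else 0L
      prob <- add_atom(prob, r, nm, native$atoms$elem[id], native$xyz[id, ],
                       parent = pidx, bb = TRUE)
    }
    prob$built[r] <- "scaffold"
    prob$chi[r] <- list(numeric(0))
  }
  mt <- measure_torsions(prob)
  prob$bb_tor <- mt$bb
  prob
}

#' Energy-vs-RMSD report
#'
#' Emits a per-model table (label, energy, loop C-alpha RMSD to the
#' reference) and optionally a scatter plot.
#'
#' @param ensembles named list of StageEnsembles.
#' @param reference reference \code{Conformation}.
#' @param loop_range integer c(k, l).
#' @param table_file optional path for a tab-separated table.
#' @param plot_file optional path for a PDF scatter plot.
#' @return the data.frame, invisibly when files are written.
#' @export
report_energy_vs_rmsd <- function(ensembles, reference,
                                  loop_range = reference$loop,
                                  table_file = NULL, plot_file = NULL) {
  rows <- NULL
  for (lab in names(ensembles)) {
    ens <- ensembles[[lab]]
    for (q in seq_along(ens$models))
      rows <- rbind(rows, data.frame(
        label = lab, model = q, energy = ens$energies[q],
        ca_rmsd = ca_rmsd(ens$models[[q]], reference, loop_range),
        stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(label = character(0), model = integer(0),
                       energy = numeric(0), ca_rmsd = numeric(0))
  if (!is.null(table_file))
    utils::write.table(rows, table_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(plot_file) && nrow(rows)) {
    grDevices::pdf(plot_file, width = 5, height = 4)
    labs <- factor(rows$label)
    graphics::plot(rows$ca_rmsd, rows$energy, col = as.integer(labs),
                   pch = 19, cex = 0.6,
                   xlab = expression(paste("C", alpha, " RMSD (Å)")),
                   ylab = "energy (kBT)")
    graphics::legend("topright", legend = levels(labs),
                     col = seq_along(levels(labs)), pch = 19, cex = 0.8)
    grDevices::dev.off()
  }
  if (is.null(table_file) && is.null(plot_file)) rows else invisible(rows)
}
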