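# Chain closure: bridge the N- and C-terminal loop fragments into a
# continuous loop.  One designated gap residue is grid-sampled; the
# remaining bridge torsions are closed by cyclic coordinate descent (CCD)
# against the three virtual/real atom pairs at the cutpoint; closures
# passing the 1.5 A screen get full-loop side-chain optimization,
# clustering, and torsional minimization with the linear chainbreak
# penalty at weight 150.

#' Cyclic coordinate descent chain closure
#'
#' Iterates over the bridge torsions cyclically (N to C order), setting
#' each to the analytic angle minimizing the summed squared deviation of
#' the three virtual/real target-atom pairs.  Stops at \code{max_cycles}
#' or when the RMS closure deviation drops below \code{tol}.  Non-bridge
#' torsions are never moved, and no per-torsion update increases the
#' deviation.
#'
#' @param conf a \code{Conformation} with a cutpoint.
#' @param bridge_torsions data.frame with columns \code{res}, \code{name}
#'   (ordered N to C).
#' @param max_cycles cycle cap (default 1000).
#' @param tol RMS deviation tolerance in Angstroms (default 1e-4).
#' @return list with \code{conf} (closed model) and \code{deviation}
#'   (final RMS closure deviation, Angstroms).
#' @export
ccd_close <- function(conf, bridge_torsions, max_cycles = 1000, tol = 1e-4) {
  if (is.na(conf$cutpoint)) stop("no cutpoint set")
  if (is.null(bridge_torsions) || nrow(bridge_torsions) == 0L)
    stop("empty bridge torsion list")
  mvs <- build_move_set(conf, bridge_torsions)
  prs <- chainbreak_pairs(conf)
  xyz <- conf$xyz
  devfun <- function(xyz)
    sqrt(mean(rowSums((xyz[prs[, 1], , drop = FALSE] -
                       xyz[prs[, 2], , drop = FALSE])^2)))
  dev <- devfun(xyz)
  for (cyc in seq_len(max_cycles)) {
    if (dev < tol) break
    dev_start <- dev
    for (mv in mvs) {
      movset <- mv$moving
      u <- .vhat(xyz[mv$C, ] - xyz[mv$B, ])
      origin <- xyz[mv$C, ]
      A <- 0; Bc <- 0
      for (pr in seq_len(3)) {
        a1 <- prs[pr, 1]; a2 <- prs[pr, 2]
        m1 <- a1 %in% movset; m2 <- a2 %in% movset
        if (m1 == m2) next                 # both or neither move: constant
        P <- if (m1) xyz[a1, ] else xyz[a2, ]
        Q <- if (m1) xyz[a2, ] else xyz[a1, ]
        v <- P - origin
        av <- sum(v * u) * u
        b <- v - av
        d <- Q - origin - av
        A <- A + sum(b * d)
        Bc <- Bc + sum(.vcross(u, b) * d)
      }
      if (A == 0 && Bc == 0) next
      ang <- atan2(Bc, A) * .r2d
      cand <- rotate_about_axis(xyz, movset, origin, u, ang)
      if (devfun(cand) <= dev + 1e-12) { xyz <- cand; dev <- devfun(xyz) }
    }
    if (dev_start - dev < 1e-6) break  # plateau: no usable progress left
  }
  conf$xyz <- xyz
  for (mv in mvs) {
    val <- .move_value(xyz, mv)
    if (mv$name %in% c("phi", "psi", "omega"))
      conf$bb_tor[mv$res, mv$name] <- val
    else conf$chi[[mv$res]][as.integer(sub("chi", "", mv$name))] <- val
  }
  list(conf = conf, deviation = dev)
}

# CCD torsion list for a closure attempt: psi of the residue preceding the
# first bridge residue (when movable), phi/psi of every bridge residue, phi
# of the residue after the last bridge residue (when movable)
.ccd_torsions <- function(conf, bridge, config) {
  k <- conf$loop[1]; l <- conf$loop[2]
  first <- if (length(bridge)) min(bridge) else conf$cutpoint + 1L
  last <- if (length(bridge)) max(bridge) else conf$cutpoint
  out <- NULL
  pre <- first - 1L
  if (pre >= k || (pre == conf$loop[1] - 1L && config$sample_loop_takeoff))
    out <- rbind(out, data.frame(res = pre, name = "psi"))
  for (r in bridge)
    out <- rbind(out, data.frame(res = r, name = c("phi", "psi")))
  post <- last + 1L
  if (post <= l || (post == l + 1L && config$sample_loop_takeoff))
    out <- rbind(out, data.frame(res = post, name = "phi"))
  out
}


# full-loop backbone move set; omega across the cutpoint is skipped (that
# bond is formally broken)
.loop_bb_moves <- function(conf, residues) {
  mv <- NULL
  for (r in residues) for (nm in c("phi", "psi", "omega")) {
    if (nm == "omega" && !is.na(conf$cutpoint) && r == conf$cutpoint + 1L) next
    mv <- rbind(mv, data.frame(res = r, name = nm, stringsAsFactors = FALSE))
  }
  mv
}

# extended-chain starting torsions for freshly added gap residues
.EXT <- c(phi = -135, psi = 135)

# full-loop optimization of a closed model: side-chain trials, then
# torsional minimization over all loop backbone torsions plus loop and
# neighboring chi, with the chainbreak penalty active
.full_loop_optimize <- function(conf, config, rng_seed) {
  k <- conf$loop[1]; l <- conf$loop[2]
  loopres <- k:l
  ws <- energy_weights("sampling",
                       linear_chainbreak = config$chainbreak_weight)
  wm <- energy_weights("minimization",
                       linear_chainbreak = config$chainbreak_weight)
  if (isTRUE(config$constrain_native) && !is.null(config$native))
    ws["coordinate_constraint"] <- wm["coordinate_constraint"] <- 1.0
  cst <- if (isTRUE(config$constrain_native) && !is.null(config$native))
    list(reference = config$native, residues = loopres) else NULL
  conf$excl <- conf_exclusions(conf)
  nb <- neighbor_list(conf, loopres, config$neighbor_cutoff)
  conf <- rotamer_trials(conf, nb, ws, rng_seed, sweeps = config$rt_sweeps)
  mv <- .loop_bb_moves(conf, loopres)
  if (config$sample_loop_takeoff)
    mv <- rbind(mv, data.frame(res = l + 1L, name = "phi"))
  for (r in nb) if (length(conf$chi[[r]]))
    mv <- rbind(mv, data.frame(res = r,
                               name = paste0("chi", seq_along(conf$chi[[r]]))))
  # omega of the takeoff bond at k is part of the loop; omega at k requires
  # residue k-1's C which always exists (scaffold anchor)
  conf <- torsion_minimize(conf, mv, wm, max_iter = config$min_iter,
                           tol = config$min_tol, constraint = cst)
  # alternate CCD re-tightening with backbone-only minimization: the last
  # minimization keeps (or improves) the near-perfect closure geometry
  bbmv <- .loop_bb_moves(conf, loopres)
  ccd_set <- bbmv[bbmv$name %in% c("phi", "psi"), , drop = FALSE]
  for (round in 1:2) {
    if (closure_deviation(conf) <= 1e-3) break
    conf <- ccd_close(conf, ccd_set, max_cycles = config$ccd_cycles,
                      tol = config$ccd_tol)$conf
    conf <- torsion_minimize(conf, bbmv, wm,
                             max_iter = 2 * config$min_iter,
                             tol = config$min_tol, constraint = cst)
  }
  list(conf = conf, energy = score(conf, wm, constraint = cst)$total)
}

#' Close the loop from a build-up stage
#'
#' Appends/prepends the 1-3 gap residues, grid-samples phi/psi of the
#' designated end gap residue, closes the remaining bridge torsions by CCD,
#' screens closures at 1.5 A, and subjects survivors to full-loop
#' side-chain optimization, clustering and minimization with the linear
#' chainbreak penalty active.
#'
#' @param ensemble_in \code{StageEnsemble} at stage (i, j) with
#'   1 <= j - i - 1 <= 3.
#' @param gap_sampling_end \code{"first"} (grid at gap residue i+1) or
#'   \code{"last"} (grid at gap residue j-1); identical when the gap is 1.
#' @param config an \code{\link{swa_config}}.
#' @param rng_seed integer seed.
#' @return list of closed candidates: \code{models}, \code{energies},
#'   \code{deviations} (pre-optimization closure deviations of survivors).
#' @export
close_from_stage <- function(ensemble_in, gap_sampling_end = c("first", "last"),
                             config = swa_config(), rng_seed = 1) {
  gap_sampling_end <- match.arg(gap_sampling_end)
  empty <- list(models = list(), energies = numeric(0),
                deviations = numeric(0))
  if (!length(ensemble_in$models)) return(empty)
  st <- ensemble_in$stage
  i <- st[1]; j <- st[2]
  gap <- (i + 1L):(j - 1L)
  m <- length(gap)
  if (m < 1L || m > config$max_gap)
    stop("gap outside 1-", config$max_gap, " residues")
  if (m == 1L) gap_sampling_end <- "first"  # variants coincide at gap 1
  proto <- ensemble_in$models[[1]]
  seq3 <- proto$seq
  ws <- energy_weights("sampling")
  npar <- min(length(ensemble_in$models), config$closure_parents)
  out_models <- list(); out_E <- numeric(0); out_dev <- numeric(0)
  for (p in seq_len(npar)) {
    parent <- ensemble_in$models[[p]]
    if (gap_sampling_end == "first") {
      sres <- i + 1L
      conf <- append_residue(parent, sres, .EXT["phi"], .EXT["psi"])
      bridge <- if (m > 1L) (i + 2L):(j - 1L) else integer(0)
      for (r in rev(bridge))
        conf <- prepend_residue(conf, r, .EXT["phi"], .EXT["psi"])
      cut <- i + 1L
    } else {
      sres <- j - 1L
      conf <- prepend_residue(parent, sres, .EXT["phi"], .EXT["psi"])
      bridge <- if (m > 1L) (i + 1L):(j - 2L) else integer(0)
      for (r in bridge)
        conf <- append_residue(conf, r, .EXT["phi"], .EXT["psi"])
      cut <- if (m > 1L) j - 2L else i
    }
    conf <- add_cutpoint(conf, cut)
    conf$excl <- conf_exclusions(conf)
    ccd_set <- .ccd_torsions(conf, bridge, config)
    if (is.null(ccd_set)) next
    om_values <- if (config$omega_cis_prepro && seq3[sres] == "PRO")
      c(180, 0) else 180
    spec <- list(torsion_step = config$torsion_step,
                 rama_cutoff = config$rama_cutoff, omega_values = om_values)
    rdf <- data.frame(res = sres, type = seq3[sres],
                      next_type = if (sres < length(seq3)) seq3[sres + 1] else NA,
                      stringsAsFactors = FALSE)
    assigns <- enumerate_backbone_grid(spec, rdf)
    smoves <- data.frame(res = sres, name = c("phi", "psi"))
    smvs <- build_move_set(conf, smoves)
    omv <- if (length(om_values) > 1L)
      build_move_set(conf, data.frame(res = sres, name = "omega")) else NULL
    for (a in seq_len(nrow(assigns))) {
      conf2 <- conf
      conf2$xyz <- apply_move_set(conf$xyz, smvs,
                                  as.numeric(assigns[a, 1:2]))
      conf2$bb_tor[sres, c("phi", "psi")] <- as.numeric(assigns[a, 1:2])
      if (!is.null(omv)) {
        conf2$xyz <- apply_move_set(conf2$xyz, omv, assigns$omega[a])
        conf2$bb_tor[sres, "omega"] <- assigns$omega[a]
      }
      cc <- ccd_close(conf2, ccd_set, max_cycles = config$ccd_cycles,
                      tol = config$ccd_tol)
      if (cc$deviation >= config$closure_screen) next
      cand <- cc$conf
      cand$closure_dev <- cc$deviation
      if (!.screen_ok(cand, config)) next
      out_models[[length(out_models) + 1L]] <- cand
      out_E <- c(out_E, score(cand, ws)$total)
      out_dev <- c(out_dev, cc$deviation)
    }
  }
  if (!length(out_models)) return(empty)
  # survivors: full-loop side-chain optimization + clustering + minimization
  cl <- cluster_fine(out_models, out_E, config$fine_radius, config$keep_fine)
  fin_models <- list(); fin_E <- numeric(0); fin_dev <- numeric(0)
  for (q in seq_along(cl$models)) {
    o <- .full_loop_optimize(cl$models[[q]], config,
                             stage_seed(rng_seed, i, j, q))
    if (!.screen_ok(o$conf, config)) next
    fin_models[[length(fin_models) + 1L]] <- .slim(o$conf)
    fin_E <- c(fin_E, o$energy)
    fin_dev <- c(fin_dev, cl$models[[q]]$closure_dev)
  }
  cl2 <- cluster_fine(fin_models, fin_E, config$fine_radius, config$keep_fine)
  list(models = cl2$models, energies = cl2$energies,
       deviations = fin_dev[cl2$index])
}

# graft the C-terminal fragment of confC onto confN (shared scaffold);
# atoms are copied in confC's order with parents remapped by (res, name)
graft_fragment <- function(confN, confC) {
  sel <- which(confC$atoms$res %in% which(confC$built == "cfrag") |
               (confC$atoms$name %in% .CAP_C_ATOMS))
  sel <- sel[order(sel)]
  conf <- confN
  for (k in sel) {
    at <- confC$atoms[k, ]
    par <- at$parent
    pidx <- if (par > 0L)
      aidx(conf, confC$atoms$res[par], confC$atoms$name[par]) else 0L
    conf <- add_atom(conf, at$res, at$name, at$elem, confC$xyz[k, ],
                     parent = pidx, bb = at$bb, virtual = at$virtual)
  }
  cres <- which(confC$built == "cfrag")
  conf$built[cres] <- "cfrag"
  conf$bb_tor[cres, ] <- confC$bb_tor[cres, , drop = FALSE]
  # the anchor's phi/omega were consumed when the C fragment was grown
  anchor <- max(cres) + 1L
  if (anchor <= conf$nres)
    conf$bb_tor[anchor, c("phi", "omega")] <-
      confC$bb_tor[anchor, c("phi", "omega")]
  conf$chi[cres] <- confC$chi[cres]
  conf$caps$c <- confC$caps$c
  conf
}

#' Recombine independently built N- and C-terminal fragment ensembles
#'
#' Pairs models from a pure-N ensemble (i, l+1) and a pure-C ensemble
#' (k-1, j), ranked by summed fragment energies and capped at
#' \code{config$max_pairs}; each combined model (equivalent to stage
#' (i, j)) is closed via the standard chain-closure machinery.
#'
#' @param ens_N_only \code{StageEnsemble} at (i, l+1) (N fragment only).
#' @param ens_C_only \code{StageEnsemble} at (k-1, j) (C fragment only).
#' @param config an \code{\link{swa_config}}.
#' @param rng_seed integer seed.
#' @param gap_sampling_end closure variant passed through.
#' @return as \code{\link{close_from_stage}}.
#' @export
recombine_fragments <- function(ens_N_only, ens_C_only,
                                config = swa_config(), rng_seed = 1,
                                gap_sampling_end = "first") {
  empty <- list(models = list(), energies = numeric(0),
                deviations = numeric(0))
  nN <- length(ens_N_only$models); nC <- length(ens_C_only$models)
  if (!nN || !nC) return(empty)
  i <- ens_N_only$stage[1]; j <- ens_C_only$stage[2]
  gap <- j - i - 1L
  if (gap < 1L || gap > config$max_gap) stop("incompatible stages")
  pairs <- expand.grid(a = seq_len(nN), b = seq_len(nC))
  pairs$E <- ens_N_only$energies[pairs$a] + ens_C_only$energies[pairs$b]
  pairs <- pairs[order(pairs$E), , drop = FALSE]
  pairs <- utils::head(pairs, config$max_pairs)
  models <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs)))
    models[[r]] <- graft_fragment(ens_N_only$models[[pairs$a[r]]],
                                  ens_C_only$models[[pairs$b[r]]])
  merged <- list(stage = c(i, j), models = models, energies = pairs$E)
  close_from_stage(merged, gap_sampling_end, config, rng_seed)
}
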