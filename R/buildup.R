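# The core stepwise-assembly move: enumerative backbone grid sampling for a
# newly added capped residue (and optionally the fragment-adjacent residue),
# Ramachandran filtering, side-chain optimization, fine leader clustering,
# and per-model torsional minimization.

#' Grid values for one torsion
#'
#' Left-inclusive sampling of [-180, 180): 18 values at the 20-degree step.
#'
#' @param step grid step in degrees (must divide 360).
#' @return numeric vector of sample phases.
#' @export
grid_values <- function(step = 20) {
  if (360 %% step != 0) stop("step must divide 360")
  seq(-180, 180 - step, by = step)
}

# (phi, psi) pairs of the grid surviving the rama filter for one residue
.rama_grid <- function(res3, next3, step, cutoff) {
  key <- paste("grid", res3, next3, step, cutoff, sep = "_")
  if (!is.null(.swa_cache[[key]])) return(.swa_cache[[key]])
  g <- grid_values(step)
  pairs <- expand.grid(phi = g, psi = g, KEEP.OUT.ATTRS = FALSE)
  cls <- rama_class(res3, next3)
  keep <- vapply(seq_len(nrow(pairs)), function(r)
    rama_score(cls, pairs$phi[r], pairs$psi[r]) <= cutoff, logical(1))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  .swa_cache[[key]] <- out
  out
}

#' Enumerate backbone torsion assignments for a build step
#'
#' Cartesian product of the per-residue (phi, psi) grids minus assignments
#' failing the Ramachandran filter at any sampled residue, times the omega
#' choices (180 only, or 180 and 0 at pre-proline).  Deterministic order.
#'
#' @param spec list with \code{torsion_step}, \code{rama_cutoff} and
#'   \code{omega_values} (e.g. \code{c(180)} or \code{c(180, 0)}).
#' @param residues data.frame with columns \code{res} (index), \code{type}
#'   (three-letter code) and \code{next_type} (three-letter code or NA),
#'   one or two rows.
#' @return data.frame with columns \code{phi_<res>}, \code{psi_<res>} per
#'   sampled residue and \code{omega}.
#' @export
enumerate_backbone_grid <- function(spec, residues) {
  stopifnot(nrow(residues) %in% c(1L, 2L))
  per <- lapply(seq_len(nrow(residues)), function(r)
    .rama_grid(residues$type[r], residues$next_type[r],
               spec$torsion_step, spec$rama_cutoff))
  omega <- spec$omega_values
  if (is.null(omega)) omega <- 180
  if (nrow(residues) == 1L) {
    g <- per[[1]]
    out <- g[rep(seq_len(nrow(g)), times = length(omega)), , drop = FALSE]
    out$omega <- rep(omega, each = nrow(g))
    names(out)[1:2] <- paste0(c("phi_", "psi_"), residues$res[1])
  } else {
    g1 <- per[[1]]; g2 <- per[[2]]
    idx <- expand.grid(a = seq_len(nrow(g1)), b = seq_len(nrow(g2)),
                       w = seq_along(omega), KEEP.OUT.ATTRS = FALSE)
    out <- data.frame(g1[idx$a, 1], g1[idx$a, 2], g2[idx$b, 1], g2[idx$b, 2],
                      omega = omega[idx$w])
    names(out) <- c(paste0(c("phi_", "psi_"), residues$res[1]),
                    paste0(c("phi_", "psi_"), residues$res[2]), "omega")
  }
  rownames(out) <- NULL
  out
}

# rebuilt (non-scaffold) residues of a model
.rebuilt_res <- function(conf) which(conf$built %in% c("nfrag", "cfrag"))

# coordinate row for clustering: named backbone atoms of given residues
.cluster_coords <- function(conf, residues, atoms = c("N", "CA", "C", "O")) {
  idx <- unlist(lapply(residues, function(r)
    vapply(atoms, function(a) aidx(conf, r, a), integer(1))))
  idx <- idx[idx > 0L]
  as.vector(t(conf$xyz[idx, , drop = FALSE]))
}

# greedy energy-ordered leader clustering on precomputed coordinate rows;
# returns the indices (into the input) of retained models, energy-sorted
leader_cluster <- function(coords, energies, radius, keep = Inf) {
  n <- length(energies)
  if (!n) return(integer(0))
  m <- ncol(coords) / 3
  if (!m) stop("empty atom selection for clustering")
  ord <- order(energies)
  leaders <- integer(0)
  for (o in ord) {
    if (length(leaders) >= keep) break
    ok <- TRUE
    if (length(leaders)) {
      d2 <- rowSums((coords[leaders, , drop = FALSE] -
                     matrix(coords[o, ], length(leaders), ncol(coords),
                            byrow = TRUE))^2) / m
      if (any(d2 < radius^2)) ok <- FALSE
    }
    if (ok) leaders <- c(leaders, o)
  }
  leaders
}

#' Fine clustering of build-step models
#'
#' Greedy energy-ordered leader clustering without superposition over the
#' backbone N, C, CA, O atoms of the rebuilt residues; the lowest-energy
#' model is always retained and at most \code{keep} models are returned,
#' energy-sorted.
#'
#' @param models list of \code{Conformation}s sharing scaffold coordinates.
#' @param energies numeric vector of model energies.
#' @param radius cluster radius in Angstroms (default 0.10).
#' @param keep maximum number of retained models (default 400).
#' @param residues residue indices for the RMSD (default: rebuilt residues).
#' @param atoms atom names for the RMSD (default backbone N, CA, C, O).
#' @return list with \code{models}, \code{energies} and \code{index} (the
#'   retained positions in the input).
#' @export
cluster_fine <- function(models, energies, radius = 0.10, keep = 400,
                         residues = NULL, atoms = c("N", "CA", "C", "O")) {
  if (!length(models))
    return(list(models = list(), energies = numeric(0), index = integer(0)))
  if (is.null(residues)) residues <- .rebuilt_res(models[[1]])
  coords <- do.call(rbind, lapply(models, .cluster_coords, residues, atoms))
  sel <- leader_cluster(coords, energies, radius, keep)
  list(models = models[sel], energies = energies[sel], index = sel)
}

# strip per-conformation caches before storing in an ensemble
.slim <- function(conf) { conf$excl <- NULL; conf }

# per-candidate backbone-RMSD screen against a native reference
.screen_ok <- function(conf, config) {
  if (is.na(config$rmsd_screen) || is.null(config$native)) return(TRUE)
  res <- .rebuilt_res(conf)
  if (!length(res)) return(TRUE)
  x <- .cluster_coords(conf, res)
  y <- .cluster_coords(config$native, res)
  sqrt(mean((x - y)^2) * 3) < config$rmsd_screen
}

#' One stepwise-assembly growth step
#'
#' For every parent model and every grid assignment surviving the
#' Ramachandran filter: place the new capped residue, optimize side chains
#' of the sampled residues and their neighbors (sampling weights), cluster
#' finely, minimize each retained model over the new residue's backbone
#' torsions and neighboring chi (minimization weights), and cluster again.
#'
#' @param ensemble_in a \code{StageEnsemble} (list with \code{stage},
#'   \code{models}, \code{energies}) at the parent stage.
#' @param direction \code{"N"} (append to the N fragment) or \code{"C"}.
#' @param config an \code{\link{swa_config}}.
#' @param rng_seed integer seed.
#' @return list of candidate models: \code{models}, \code{energies}
#'   (minimization-dialect totals).
#' @export
grow_step <- function(ensemble_in, direction = c("N", "C"),
                      config = swa_config(), rng_seed = 1) {
  direction <- match.arg(direction)
  if (!length(ensemble_in$models))
    return(list(models = list(), energies = numeric(0)))
  st <- ensemble_in$stage
  proto <- ensemble_in$models[[1]]
  k <- proto$loop[1]; l <- proto$loop[2]
  ws <- energy_weights("sampling")
  wm <- energy_weights("minimization")
  if (direction == "N") {
    new <- st[1] + 1L
    adj <- if (config$sample_adjacent && st[1] >= k) st[1] else NA_integer_
    if (new > st[2] - 1L) stop("grow direction inconsistent with stage index")
  } else {
    new <- st[2] - 1L
    adj <- if (config$sample_adjacent && st[2] <= l) st[2] else NA_integer_
    if (new < st[1] + 1L) stop("grow direction inconsistent with stage index")
  }
  sres <- c(new, if (!is.na(adj)) adj)
  seq3 <- proto$seq
  nxt <- function(r) if (r < length(seq3)) seq3[r + 1] else NA
  rdf <- data.frame(res = sres, type = seq3[sres],
                    next_type = vapply(sres, nxt, character(1)),
                    stringsAsFactors = FALSE)
  # omega of the newly formed peptide bond; cis sampled before proline
  om_res <- if (direction == "N") new else new + 1L
  omega_values <- if (config$omega_cis_prepro && seq3[om_res] == "PRO")
    c(180, 0) else 180
  spec <- list(torsion_step = config$torsion_step,
               rama_cutoff = config$rama_cutoff, omega_values = omega_values)
  assigns <- enumerate_backbone_grid(spec, rdf)
  out_models <- list(); out_energies <- numeric(0)
  for (p in seq_along(ensemble_in$models)) {
    parent <- ensemble_in$models[[p]]
    conf1 <- if (direction == "N")
      append_capped_residue(parent, new, phi = -120, psi = 130, omega = 180)
    else
      prepend_capped_residue(parent, new, phi = -120, psi = 130, omega = 180)
    conf1$excl <- conf_exclusions(conf1)
    moves <- data.frame(res = rep(sres, each = 2),
                        name = rep(c("phi", "psi"), length(sres)),
                        stringsAsFactors = FALSE)
    moves <- rbind(moves, data.frame(res = om_res, name = "omega"))
    mvs <- build_move_set(conf1, moves)
    vcols <- c(rbind(paste0("phi_", sres), paste0("psi_", sres)), "omega")
    cand_models <- list(); cand_E <- numeric(0)
    for (a in seq_len(nrow(assigns))) {
      vals <- as.numeric(assigns[a, vcols])
      conf2 <- conf1
      conf2$xyz <- apply_move_set(conf1$xyz, mvs, vals)
      for (q in seq_along(sres)) {
        conf2$bb_tor[sres[q], "phi"] <- assigns[a, paste0("phi_", sres[q])]
        conf2$bb_tor[sres[q], "psi"] <- assigns[a, paste0("psi_", sres[q])]
      }
      conf2$bb_tor[om_res, "omega"] <- assigns$omega[a]
      rtres <- if (isTRUE(config$rt_neighbors))
        neighbor_list(conf2, sres, config$neighbor_cutoff) else sres
      conf2 <- rotamer_trials(conf2, rtres, ws,
                              rng_seed = stage_seed(rng_seed, p, a),
                              sweeps = config$rt_sweeps)
      if (!.screen_ok(conf2, config)) next
      cand_models[[length(cand_models) + 1L]] <- conf2
      cand_E <- c(cand_E, score(conf2, ws)$total)
    }
    cl <- cluster_fine(cand_models, cand_E, config$fine_radius,
                       config$keep_fine)
    # per-model minimization: new-residue backbone + neighboring chi
    min_models <- list(); min_E <- numeric(0)
    for (q in seq_along(cl$models)) {
      m <- cl$models[[q]]
      mv2 <- data.frame(res = new, name = c("phi", "psi"),
                        stringsAsFactors = FALSE)
      mv2 <- rbind(mv2, data.frame(res = om_res, name = "omega"))
      nb <- if (isTRUE(config$rt_neighbors))
        neighbor_list(m, sres, config$neighbor_cutoff) else sres
      for (r in nb) if (length(m$chi[[r]]))
        mv2 <- rbind(mv2, data.frame(res = r,
                                     name = paste0("chi", seq_along(m$chi[[r]]))))
      m <- torsion_minimize(m, mv2, wm, max_iter = config$min_iter,
                            tol = config$min_tol)
      if (!.screen_ok(m, config)) next
      min_models[[length(min_models) + 1L]] <- .slim(m)
      min_E <- c(min_E, score(m, wm)$total)
    }
    cl2 <- cluster_fine(min_models, min_E, config$fine_radius,
                        config$keep_fine)
    out_models <- c(out_models, cl2$models)
    out_energies <- c(out_energies, cl2$energies)
  }
  list(models = out_models, energies = out_energies)
}
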