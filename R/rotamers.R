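# Side-chain conformer library and optimization: coarse backbone-independent
# rotamers with +/- 1 sigma expansions at chi1/chi2, Cbeta-based neighbor
# detection, stochastic one-at-a-time rotamer trials, and whole-model
# pre-packing.

# run expr with a private, seeded RNG stream; restores the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Rotamer library for a residue type
#'
#' @param res3 three-letter residue code.
#' @return data.frame with columns \code{chi1..chi4} (NA where the residue
#'   has fewer chis) and \code{sigma}; zero rows for residues without chi.
#' @export
rotamer_library <- function(res3) {
  lib <- .swa_table("rotamer_library.tsv")
  lib[lib$res == res3, c("chi1", "chi2", "chi3", "chi4", "sigma"), drop = FALSE]
}

#' Candidate chi vectors for side-chain optimization
#'
#' Canonical library rotamers plus variants with chi1 and chi2 shifted by
#' +/- 1 standard deviation (at most a 9-fold expansion).  Residues without
#' chi angles yield exactly one empty candidate.
#'
#' @param res3 three-letter residue code.
#' @param expand include the +/- 1 sigma chi1/chi2 expansions.
#' @return list of numeric chi vectors.
#' @export
rotamer_candidates <- function(res3, expand = TRUE) {
  key <- paste0("cand_", res3, "_", expand)
  if (!is.null(.swa_cache[[key]])) return(.swa_cache[[key]])
  nk <- n_chi(res3)
  if (nk == 0L) return(list(numeric(0)))
  lib <- rotamer_library(res3)
  out <- list()
  for (r in seq_len(nrow(lib))) {
    base <- as.numeric(lib[r, seq_len(nk)])
    sg <- lib$sigma[r]
    d1 <- c(0, -sg, sg)
    d2 <- if (nk >= 2) c(0, -sg, sg) else 0
    if (!expand) { d1 <- 0; d2 <- 0 }
    for (a in d1) for (b in d2) {
      v <- base
      v[1] <- wrap_angle(v[1] + a)
      if (nk >= 2) v[2] <- wrap_angle(v[2] + b)
      out[[length(out) + 1L]] <- v
    }
  }
  .swa_cache[[key]] <- out
  out
}

#' Residues neighboring a focus set, by C-beta distance
#'
#' A residue neighbors the focus set when its C-beta (C-alpha for glycine
#' or side-chain-less models) lies within \code{cutoff} of any focus
#' residue's C-beta.  The focus residues themselves are always included.
#'
#' @param conf a \code{Conformation}.
#' @param focus_residues integer vector of built residue indices.
#' @param cutoff distance cutoff in Angstroms (default 10).
#' @param include_fixed include scaffold residues (default TRUE).
#' @return sorted integer vector of residue indices.
#' @export
neighbor_list <- function(conf, focus_residues, cutoff = 10,
                          include_fixed = TRUE) {
  rep_atom <- function(r) {
    i <- aidx(conf, r, "CB")
    if (!i) i <- aidx(conf, r, "CA")
    i
  }
  built <- which(conf$built != "unbuilt")
  stopifnot(all(focus_residues %in% built))
  reps <- vapply(built, rep_atom, integer(1))
  built <- built[reps > 0L]; reps <- reps[reps > 0L]
  fxyz <- conf$xyz[vapply(focus_residues, rep_atom, integer(1)), , drop = FALSE]
  keep <- vapply(seq_along(built), function(k) {
    d2 <- rowSums(sweep(fxyz, 2, conf$xyz[reps[k], ])^2)
    any(d2 <= cutoff^2)
  }, logical(1))
  out <- built[keep]
  if (!include_fixed) out <- out[conf$built[out] != "scaffold" |
                                 out %in% focus_residues]
  sort(unique(c(out, focus_residues)))
}

# local energy of residue i's side chain against the current context:
# pair terms restricted to its side-chain atoms, plus its rotamer term
.sc_local_energy <- function(conf, i, weights) {
  sel <- which(conf$atoms$res == i & !conf$atoms$bb & !conf$atoms$virtual)
  if (!length(sel)) return(0)
  excl <- if (!is.null(conf$excl)) conf$excl else conf_exclusions(conf)
  mov <- logical(nrow(conf$xyz)); mov[sel] <- TRUE
  pt <- .cpp_pair_terms(conf$xyz, conf$atoms$radius, conf$atoms$hclass,
                        conf$atoms$hparent - 1L, conf$atoms$bb,
                        !conf$atoms$virtual, mov, TRUE,
                        excl[, 1] - 1L, excl[, 2] - 1L, 6.0, 0.15, 3.2, 2.9)
  w <- unclass(weights)
  sum(w[c("fa_atr", "fa_rep", "hbond_bb", "hbond_sc")] *
        pt[c("fa_atr", "fa_rep", "hbond_bb", "hbond_sc")]) +
    w["rotamer"] * rotamer_dev(conf$seq[i], conf$chi[[i]])
}

# one greedy visit: place the best candidate rotamer at residue i
.best_rotamer <- function(conf, i, weights, candidates) {
  best_e <- .sc_local_energy(conf, i, weights)
  best_conf <- conf
  for (chi in candidates) {
    cand <- set_sidechain_chi(conf, i, chi)
    e <- .sc_local_energy(cand, i, weights)
    if (e < best_e - 1e-12) { best_e <- e; best_conf <- cand }
  }
  best_conf
}

#' Greedy one-at-a-time rotamer optimization (rotamer trials)
#'
#' Visits the requested residues in a seeded random order (possibly several
#' sweeps) and replaces each side chain with its lowest-energy library
#' candidate (including +/- 1 sigma expansions) given the current context.
#' Total energy is non-increasing across accepted replacements and the
#' result is deterministic given the seed.
#'
#' @param conf a \code{Conformation}.
#' @param residues residue indices with placed backbones.
#' @param weights an \code{\link{energy_weights}} vector (sampling dialect
#'   is conventional here).
#' @param rng_seed integer seed for the visit order.
#' @param sweeps number of visiting sweeps (default 2).
#' @return the updated \code{Conformation}.
#' @export
rotamer_trials <- function(conf, residues, weights = energy_weights("sampling"),
                           rng_seed = 1, sweeps = 2) {
  if (any(conf$built[residues] == "unbuilt"))
    stop("rotamer trials requested for unbuilt residue(s)")
  residues <- residues[n_chi(conf$seq[residues]) > 0L]
  if (!length(residues)) return(conf)
  conf$excl <- conf_exclusions(conf)
  cand <- lapply(conf$seq[residues], rotamer_candidates)
  names(cand) <- as.character(residues)
  with_seed(rng_seed, {
    for (s in seq_len(sweeps)) {
      ord <- if (length(residues) == 1L) residues
             else sample(residues, length(residues))
      for (i in ord)
        conf <- .best_rotamer(conf, i, weights, cand[[as.character(i)]])
    }
  })
  conf
}

#' Pre-pack the scaffold side chains
#'
#' Places any missing scaffold side chains from ideal geometry, globally
#' optimizes them by multi-sweep seeded rotamer trials with a
#' Metropolis-annealed first phase, then continuously minimizes all chi
#' torsions.  The backbone is untouched; loop residues must be unbuilt.
#'
#' @param conf a \code{Conformation} whose loop residues are unbuilt.
#' @param weights sampling-dialect weights used for packing.
#' @param rng_seed integer seed.
#' @param anneal_sweeps Metropolis sweeps at decreasing temperature
#'   (default 20).
#' @return the prepacked \code{Conformation}.
#' @export
prepack <- function(conf, weights = energy_weights("sampling"), rng_seed = 1,
                    anneal_sweeps = 20) {
  resid <- which(conf$built == "scaffold")
  for (i in resid) {
    if (n_chi(conf$seq[i]) == 0L) {
      if (conf$seq[i] != "GLY" && !aidx(conf, i, "CB"))
        conf <- add_sidechain(conf, i)
      next
    }
    if (!aidx(conf, i, "CB") || is.null(conf$chi[[i]]) ||
        anyNA(conf$chi[[i]]))
      conf <- set_sidechain(conf, i, default_chi(conf$seq[i]))
  }
  packable <- resid[n_chi(conf$seq[resid]) > 0L]
  if (!length(packable)) return(conf)
  conf$excl <- conf_exclusions(conf)
  cand <- lapply(conf$seq[packable], rotamer_candidates)
  names(cand) <- as.character(packable)
  with_seed(rng_seed, {
    temps <- exp(seq(log(3), log(0.3), length.out = max(anneal_sweeps, 1)))
    for (s in seq_len(max(anneal_sweeps, 1))) {
      ord <- if (length(packable) == 1L) packable
             else sample(packable, length(packable))
      for (i in ord) {
        ci <- cand[[as.character(i)]]
        pick <- ci[[sample.int(length(ci), 1)]]
        e0 <- .sc_local_energy(conf, i, weights)
        cand_conf <- set_sidechain_chi(conf, i, pick)
        e1 <- .sc_local_energy(cand_conf, i, weights)
        if (e1 < e0 || runif(1) < exp(-(e1 - e0) / temps[s]))
          conf <- cand_conf
      }
    }
  })
  conf <- rotamer_trials(conf, packable, weights, rng_seed + 1L, sweeps = 2)
  # continuous chi relaxation under the same dialect used for packing
  moves <- do.call(rbind, lapply(packable, function(i)
    data.frame(res = i, name = paste0("chi", seq_along(conf$chi[[i]])),
               stringsAsFactors = FALSE)))
  torsion_minimize(conf, moves, weights, max_iter = 50)
}
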