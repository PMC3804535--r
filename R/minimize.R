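# Continuous torsion-space minimization over a declared move set.  Uses
# quasi-Newton (BFGS) descent with central-difference gradients of the
# total weighted energy; torsions are optimized in unwrapped radians and
# wrapped on write-back.  The final energy never exceeds the initial one.

# objective closure over a move set; the Ramachandran and rotamer terms are
# evaluated directly from the candidate torsion values, pair terms from the
# rebuilt coordinates (with fixed-fixed caching)
.make_objective <- function(conf, mvs, weights, constraint = NULL) {
  movable <- sort(unique(unlist(lapply(mvs, `[[`, "moving"))))
  cache <- energy_cache(conf, movable)
  n <- nrow(conf$xyz)
  mov <- logical(n); mov[movable] <- TRUE
  excl <- conf_exclusions(conf)
  w <- unclass(weights)
  base_bb <- conf$bb_tor
  base_chi <- conf$chi
  res_names <- vapply(mvs, function(m) m$name, character(1))
  res_ids <- vapply(mvs, function(m) as.integer(m$res), integer(1))
  cb_on <- !is.na(conf$cutpoint)
  cbp <- if (cb_on) chainbreak_pairs(conf) else NULL
  # rama/rotamer contributions of residues untouched by the move set are
  # constant during minimization
  aff <- sort(unique(res_ids))
  const_rama <- 0; const_rot <- 0
  for (i in setdiff(which(conf$built != "unbuilt"), aff)) {
    ph <- base_bb[i, "phi"]; ps <- base_bb[i, "psi"]
    if (!is.na(ph) && !is.na(ps))
      const_rama <- const_rama +
        unname(rama_score(conf$seq[i], unname(ph), unname(ps),
                          if (i < conf$nres) conf$seq[i + 1] else NA))
    if (length(base_chi[[i]]) && !anyNA(base_chi[[i]]))
      const_rot <- const_rot + rotamer_dev(conf$seq[i], base_chi[[i]])
  }

  eval_terms <- function(xdeg) {
    xyz <- apply_move_set(conf$xyz, mvs, xdeg)
    pt <- .cpp_pair_terms(xyz, conf$atoms$radius, conf$atoms$hclass,
                          conf$atoms$hparent - 1L, conf$atoms$bb,
                          !conf$atoms$virtual, mov, TRUE,
                          excl[, 1] - 1L, excl[, 2] - 1L, 6.0, 0.15, 3.2, 2.9)
    pt <- pt + cache
    bb <- base_bb; chi <- base_chi
    for (k in seq_along(mvs)) {
      if (res_names[k] %in% c("phi", "psi", "omega"))
        bb[res_ids[k], res_names[k]] <- wrap_angle(xdeg[k])
      else chi[[res_ids[k]]][as.integer(sub("chi", "", res_names[k]))] <-
          wrap_angle(xdeg[k])
    }
    rama <- const_rama; rot <- const_rot
    for (i in aff) {
      ph <- bb[i, "phi"]; ps <- bb[i, "psi"]
      if (!is.na(ph) && !is.na(ps))
        rama <- rama + unname(rama_score(conf$seq[i], unname(ph), unname(ps),
                                  if (i < conf$nres) conf$seq[i + 1] else NA))
      if (length(chi[[i]]) && !anyNA(chi[[i]]))
        rot <- rot + rotamer_dev(conf$seq[i], chi[[i]])
    }
    cb <- if (cb_on) sum(sqrt(rowSums((xyz[cbp[, 1], , drop = FALSE] -
                                       xyz[cbp[, 2], , drop = FALSE])^2))) else 0
    cst <- 0
    if (!is.null(constraint)) {
      tmp <- conf; tmp$xyz <- xyz
      cst <- do.call(ca_fade_constraint, c(list(conf = tmp), constraint))
    }
    sum(w[c("fa_atr", "fa_rep", "hbond_bb", "hbond_sc")] *
          pt[c("fa_atr", "fa_rep", "hbond_bb", "hbond_sc")]) +
      w["rama"] * rama + w["rotamer"] * rot +
      w["linear_chainbreak"] * cb + w["coordinate_constraint"] * cst
  }
  eval_terms
}

#' Quasi-Newton torsional minimization
#'
#' Minimizes the total weighted energy over the named torsions using BFGS
#' with central-difference gradients.  Non-move-set torsions are unchanged;
#' the returned energy is never above the starting energy; deterministic.
#'
#' @param conf a \code{Conformation}.
#' @param move_set data.frame with columns \code{res} and \code{name}
#'   (torsion names as in \code{\link{set_torsion}}); empty is a no-op.
#' @param weights an \code{\link{energy_weights}} vector.
#' @param max_iter BFGS iteration cap (default 200).
#' @param tol convergence tolerance in energy units (default 1e-4).
#' @param constraint optional coordinate-constraint spec (see
#'   \code{\link{score}}).
#' @param restarts BFGS restarts (Hessian resets); raise for tight
#'   convergence on small move sets.
#' @return the minimized \code{Conformation}.
#' @export
torsion_minimize <- function(conf, move_set, weights = energy_weights(),
                             max_iter = 200, tol = 1e-4, constraint = NULL,
                             restarts = 1L) {
  if (is.null(move_set) || nrow(move_set) == 0L || max_iter <= 0L)
    return(conf)
  mvs <- build_move_set(conf, move_set)
  obj <- .make_objective(conf, mvs, weights, constraint)
  x0 <- move_set_values(conf$xyz, mvs)
  e0 <- obj(x0)
  if (!is.finite(e0)) stop("non-finite starting energy")
  fr <- function(x) obj(x * .r2d)
  grr <- function(x) {
    h <- 5e-4
    vapply(seq_along(x), function(k) {
      xp <- x; xp[k] <- x[k] + h
      xm <- x; xm[k] <- x[k] - h
      (fr(xp) - fr(xm)) / (2 * h)
    }, numeric(1))
  }
  xcur <- x0 * .d2r; ecur <- e0
  for (restart in seq_len(max(restarts, 1L))) {  # restarts reset the Hessian
    fit <- tryCatch(
      stats::optim(xcur, fr, grr, method = "BFGS",
                   control = list(maxit = if (restart == 1L) max_iter else
                                    min(max_iter, 30L),
                                  reltol = 1e-14)),
      error = function(e) list(par = xcur, value = ecur))
    if (fit$value < ecur - 1e-12) {
      gain <- ecur - fit$value
      xcur <- fit$par; ecur <- fit$value
      if (gain < tol) break
    } else break
  }
  if (ecur <= e0) xbest <- xcur * .r2d else xbest <- x0
  conf$xyz <- apply_move_set(conf$xyz, mvs, xbest)
  for (k in seq_along(mvs)) {
    nm <- mvs[[k]]$name; i <- mvs[[k]]$res
    if (nm %in% c("phi", "psi", "omega"))
      conf$bb_tor[i, nm] <- wrap_angle(xbest[k])
    else conf$chi[[i]][as.integer(sub("chi", "", nm))] <- wrap_angle(xbest[k])
  }
  conf
}

#' Central-difference gradient of the energy over a move set
#'
#' Exposed for gradient-correctness checks: returns dE/dtorsion (energy
#' units per radian) at the current conformation.
#'
#' @inheritParams torsion_minimize
#' @param step finite-difference half-step in radians.
#' @return numeric vector, one entry per move-set torsion.
#' @export
energy_gradient <- function(conf, move_set, weights = energy_weights(),
                            step = 5e-4, constraint = NULL) {
  mvs <- build_move_set(conf, move_set)
  obj <- .make_objective(conf, mvs, weights, constraint)
  x0 <- move_set_values(conf$xyz, mvs) * .d2r
  fr <- function(x) obj(x * .r2d)
  vapply(seq_along(x0), function(k) {
    xp <- x0; xp[k] <- x0[k] + step
    xm <- x0; xm[k] <- x0[k] - step
    (fr(xp) - fr(xm)) / (2 * step)
  }, numeric(1))
}
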