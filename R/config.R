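# Run configuration: every tunable of the sampling pipeline in one place.
# The "default" preset carries the full protocol-scale settings; "coarse" is
# the desk-scale preset used by the packaged examples and acceptance runs
# (smaller retained ensembles and iteration caps, adjacent-residue
# resampling off) -- the protocol structure is identical.

#' Pipeline configuration
#'
#' @param preset \code{"default"} (protocol-scale retention: 400-model
#'   ensembles, 4000-model stage pools) or \code{"coarse"} (desk-scale).
#' @param ... named overrides of any field.
#' @return a named list of class \code{swa_config}.
#' @export
swa_config <- function(preset = c("default", "coarse"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    torsion_step = 20,        # grid: -180 to 180 in 20 deg increments
    rama_cutoff = 0.8,        # discard grid samples above this rama score
    omega_cis_prepro = TRUE,  # also sample omega = 0 before proline
    sample_adjacent = TRUE,   # resample the fragment-adjacent residue
    sample_loop_takeoff = FALSE,
    fine_radius = 0.10,       # fine leader-cluster radius (A)
    keep_fine = 400,          # models kept per parent after fine clustering
    stage_pool = 4000,        # stage collation: lowest-energy pool size
    stage_radius = 0.25,      # stage recluster radius (A)
    stage_keep = 400,         # models carried forward per stage
    final_radius = 1.0,       # final recluster radius (A, loop C-alpha)
    n_final = 5,              # number of predictions
    chainbreak_weight = 150,  # linear_chainbreak weight during closure
    closure_screen = 1.5,     # max pre-optimization closure deviation (A)
    closure_parents = Inf,    # parent models entering each closure edge
    ccd_cycles = 1000,
    ccd_tol = 1e-4,           # CCD stop tolerance (A)
    min_iter = 200,           # BFGS iteration cap
    min_tol = 1e-4,
    rt_sweeps = 2,            # rotamer-trials sweeps per build step
    rt_neighbors = TRUE,      # repack neighbors (not just sampled) per grid point
    neighbor_cutoff = 10,     # C-beta neighbor distance (A)
    max_pairs = 10000,        # fragment-recombination pairing cap
    max_gap = 3,
    mode = "auto",            # auto | linear | full
    prepack_sweeps = 20,
    convergence_gap = 1.0,    # kBT gap defining convergence
    rmsd_screen = NA,         # backbone-RMSD screen vs native (A), NA = off
    native = NULL,            # reference Conformation for screens/constraints
    constrain_native = FALSE) # activate the C-alpha fade constraint
  if (preset == "coarse") {
    cfg$sample_adjacent <- FALSE
    cfg$rt_neighbors <- FALSE
    cfg$keep_fine <- 8
    cfg$stage_pool <- 600
    cfg$stage_keep <- 50
    cfg$min_iter <- 30
    cfg$rt_sweeps <- 1
    cfg$ccd_cycles <- 200
    cfg$max_pairs <- 40
    cfg$closure_parents <- 8
    cfg$prepack_sweeps <- 8
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (360 %% cfg$torsion_step != 0)
    stop("torsion_step must divide 360")
  structure(cfg, class = "swa_config")
}

#' @export
print.swa_config <- function(x, ...) {
  cat("swa_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) v <- "NULL"
    if (inherits(v, "Conformation")) v <- "<Conformation>"
    cat(sprintf("  %-20s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# stable per-stage seed derived from the master seed (kept below 2^31)
stage_seed <- function(seed, i, j, tag = 0L) {
  as.integer((as.numeric(seed) * 7919 + (i + 50) * 1009 +
              (j + 50) * 131 + tag * 17) %% 2147483611)
}
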