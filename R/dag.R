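# Stage-graph construction and execution.  A stage (i, j) means: N-terminal
# fragment built forward through residue i, C-terminal fragment built
# backward through residue j (start node is (k-1, l+1)).  The full graph is
# O(N^2) in the loop length; the simplified graph grows only pure-N and
# pure-C chains and is O(N).  The pipeline runs the linear graph first and
# escalates to the full graph when the final energy gap is below 1 kBT.

#' Construct the build-up stage graph
#'
#' @param loop integer vector c(k, l), 1-based inclusive loop bounds.
#' @param mode \code{"full"} (all stages (i, j)) or \code{"linear"}
#'   (pure-N and pure-C chains only).
#' @param max_gap largest gap bridged by chain closure (default 3).
#' @return a \code{BuildDAG}: list with \code{nodes} (data.frame i, j),
#'   \code{edges} (data.frame from/to stage indices and \code{type}),
#'   \code{mode}, \code{loop}.
#' @export
build_dag <- function(loop, mode = c("full", "linear"), max_gap = 3) {
  mode <- match.arg(mode)
  k <- loop[1]; l <- loop[2]
  if (l < k) stop("inverted loop bounds")
  N <- l - k + 1L
  i0 <- k - 1L; j0 <- l + 1L
  nodes <- expand.grid(a = 0:N, b = 0:N)
  nodes <- nodes[nodes$a + nodes$b <= N - 1L, , drop = FALSE]
  if (mode == "linear") nodes <- nodes[nodes$a == 0L | nodes$b == 0L, ,
                                       drop = FALSE]
  nodes <- data.frame(i = i0 + nodes$a, j = j0 - nodes$b)
  nodes <- nodes[order(nodes$i - i0 + j0 - nodes$j, nodes$i), , drop = FALSE]
  rownames(nodes) <- NULL
  has_node <- function(i, j) any(nodes$i == i & nodes$j == j)
  edges <- NULL
  add_edge <- function(fi, fj, ti, tj, type)
    edges <<- rbind(edges, data.frame(from_i = fi, from_j = fj,
                                      to_i = ti, to_j = tj, type = type,
                                      stringsAsFactors = FALSE))
  for (r in seq_len(nrow(nodes))) {
    i <- nodes$i[r]; j <- nodes$j[r]
    if (has_node(i + 1L, j) && i + 1L < j) add_edge(i, j, i + 1L, j, "grow-N")
    if (has_node(i, j - 1L) && i < j - 1L) add_edge(i, j, i, j - 1L, "grow-C")
    gap <- j - i - 1L
    if (gap >= 1L && gap <= max_gap) {
      add_edge(i, j, k, l, "close-first")
      if (gap > 1L) add_edge(i, j, k, l, "close-last")
    }
  }
  # recombination: pure-N (i, l+1) with pure-C (k-1, j), combined gap 1..max
  pureN <- nodes[nodes$j == j0 & nodes$i > i0, , drop = FALSE]
  pureC <- nodes[nodes$i == i0 & nodes$j < j0, , drop = FALSE]
  for (a in seq_len(nrow(pureN))) for (b in seq_len(nrow(pureC))) {
    gap <- pureC$j[b] - pureN$i[a] - 1L
    if (gap >= 1L && gap <= max_gap)
      edges <- rbind(edges, data.frame(from_i = pureN$i[a], from_j = j0,
                                       to_i = i0, to_j = pureC$j[b],
                                       type = "recombine",
                                       stringsAsFactors = FALSE))
  }
  structure(list(nodes = nodes, edges = edges, mode = mode, loop = loop,
                 max_gap = max_gap),
            class = "BuildDAG")
}

#' @export
print.BuildDAG <- function(x, ...) {
  cat("BuildDAG (", x$mode, " mode): loop ", x$loop[1], "-", x$loop[2],
      ", ", nrow(x$nodes), " open stages, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Convergence test on a final ensemble
#'
#' TRUE iff the energy gap between the lowest and second-lowest energy
#' model is at least \code{gap} (1 kBT by default); a single-model
#' ensemble counts as converged, an empty one is an error.
#'
#' @param final_ensemble list with sorted \code{energies}.
#' @param gap convergence threshold in energy units.
#' @return logical.
#' @export
converged <- function(final_ensemble, gap = 1.0) {
  e <- sort(final_ensemble$energies)
  if (!length(e)) stop("empty ensemble")
  if (length(e) == 1L) return(TRUE)
  (e[2] - e[1]) >= gap
}

# stage collation: keep the `pool` lowest-energy models, leader-recluster
# over the rebuilt fragment backbones at `radius`, carry `keep` forward
.collate <- function(models, energies, config, radius = config$stage_radius,
                     keep = config$stage_keep, residues = NULL,
                     atoms = c("N", "CA", "C", "O")) {
  if (!length(models))
    return(list(models = list(), energies = numeric(0)))
  ord <- order(energies)
  ord <- utils::head(ord, config$stage_pool)
  models <- models[ord]; energies <- energies[ord]
  cl <- cluster_fine(models, energies, radius, keep, residues, atoms)
  list(models = cl$models, energies = cl$energies)
}

#' Execute a build-up graph
#'
#' Runs the stages in topological order: each open stage collates the
#' outputs of its incoming grow edges (lowest 4000, recluster at 0.25 A
#' over the rebuilt fragment backbone, keep 400); closure and
#' recombination edges feed the final full-loop stage, which is reclustered
#' at 1.0 A over loop C-alpha atoms to yield at most five predictions.
#'
#' @param dag a \code{\link{build_dag}} result.
#' @param scaffold_conf prepacked scaffold \code{Conformation} with the
#'   loop unbuilt.
#' @param config an \code{\link{swa_config}}.
#' @param rng_seed integer master seed (per-stage seeds are derived).
#' @param verbose print a per-stage log line.
#' @return list with \code{predictions} (final StageEnsemble, <= 5 models),
#'   \code{final_pool} (pre-selection closed ensemble), \code{log}
#'   (per-stage data.frame), \code{closure_devs}.
#' @export
run_dag <- function(dag, scaffold_conf, config = swa_config(), rng_seed = 1,
                    verbose = FALSE) {
  k <- dag$loop[1]; l <- dag$loop[2]
  i0 <- k - 1L; j0 <- l + 1L
  key <- function(i, j) paste(i, j, sep = ",")
  store <- new.env(parent = emptyenv())
  store[[key(i0, j0)]] <- list(stage = c(i0, j0),
                               models = list(.slim(scaffold_conf)),
                               energies =
                                 score(scaffold_conf,
                                       energy_weights("minimization"))$total)
  closed_models <- list(); closed_E <- numeric(0); closed_dev <- numeric(0)
  log <- NULL
  # topological order: nodes sorted by total built residues
  for (r in seq_len(nrow(dag$nodes))) {
    i <- dag$nodes$i[r]; j <- dag$nodes$j[r]
    if (i == i0 && j == j0) next
    t0 <- proc.time()[3]
    in_models <- list(); in_E <- numeric(0); n_in <- 0L
    # incoming grow edges
    inc <- dag$edges[dag$edges$to_i == i & dag$edges$to_j == j &
                     dag$edges$type %in% c("grow-N", "grow-C"), , drop = FALSE]
    for (e in seq_len(nrow(inc))) {
      par <- store[[key(inc$from_i[e], inc$from_j[e])]]
      if (is.null(par) || !length(par$models)) next
      n_in <- n_in + length(par$models)
      dir <- if (inc$type[e] == "grow-N") "N" else "C"
      gs <- grow_step(par, dir, config,
                      rng_seed = stage_seed(rng_seed, i, j,
                                            if (dir == "N") 1L else 2L))
      in_models <- c(in_models, gs$models)
      in_E <- c(in_E, gs$energies)
    }
    ens <- .collate(in_models, in_E, config)
    ens$stage <- c(i, j)
    store[[key(i, j)]] <- ens
    log <- rbind(log, data.frame(i = i, j = j, n_in = n_in,
                                 n_out = length(ens$models),
                                 min_energy = if (length(ens$energies))
                                   min(ens$energies) else NA_real_,
                                 seconds = round(proc.time()[3] - t0, 2)))
    if (verbose)
      message(sprintf("stage (%d,%d): %d in -> %d out, minE %.2f [%.1fs]",
                      i, j, n_in, length(ens$models),
                      if (length(ens$energies)) min(ens$energies) else NA,
                      proc.time()[3] - t0))
  }
  # closure + recombination edges feed the final stage
  cedges <- dag$edges[dag$edges$type %in%
                      c("close-first", "close-last", "recombine"), ,
                      drop = FALSE]
  for (e in seq_len(nrow(cedges))) {
    t0 <- proc.time()[3]
    type <- cedges$type[e]
    if (type == "recombine") {
      ensN <- store[[key(cedges$from_i[e], j0)]]
      ensC <- store[[key(i0, cedges$to_j[e])]]
      if (is.null(ensN) || is.null(ensC) ||
          !length(ensN$models) || !length(ensC$models)) next
      cs <- recombine_fragments(ensN, ensC, config,
                                stage_seed(rng_seed, cedges$from_i[e],
                                           cedges$to_j[e], 3L))
    } else {
      par <- store[[key(cedges$from_i[e], cedges$from_j[e])]]
      if (is.null(par) || !length(par$models)) next
      end <- if (type == "close-first") "first" else "last"
      cs <- close_from_stage(par, end, config,
                             stage_seed(rng_seed, cedges$from_i[e],
                                        cedges$from_j[e],
                                        if (end == "first") 4L else 5L))
    }
    closed_models <- c(closed_models, cs$models)
    closed_E <- c(closed_E, cs$energies)
    closed_dev <- c(closed_dev, cs$deviations)
    log <- rbind(log, data.frame(i = cedges$from_i[e], j = cedges$from_j[e],
                                 n_in = NA_integer_,
                                 n_out = length(cs$models),
                                 min_energy = if (length(cs$energies))
                                   min(cs$energies) else NA_real_,
                                 seconds = round(proc.time()[3] - t0, 2)))
    if (verbose)
      message(sprintf("%s (%d,%d): %d closed [%.1fs]", type,
                      cedges$from_i[e],
                      if (type == "recombine") cedges$to_j[e] else cedges$from_j[e],
                      length(cs$models), proc.time()[3] - t0))
  }
  ordc <- order(closed_E)
  closed_models <- closed_models[ordc]
  closed_E <- closed_E[ordc]
  closed_dev <- closed_dev[ordc]
  pool <- .collate(closed_models, closed_E, config)
  loopres <- k:l
  fin <- cluster_fine(pool$models, pool$energies, config$final_radius,
                      config$n_final, residues = loopres, atoms = "CA")
  pred <- list(stage = c(k, l), models = fin$models, energies = fin$energies)
  list(predictions = pred,
       final_pool = c(pool, list(stage = c(k, l))),
       log = log,
       closure_devs = closed_dev)
}

#' Run the full stepwise-assembly loop prediction
#'
#' Prepacks the scaffold, executes the simplified O(N) build-up graph, and
#' escalates to the full O(N^2) graph when the final energy gap is below
#' 1 kBT (mode \code{"auto"}); \code{"linear"} or \code{"full"} pin the
#' graph.  Deterministic given the seed.
#'
#' @param scaffold_conf scaffold \code{Conformation} with loop residues
#'   unbuilt (side chains may be absent).
#' @param loop integer c(k, l); defaults to \code{scaffold_conf$loop}.
#' @param config an \code{\link{swa_config}}.
#' @param rng_seed integer seed.
#' @param verbose logical.
#' @return an object of class \code{swa_result}.
#' @export
swa_run <- function(scaffold_conf, loop = scaffold_conf$loop,
                    config = swa_config(), rng_seed = 1, verbose = FALSE) {
  if (is.null(loop)) stop("no loop definition")
  scaffold_conf$loop <- loop
  pre <- prepack(scaffold_conf, energy_weights("sampling"),
                 rng_seed = stage_seed(rng_seed, 0L, 0L),
                 anneal_sweeps = config$prepack_sweeps)
  run_one <- function(mode) {
    dag <- build_dag(loop, mode, config$max_gap)
    run_dag(dag, pre, config, rng_seed, verbose)
  }
  mode <- config$mode
  if (mode == "auto") {
    res <- run_one("linear")
    used <- "linear"
    esc <- length(res$predictions$energies) &&
      !converged(res$predictions, config$convergence_gap)
    if (esc) {
      res <- run_one("full")
      used <- "full"
    }
  } else {
    res <- run_one(mode)
    used <- mode
  }
  structure(list(predictions = res$predictions,
                 final_pool = res$final_pool,
                 log = res$log,
                 closure_devs = res$closure_devs,
                 mode_used = used,
                 converged = if (length(res$predictions$energies))
                   converged(res$predictions, config$convergence_gap) else NA,
                 prepacked = pre,
                 config = config,
                 seed = rng_seed),
            class = "swa_result")
}

#' @export
print.swa_result <- function(x, ...) {
  cat("swa_result:", length(x$predictions$models), "predictions (mode",
      x$mode_used, ")\n")
  if (length(x$predictions$energies)) {
    cat("  energies:", paste(round(x$predictions$energies, 2),
                             collapse = ", "), "\n")
    cat("  converged (>= 1 kBT gap):", x$converged, "\n")
  }
  invisible(x)
}
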