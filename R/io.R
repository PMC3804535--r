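# Formats: PDB reading (via bio3d, tolerant of missing loop residues and
# side chains), PDB writing (fixed-width writer supporting multi-model
# ensembles), FASTA, loop files, YAML configuration, and the ensemble
# archive (models.pdb + scores.tsv).

# canonical output order of atoms within a residue
.atom_order <- function(names) {
  pref <- c("N", "CA", "C", "O", "H", "CB")
  match(names, pref, nomatch = length(pref) + 1L)
}

.pdb_line <- function(serial, name, res3, resno, xyz, elem) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, res3, resno, xyz[1], xyz[2], xyz[3], 1.0, 0.0, elem)
}

# ATOM records for one conformation (virtual atoms skipped, caps kept)
.pdb_records <- function(conf) {
  keep <- which(!conf$atoms$virtual)
  keep <- keep[order(conf$atoms$res[keep],
                     .atom_order(conf$atoms$name[keep]), keep)]
  lines <- character(length(keep))
  for (q in seq_along(keep)) {
    k <- keep[q]
    lines[q] <- .pdb_line(q, conf$atoms$name[k], conf$seq[conf$atoms$res[k]],
                          conf$atoms$res[k] + conf$offset, conf$xyz[k, ],
                          conf$atoms$elem[k])
  }
  lines
}

#' Write a conformation (or ensemble) to PDB
#'
#' Standard ATOM records, chain A, occupancy 1.00, element column
#' populated.  A list of conformations is written as MODEL/ENDMDL blocks.
#'
#' @param conf a \code{Conformation} or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(conf, path) {
  if (inherits(conf, "Conformation")) {
    writeLines(c(.pdb_records(conf), "END"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (m in seq_along(conf)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      writeLines(.pdb_records(conf[[m]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read a scaffold PDB into a Conformation
#'
#' Reads via \pkg{bio3d}; tolerant of missing side chains and missing loop
#' residues (which define the built mask).  Author numbering is mapped to
#' 1-based sequence position via \code{offset}; a supplied \code{sequence}
#' is validated against the structure (identity conflicts are fatal, with
#' a diff report).
#'
#' @param path PDB file path.
#' @param sequence optional full-chain sequence (one-letter string or
#'   three-letter vector); required when loop residues are absent from the
#'   file.
#' @param offset author numbering minus sequence position (default:
#'   inferred so the first record is position 1 when no sequence given,
#'   else 0).
#' @return a \code{Conformation}.
#' @export
read_pdb <- function(path, sequence = NULL, offset = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[!at$elety %in% .VIRTUAL_ATOMS, , drop = FALSE]
  if (is.null(offset)) offset <- 0L
  pos <- at$resno - offset
  if (min(pos) < 1L)
    stop("residue numbering below 1 after applying offset ", offset)
  if (is.null(sequence)) {
    present <- sort(unique(pos))
    missing <- setdiff(seq_len(max(pos)), present)
    if (length(missing))
      stop("residues ", paste(missing, collapse = ","),
           " absent from PDB; supply `sequence` to define them")
    seq3 <- vapply(present, function(p) at$resid[pos == p][1], character(1))
  } else {
    seq3 <- if (all(sequence %in% .AA3)) sequence else aa_three(sequence)
    conflict <- NULL
    for (p in unique(pos)) {
      got <- at$resid[pos == p][1]
      if (p > length(seq3)) stop("PDB residue ", p, " beyond sequence end")
      if (got != seq3[p])
        conflict <- rbind(conflict,
                          data.frame(position = p, pdb = got,
                                     sequence = seq3[p]))
    }
    if (!is.null(conflict)) {
      msg <- paste(utils::capture.output(print(conflict, row.names = FALSE)),
                   collapse = "\n")
      stop("sequence/structure mismatch:\n", msg)
    }
  }
  conf <- new_conformation(seq3)
  conf$offset <- as.integer(offset)
  present <- sort(unique(pos))
  for (r in present) {
    rows <- which(pos == r)
    nm <- at$elety[rows]
    ord <- order(.atom_order(nm))
    topo <- residue_topology(seq3[r])
    for (q in ord) {
      name <- at$elety[rows[q]]
      x <- c(at$x[rows[q]], at$y[rows[q]], at$z[rows[q]])
      known_bb <- name %in% c(.BB_NAMES, .CAP_N_ATOMS, .CAP_C_ATOMS)
      in_topo <- name %in% topo$atom
      if (!known_bb && !in_topo) next  # unknown / nonpolar-H record
      parent_name <- if (name == "N") NA
        else if (name == "CA") "N"
        else if (name == "C") "CA"
        else if (name %in% c("O", "NM")) "C"
        else if (name == "H") "N"
        else if (name == "CB") "CA"
        else if (name %in% c("CM", "HM")) "NM"
        else if (name == "CP") "N"
        else if (name %in% c("OP", "CMP")) "CP"
        else topo$a3[match(name, topo$atom)]
      pidx <- 0L
      if (name == "N") {
        if (r > 1L) pidx <- aidx(conf, r - 1L, "C")
      } else pidx <- aidx(conf, r, parent_name)
      if (!pidx && name != "N") next  # orphan (partial side chain)
      elem <- if (name %in% c(.BB_NAMES, .CAP_N_ATOMS, .CAP_C_ATOMS)) {
        c(N = "N", CA = "C", C = "C", O = "O", H = "H", NM = "N", CM = "C",
          HM = "H", CP = "C", OP = "O", CMP = "C")[name]
      } else topo$elem[match(name, topo$atom)]
      bbf <- name %in% c(.BB_NAMES, .CAP_N_ATOMS, .CAP_C_ATOMS)
      conf <- add_atom(conf, r, name, unname(elem), x, parent = pidx, bb = bbf)
    }
    conf$built[r] <- "scaffold"
  }
  mt <- measure_torsions(conf)
  conf$bb_tor <- mt$bb
  for (r in present) {
    nk <- n_chi(seq3[r])
    if (nk == 0L) { conf$chi[r] <- list(numeric(0)); next }
    tup <- chi_atoms(seq3[r])
    v <- rep(NA_real_, nk)
    for (kk in seq_len(nk)) {
      id <- vapply(tup[[kk]], function(a) aidx(conf, r, a), integer(1))
      if (all(id > 0))
        v[kk] <- dihedral(conf$xyz[id[1], ], conf$xyz[id[2], ],
                          conf$xyz[id[3], ], conf$xyz[id[4], ])
    }
    conf$chi[[r]] <- if (anyNA(v)) numeric(0) else v
  }
  conf
}

#' Read a FASTA file (first record)
#' @param path file path.
#' @return list with \code{header} and \code{sequence} (one-letter string).
#' @export
read_fasta <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hd <- grep("^>", ln)
  if (!length(hd)) stop("no FASTA header in ", path)
  end <- if (length(hd) > 1L) hd[2] - 1L else length(ln)
  list(header = sub("^>", "", ln[hd[1]]),
       sequence = gsub("[^A-Za-z]", "",
                       paste(ln[(hd[1] + 1L):end], collapse = "")))
}

#' Write a FASTA file
#' @param sequence one-letter string or three-letter vector.
#' @param path file path.
#' @param header record header (without \code{>}).
#' @export
write_fasta <- function(sequence, path, header = "chain_A") {
  if (all(sequence %in% .AA3)) sequence <- paste(aa_one(sequence),
                                                 collapse = "")
  writeLines(c(paste0(">", header), sequence), path)
  invisible(path)
}

#' Read a loop definition file
#'
#' Whitespace-separated \code{start end} per line, 1-based inclusive.
#'
#' @param path file path.
#' @return list of integer c(start, end) vectors.
#' @export
read_loopfile <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  out <- lapply(seq_along(ln), function(q) {
    f <- suppressWarnings(as.integer(strsplit(ln[q], "\\s+")[[1]]))
    if (length(f) < 2L || anyNA(f[1:2]))
      stop("malformed loop file line ", q, ": '", ln[q], "'")
    if (f[2] < f[1]) stop("inverted loop bounds at line ", q)
    f[1:2]
  })
  out
}

#' Load a YAML run configuration
#'
#' Fields are validated against \code{\link{swa_config}}; unknown fields
#' are an error.
#'
#' @param path YAML file path (NULL gives the defaults).
#' @param preset base preset to override (default \code{"default"}).
#' @return an \code{swa_config}.
#' @export
load_config <- function(path = NULL, preset = "default") {
  if (is.null(path)) return(swa_config(preset))
  y <- yaml::read_yaml(path)
  if (!is.null(y$preset)) { preset <- y$preset; y$preset <- NULL }
  do.call(swa_config, c(list(preset = preset), y))
}

#' Write / read a stage-ensemble archive
#'
#' A directory with \code{models.pdb} (multi-model) and \code{scores.tsv}
#' (model id, per-term energies, total, closure deviation and RMSD when
#' available) -- inspectable with standard structure viewers.
#'
#' @param ensemble list with \code{models}, \code{energies} (and optional
#'   \code{deviations}).
#' @param dir archive directory (created).
#' @param weights weights used for the per-term breakdown.
#' @param reference optional \code{Conformation} for an RMSD column.
#' @return the directory, invisibly.
#' @export
archive_write <- function(ensemble, dir, weights = energy_weights(),
                          reference = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(ensemble$models, file.path(dir, "models.pdb"))
  rows <- NULL
  for (q in seq_along(ensemble$models)) {
    br <- score(ensemble$models[[q]], weights)
    row <- data.frame(model = q, t(br$terms), total = br$total)
    row$closure_dev <- if (!is.null(ensemble$deviations) &&
                           length(ensemble$deviations) >= q)
      ensemble$deviations[q] else NA_real_
    row$ca_rmsd <- if (!is.null(reference))
      ca_rmsd(ensemble$models[[q]], reference) else NA_real_
    rows <- rbind(rows, row)
  }
  if (is.null(rows)) rows <- data.frame(model = integer(0))
  utils::write.table(rows, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname archive_write
#' @param sequence full-chain sequence for rereading models.
#' @param loop loop range c(k, l).
#' @export
archive_read <- function(dir, sequence, loop = NULL) {
  scores <- utils::read.delim(file.path(dir, "scores.tsv"))
  path <- file.path(dir, "models.pdb")
  ln <- readLines(path)
  starts <- grep("^MODEL", ln)
  ends <- grep("^ENDMDL", ln)
  models <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(c(ln[(starts[m] + 1L):(ends[m] - 1L)], "END"), tmp)
    models[[m]] <- read_pdb(tmp, sequence = sequence)
    if (!is.null(loop)) models[[m]]$loop <- loop
    unlink(tmp)
  }
  list(models = models, energies = scores$total, scores = scores)
}

#' Write a fixture bundle directory
#'
#' \code{problem.pdb}, \code{native.pdb}, \code{seq.fasta},
#' \code{loop.txt} and \code{meta.yaml} for a recovery problem.
#'
#' @param fixture result of \code{\link{make_recovery_problem}}.
#' @param dir output directory.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(fixture$problem, file.path(dir, "problem.pdb"))
  write_pdb(fixture$native, file.path(dir, "native.pdb"))
  write_fasta(fixture$native$seq, file.path(dir, "seq.fasta"),
              header = "fixture")
  writeLines(paste(fixture$loop[1], fixture$loop[2]),
             file.path(dir, "loop.txt"))
  yaml::write_yaml(list(loop = as.integer(fixture$loop),
                        n_residues = fixture$native$nres,
                        synthetic = TRUE), file.path(dir, "meta.yaml"))
  invisible(dir)
}
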