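# Residue topology: ideal internal coordinates for side-chain and polar-H
# atoms, loaded from the versioned table in inst/extdata.  Backbone atoms
# (N, CA, C, O, H) and capping groups are placed by dedicated rules in
# conformation.R; everything else comes from this table.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- setNames(names(.AA3), .AA3)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of residue codes.
#' @return character vector in the other convention.
#' @examples
#' aa_three("AG")
#' aa_one(c("ALA", "GLY"))
#' @export
aa_three <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L && !x[1] %in% .AA3)
    x <- strsplit(x, "")[[1]]
  out <- .AA3[toupper(x)]
  if (anyNA(out)) stop("unknown residue code(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- .AA1[toupper(x)]
  if (anyNA(out)) stop("unknown residue code(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

# rows of the topology table for one residue type (empty for GLY)
residue_topology <- function(res3) {
  topo <- .swa_table("residue_topology.tsv")
  topo[topo$res == res3, , drop = FALSE]
}

# number of sampled/minimized chi torsions per residue type
n_chi <- function(res3) {
  key <- "nchi"
  if (is.null(.swa_cache[[key]])) {
    topo <- .swa_table("residue_topology.tsv")
    tab <- sapply(split(topo$ttype, topo$res), function(tt) {
      k <- grep("^chi", tt, value = TRUE)
      if (!length(k)) 0L else max(as.integer(sub("chi", "", k)))
    })
    .swa_cache[[key]] <- tab
  }
  v <- .swa_cache[[key]][res3]
  v[is.na(v)] <- 0L          # GLY (no table rows), ALA handled by table
  unname(v)
}

# 4-atom name tuples defining each chi of a residue type.  The defining atom
# for chi k is the table atom with ttype == "chi<k>" and zero offset; the
# tuple is then (a1, a2, a3, atom).
chi_atoms <- function(res3) {
  nk <- n_chi(res3)
  if (nk == 0L) return(list())
  rows <- residue_topology(res3)
  lapply(seq_len(nk), function(k) {
    sel <- rows$ttype == paste0("chi", k) & rows$tors == 0
    r <- rows[sel, , drop = FALSE][1, ]
    c(r$a1, r$a2, r$a3, r$atom)
  })
}

# ideal backbone internal coordinates (Engh-Huber-like), one place only
.BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.010,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8,
  a_CNH = 119.0, a_NCO = 123.0)
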