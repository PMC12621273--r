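#' Construct a protein chain object
#'
#' A `protein_chain` holds the ordered residue records of one chain:
#' one-letter amino-acid codes, C-alpha coordinates in Angstrom, and
#' per-residue pLDDT confidence scores (0-100, as written by AlphaFold-style
#' predictors into the PDB B-factor column).
#'
#' @param chain_id Single character chain identifier (e.g. "A").
#' @param aa Character vector of one-letter amino-acid codes; non-standard
#'   residues are represented as "X".
#' @param coords Numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param plddt Numeric vector of per-residue confidence in [0, 100];
#'   defaults to 0 when absent.
#' @return An object of class `protein_chain`.
#' @export
protein_chain <- function(chain_id, aa, coords, plddt = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  aa <- as.character(aa)
  if (length(aa) != n) stop("length(aa) must equal nrow(coords)")
  bad <- !(aa %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    warning(sprintf("%d non-standard residue code(s) mapped to 'X'", sum(bad)))
    aa[bad] <- "X"
  }
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(plddt)) plddt <- rep(0, n)
  if (length(plddt) != n) stop("length(plddt) must equal the chain length")
  plddt <- pmin(100, pmax(0, as.numeric(plddt)))
  structure(
    list(chain_id = as.character(chain_id), aa = aa,
         coords = unname(coords), plddt = plddt),
    class = "protein_chain"
  )
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain %s>  %d residues\n", x$chain_id, length(x$aa)))
  cat("  sequence: ", abbreviate_seq(chain_sequence(x)), "\n", sep = "")
  cat(sprintf("  mean pLDDT: %.1f\n", mean(x$plddt)))
  invisible(x)
}

#' @export
length.protein_chain <- function(x) length(x$aa)

abbreviate_seq <- function(s, width = 50) {
  if (nchar(s) <= width) s else paste0(substr(s, 1, width - 3), "...")
}

#' Sequence of a protein chain
#'
#' @param chain A `protein_chain`.
#' @return Single string of one-letter codes in residue order.
#' @export
chain_sequence <- function(chain) paste(chain$aa, collapse = "")

# three-letter -> one-letter map for the 20 standard residues
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Read protein chains from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) and extracts, per chain, the ordered
#' C-alpha records: residue identity, coordinates, and the B-factor column
#' interpreted as pLDDT. Only the first model of multi-model files is used,
#' HETATM records are ignored, alternate locations resolve to the first
#' encountered, and residues lacking a C-alpha atom are dropped. Residues
#' are re-indexed contiguously in file order within each chain.
#'
#' @param path Path to a PDB file.
#' @param chain_ids Optional character vector restricting which chains to
#'   return (in the requested order).
#' @return A named list of `protein_chain` objects.
#' @export
read_chains <- function(path, chain_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop(sprintf("failed to parse PDB file %s: %s",
                                     path, conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  # first altloc encountered per residue
  key <- paste(at$chain, at$resno, at$insert)
  at <- at[!duplicated(key), , drop = FALSE]
  present <- unique(at$chain)
  if (is.null(chain_ids)) chain_ids <- present
  out <- list()
  for (cid in chain_ids) {
    sel <- at[at$chain == cid, , drop = FALSE]
    if (nrow(sel) == 0L)
      stop(sprintf("chain '%s' has no C-alpha atoms in %s", cid, path))
    aa <- AA3TO1[sel$resid]
    aa[is.na(aa)] <- "X"
    b <- sel$b
    b[is.na(b)] <- 0
    out[[cid]] <- protein_chain(
      chain_id = cid, aa = unname(aa),
      coords = cbind(sel$x, sel$y, sel$z), plddt = b
    )
  }
  out
}

#' Write protein chains to a PDB file
#'
#' Emits one ATOM record per residue (the C-alpha only), with the pLDDT
#' value in the B-factor column, and a TER record after each chain.
#' `read_chains(write_chain(x))` reproduces sequences and chain ids exactly,
#' coordinates to the format's 3-decimal precision and pLDDT to 2 decimals.
#'
#' @param chains A `protein_chain` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  if (inherits(chains, "protein_chain")) chains <- list(chains)
  if (length(chains) == 0L) stop("chains must be non-empty")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write %s", path)))
  on.exit(close(con))
  serial <- 0L
  for (ch in chains) {
    stopifnot(inherits(ch, "protein_chain"))
    n <- length(ch$aa)
    for (i in seq_len(n)) {
      serial <- serial + 1L
      res3 <- if (ch$aa[i] == "X") "UNK" else AA1TO3[[ch$aa[i]]]
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial %% 100000L, res3, substr(ch$chain_id, 1, 1), i %% 10000L,
        ch$coords[i, 1], ch$coords[i, 2], ch$coords[i, 3],
        1.00, ch$plddt[i]), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       serial %% 100000L,
                       if (ch$aa[n] == "X") "UNK" else AA1TO3[[ch$aa[n]]],
                       substr(ch$chain_id, 1, 1), n %% 10000L), con)
  }
  writeLines("END", con)
  invisible(path)
}
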