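# Fixed residue alphabet: the 20 standard one-letter codes in alphabetical
# order, with "X" (unknown / non-standard) occupying the final slot.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_FULL <- c(AA_ALPHABET, "X")

aa_indices <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  idx <- match(letters, AA_FULL)
  if (anyNA(idx)) {
    warning(sprintf("%d unknown character(s) mapped to 'X'", sum(is.na(idx))))
    idx[is.na(idx)] <- 21L
  }
  idx
}

#' One-hot residue embedding
#'
#' Embeds each residue of a sequence as an L-dimensional one-hot vector.
#' The first 21 columns are the fixed alphabet slots (20 standard amino
#' acids alphabetically, then "X"); columns beyond 21 are zero padding so
#' the one-hot baseline can occupy the same dimensionality as a protein
#' language model embedding.
#'
#' @param sequence Non-empty amino-acid string (characters outside the
#'   alphabet are mapped to "X" with a warning).
#' @param dim_L Embedding dimension, at least 21. Default 32.
#' @return An N x `dim_L` numeric matrix with one 1 per row.
#' @export
one_hot_embed <- function(sequence, dim_L = 32L) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (dim_L < 21L) stop("dim_L must be >= 21 for one-hot embeddings")
  idx <- aa_indices(sequence)
  m <- matrix(0, nrow = length(idx), ncol = dim_L)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# run expr with an isolated, seeded RNG stream; global RNG state untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic synthetic residue embedding
#'
#' A test double for protein language models: each residue is embedded as a
#' pseudo-random unit-norm vector keyed only by (letter, seed), so identical
#' letters always get identical rows and the mapping is reproducible across
#' processes.
#'
#' @param sequence Amino-acid string.
#' @param dim_L Embedding dimension (>= 1). Default 32.
#' @param seed Integer seed keying the letter-to-vector table.
#' @return An N x `dim_L` numeric matrix of unit-norm rows.
#' @export
synthetic_embed <- function(sequence, dim_L = 32L, seed = 1L) {
  if (dim_L < 1L) stop("dim_L must be >= 1")
  idx <- aa_indices(sequence)
  table <- with_local_seed(seed, {
    t(vapply(seq_len(21L), function(i) {
      v <- rnorm(dim_L)
      v / sqrt(sum(v^2))
    }, numeric(dim_L)))
  })
  table[idx, , drop = FALSE]
}

#' Load a precomputed embedding matrix
#'
#' Reads an N x L numeric matrix from a TSV file (rows = residues in chain
#' order) such as externally computed protein language-model embeddings, and
#' validates the row count against the chain length.
#'
#' @param path TSV file, one row per residue, no header.
#' @param expected_N Expected number of rows (the chain length).
#' @return An N x L numeric matrix.
#' @export
load_embedding <- function(path, expected_N) {
  if (!file.exists(path)) stop(sprintf("embedding file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)),
                               nrow = nrow(df), ncol = ncol(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  if (nrow(m) != expected_N)
    stop(sprintf("embedding has %d rows but the chain has %d residues",
                 nrow(m), expected_N))
  m
}

#' Resolve an embedder by name
#'
#' Returns a function `sequence -> embedding matrix` for one of the built-in
#' providers. Embeddings computed out of process (real protein language
#' models) are supplied per chain via [load_embedding()] and the "file"
#' provider, which looks the matrix up next to the structure file
#' (`<pdb path>.emb.tsv`).
#'
#' @param name One of "onehot", "synthetic", "file".
#' @param dim_L Embedding dimension.
#' @param seed Seed for the synthetic provider.
#' @return A list with fields `name`, `dim_L` and `embed(sequence, path)`.
#' @export
get_embedder <- function(name = c("onehot", "synthetic", "file"),
                         dim_L = 32L, seed = 1L) {
  name <- match.arg(name)
  embed <- switch(name,
    onehot = function(sequence, path = NULL) one_hot_embed(sequence, dim_L),
    synthetic = function(sequence, path = NULL)
      synthetic_embed(sequence, dim_L, seed),
    file = function(sequence, path = NULL) {
      if (is.null(path)) stop("the 'file' embedder needs the structure path")
      load_embedding(paste0(path, ".emb.tsv"), nchar(sequence))
    })
  list(name = name, dim_L = as.integer(dim_L), embed = embed)
}
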