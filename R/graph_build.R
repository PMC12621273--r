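#' C-alpha distance matrix of one chain
#'
#' @param chain A `protein_chain`.
#' @return N x N symmetric matrix of Euclidean C-alpha distances (Angstrom).
#' @export
distance_matrix <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  m <- as.matrix(stats::dist(chain$coords))
  dimnames(m) <- NULL
  m
}

empty_edges <- function() {
  data.frame(i = integer(), j = integer(), w = numeric())
}

#' Intra-chain contact edges
#'
#' Builds the within-chain edge list of the residue graph: a directed edge
#' in both orientations for every residue pair closer than `cutoff`
#' (strictly), weighted by the C-alpha distance. Self-loops are not emitted;
#' the attention layer adds them internally.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param cutoff Distance cutoff in Angstrom (strict "less than"). Default 8.
#' @return A data frame with columns `i`, `j` (1-based node indices), `w`.
#' @export
intra_edges <- function(dm, cutoff = 8) {
  if (cutoff <= 0) stop("cutoff must be positive")
  dm <- as.matrix(dm)
  sel <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty_edges())
  w <- dm[sel]
  data.frame(i = c(sel[, 1], sel[, 2]), j = c(sel[, 2], sel[, 1]),
             w = c(w, w))
}

#' Inter-chain fictional edges
#'
#' Every residue of chain A is connected to every residue of chain B in both
#' directions with a fixed weight equal to the 8 Angstrom contact threshold.
#' These fictional edges carry cross-chain message passing; their weight is
#' label-independent by construction.
#'
#' @param n_A,n_B Chain sizes (>= 1). Node indices for chain B are offset by
#'   `n_A`.
#' @param weight Fixed edge weight. Default 8.
#' @return Edge data frame with `2 * n_A * n_B` rows.
#' @export
inter_edges <- function(n_A, n_B, weight = 8) {
  stopifnot(n_A >= 1L, n_B >= 1L)
  g <- expand.grid(i = seq_len(n_A), j = n_A + seq_len(n_B))
  data.frame(i = c(g$i, g$j), j = c(g$j, g$i),
             w = rep(weight, 2L * nrow(g)))
}

#' Count inter-chain contacts
#'
#' A contact is an inter-chain residue pair whose C-alpha distance is below
#' `cutoff` (strictly). Returns both the pair count and the set of residues
#' participating in at least one contact.
#'
#' @param chainA,chainB `protein_chain` objects.
#' @param cutoff Contact cutoff in Angstrom. Default 8.
#' @return List with `n_pairs` (integer) and `contact_residues`, a character
#'   vector of labels `"<chain_id>:<1-based residue index>"`.
#' @export
count_contacts <- function(chainA, chainB, cutoff = 8) {
  d <- cross_dist(chainA$coords, chainB$coords)
  hit <- d < cutoff
  ra <- which(rowSums(hit) > 0)
  rb <- which(colSums(hit) > 0)
  list(
    n_pairs = sum(hit),
    contact_residues = c(
      if (length(ra)) paste0(chainA$chain_id, ":", ra),
      if (length(rb)) paste0(chainB$chain_id, ":", rb))
  )
}

# pairwise Euclidean distances between two coordinate sets (nA x nB)
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Build the pair graph of a two-chain complex
#'
#' Stacks the two chains' residue embeddings into one node-feature matrix
#' (chain A first), and combines intra-chain distance edges of each chain
#' with the fully connected inter-chain fictional edges.
#'
#' @param chainA,chainB `protein_chain` objects.
#' @param embA,embB Embedding matrices with one row per residue and a common
#'   number of columns.
#' @param cutoff Intra-chain contact cutoff (Angstrom). Default 8.
#' @param intra_A,intra_B Optional replacement intra-chain edge lists (local
#'   node indices), used by the contact-map graph mode; when supplied they
#'   stand in for the distance-derived edges.
#' @return A `pair_graph`: list with `node_features`, `edges` (data frame
#'   `i`, `j`, `w`), `chain` (character vector of "A"/"B"), `n_A`, `n_B`.
#' @export
build_pair_graph <- function(chainA, chainB, embA, embB, cutoff = 8,
                             intra_A = NULL, intra_B = NULL) {
  nA <- length(chainA$aa); nB <- length(chainB$aa)
  if (nrow(embA) != nA || nrow(embB) != nB)
    stop(sprintf("embedding rows (%d, %d) do not match chain lengths (%d, %d)",
                 nrow(embA), nrow(embB), nA, nB))
  if (ncol(embA) != ncol(embB))
    stop("the two chains' embedding dimensions differ")
  if (is.null(intra_A)) intra_A <- intra_edges(distance_matrix(chainA), cutoff)
  if (is.null(intra_B)) intra_B <- intra_edges(distance_matrix(chainB), cutoff)
  eB <- intra_B
  if (nrow(eB)) { eB$i <- eB$i + nA; eB$j <- eB$j + nA }
  edges <- rbind(intra_A, eB, inter_edges(nA, nB, weight = cutoff))
  structure(
    list(node_features = rbind(embA, embB), edges = edges,
         chain = c(rep("A", nA), rep("B", nB)),
         n_A = nA, n_B = nB),
    class = "pair_graph"
  )
}

#' @export
print.pair_graph <- function(x, ...) {
  cat(sprintf("<pair_graph>  %d + %d nodes, %d directed edges, %d features\n",
              x$n_A, x$n_B, nrow(x$edges), ncol(x$node_features)))
  invisible(x)
}

#' Edges from a predicted contact-probability matrix
#'
#' The sequence-only graph mode replaces distance-derived intra-chain edges
#' with edges between residue pairs whose predicted contact probability
#' exceeds `threshold` (strictly), all at the fixed weight 8 used for
#' fictional edges.
#'
#' @param cpm N x N contact-probability matrix (symmetric, entries in [0,1]).
#' @param threshold Probability threshold in (0, 1), strict ">". Default 0.5.
#' @param weight Edge weight. Default 8.
#' @return Edge data frame (both directions per qualifying pair).
#' @export
contact_map_edges <- function(cpm, threshold = 0.5, weight = 8) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  cpm <- as.matrix(cpm)
  if (any(cpm < 0 | cpm > 1)) stop("contact probabilities must lie in [0, 1]")
  if (max(abs(cpm - t(cpm))) > 1e-6)
    stop("contact-probability matrix must be symmetric")
  sel <- which(upper.tri(cpm) & cpm > threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty_edges())
  data.frame(i = c(sel[, 1], sel[, 2]), j = c(sel[, 2], sel[, 1]),
             w = rep(weight, 2L * nrow(sel)))
}

#' Export an edge list to TSV
#'
#' @param edges Edge data frame (`i`, `j`, `w`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a contact-probability matrix from TSV
#'
#' @param path TSV file holding a square numeric matrix, no header.
#' @return Numeric matrix.
#' @export
read_contact_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("contact map not found: %s", path))
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("contact map must be square")
  m
}
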