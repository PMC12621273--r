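#' Positive-pair filter configuration
#'
#' The dataset rules for positive pairs: strictly more than
#' `min_contacts_exclusive` inter-chain contact pairs and both chain lengths
#' within `[min_len, max_len]` (inclusive).
#'
#' @param min_contacts_exclusive Contact-pair count that must be exceeded.
#'   Default 8.
#' @param min_len,max_len Inclusive sequence-length bounds. Defaults 35, 300.
#' @param cutoff Contact cutoff in Angstrom. Default 8.
#' @param contact_count `"pairs"` (default) counts inter-chain residue
#'   pairs; `"residues"` counts contact residues instead.
#' @return A `pair_filter_config` list.
#' @export
pair_filter_config <- function(min_contacts_exclusive = 8L, min_len = 35L,
                               max_len = 300L, cutoff = 8,
                               contact_count = c("pairs", "residues")) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(min_contacts_exclusive = min_contacts_exclusive,
                 min_len = min_len, max_len = max_len, cutoff = cutoff,
                 contact_count = match.arg(contact_count)),
            class = "pair_filter_config")
}

#' Filter a candidate positive pair
#'
#' @param chainA,chainB `protein_chain` objects.
#' @param cfg A [pair_filter_config()].
#' @return List with `keep` (logical) and `reasons` (character vector naming
#'   each failed criterion: "contacts" and/or "length").
#' @export
filter_positive_pair <- function(chainA, chainB, cfg = pair_filter_config()) {
  cc <- count_contacts(chainA, chainB, cfg$cutoff)
  n <- if (cfg$contact_count == "pairs") cc$n_pairs
       else length(cc$contact_residues)
  reasons <- character()
  if (n <= cfg$min_contacts_exclusive) reasons <- c(reasons, "contacts")
  lens <- c(length(chainA$aa), length(chainB$aa))
  if (any(lens < cfg$min_len | lens > cfg$max_len))
    reasons <- c(reasons, "length")
  list(keep = length(reasons) == 0L, reasons = reasons)
}

canonical_pair <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "\r")

#' Read an exclusion list of known-interacting pairs
#'
#' @param path Two-column TSV of protein identifiers, no header.
#' @return Character vector of canonical unordered pair keys, usable as the
#'   `exclusion` argument of [sample_negatives()].
#' @export
read_exclusion <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  unique(canonical_pair(df[[1]], df[[2]]))
}

as_exclusion_keys <- function(exclusion) {
  if (is.null(exclusion)) return(character())
  if (is.list(exclusion))
    return(unique(vapply(exclusion,
                         function(p) canonical_pair(p[1], p[2]),
                         character(1))))
  exclusion
}

#' Sample random negative pairs
#'
#' Draws `n` distinct unordered protein pairs uniformly from the pool,
#' excluding self-pairs and any pair present in the exclusion list (pairs
#' known or suspected to interact). All admissible pairs are enumerated and
#' sampled without replacement, so draws are exactly uniform and an error
#' reports the achievable maximum when `n` is too large.
#'
#' @param protein_pool Character vector of protein identifiers (>= 2).
#' @param exclusion Exclusion list: a list of length-2 vectors, or canonical
#'   keys from [read_exclusion()], or NULL.
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `p`, `q` (n rows).
#' @export
sample_negatives <- function(protein_pool, exclusion = NULL, n, seed = 1L) {
  protein_pool <- unique(as.character(protein_pool))
  if (length(protein_pool) < 2L) stop("pool must contain at least 2 proteins")
  if (n == 0L) return(data.frame(p = character(), q = character()))
  excl <- as_exclusion_keys(exclusion)
  cmb <- utils::combn(protein_pool, 2L)
  keys <- canonical_pair(cmb[1, ], cmb[2, ])
  ok <- !(keys %in% excl)
  if (sum(ok) < n)
    stop(sprintf("only %d admissible pairs exist but %d were requested",
                 sum(ok), n))
  pick <- with_local_seed(seed, sample(which(ok), n))
  data.frame(p = cmb[1, pick], q = cmb[2, pick], stringsAsFactors = FALSE)
}

#' Build a balanced training manifest
#'
#' Keeps all positive pairs (label 1) and adds an equal number of randomly
#' sampled negative pairs (label 0) drawn from the proteins of the positive
#' set, excluding self-pairs, duplicates and exclusion-list members, then
#' shuffles the rows with the seed.
#'
#' @param positives Data frame with columns `pathA`, `pathB` (each path is
#'   the protein identifier) and optionally `label` (ignored; forced to 1).
#' @param exclusion See [sample_negatives()]. The positive pairs themselves
#'   are always excluded as negatives.
#' @param seed Integer seed.
#' @return Manifest data frame (`pathA`, `pathB`, `label`).
#' @export
build_balanced_manifest <- function(positives, exclusion = NULL, seed = 1L) {
  if (nrow(positives) == 0L) stop("positives must be non-empty")
  pool <- unique(c(positives$pathA, positives$pathB))
  excl <- unique(c(as_exclusion_keys(exclusion),
                   canonical_pair(positives$pathA, positives$pathB)))
  neg <- sample_negatives(pool, excl, n = nrow(positives), seed = seed)
  manifest <- rbind(
    data.frame(pathA = positives$pathA, pathB = positives$pathB, label = 1L,
               stringsAsFactors = FALSE),
    data.frame(pathA = neg$p, pathB = neg$q, label = 0L,
               stringsAsFactors = FALSE))
  manifest[with_local_seed(seed + 1L, sample.int(nrow(manifest))), ,
           drop = FALSE]
}

#' Write a filter report
#'
#' Applies [filter_positive_pair()] to every row of a manifest of candidate
#' positives and writes a TSV report (pair, keep, reasons).
#'
#' @param manifest Data frame with `pathA`, `pathB` (paths to chain PDBs).
#' @param cfg A [pair_filter_config()].
#' @param path Output TSV path.
#' @return The report data frame, invisibly.
#' @export
filter_report <- function(manifest, cfg = pair_filter_config(), path = NULL) {
  rows <- lapply(seq_len(nrow(manifest)), function(k) {
    ca <- read_chains(manifest$pathA[k])[[1]]
    cb <- read_chains(manifest$pathB[k])[[1]]
    fr <- filter_positive_pair(ca, cb, cfg)
    data.frame(pathA = manifest$pathA[k], pathB = manifest$pathB[k],
               keep = fr$keep,
               reasons = paste(fr$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(rep)
}
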