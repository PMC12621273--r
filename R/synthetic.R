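#' Specification of a synthetic two-chain complex
#'
#' Describes one toy complex for the offline test bed: chain lengths,
#' whether the pair interacts, the number of inter-chain contact pairs to
#' plant for positives, consecutive C-alpha spacing, pLDDT regimes, and the
#' interface sequence motif. For positives the interface residues of chain A
#' are drawn from the basic residues {K, R, H} and those of chain B from the
#' acidic residues {D, E}, planting a charge-complementarity signal that a
#' one-hot embedder can exploit; all other residues are uniform over the 20
#' standard letters.
#'
#' @param len_A,len_B Chain lengths (defaults 50).
#' @param interacting Logical label.
#' @param target_contact_pairs Minimum inter-chain contact pairs for a
#'   positive (>= 9 so positives pass the dataset filter). Default 20.
#' @param step Consecutive C-alpha distance in Angstrom. Default 3.8.
#' @param plddt_interface,plddt_background Mean pLDDT of interface and
#'   non-interface residues for positives. Defaults 85 and 70.
#' @param plddt_negative Mean pLDDT for negative complexes. Default 65.
#' @param plddt_sd pLDDT noise standard deviation. Default 8.
#' @param motif Apply the interface sequence motif to positives. Default
#'   TRUE.
#' @param seed Integer seed.
#' @return A `synthetic_complex_spec` list.
#' @export
synthetic_complex_spec <- function(len_A = 50L, len_B = 50L,
                                   interacting = TRUE,
                                   target_contact_pairs = 20L, step = 3.8,
                                   plddt_interface = 85,
                                   plddt_background = 70,
                                   plddt_negative = 65, plddt_sd = 8,
                                   motif = TRUE, seed = 1L) {
  if (interacting && target_contact_pairs < 9L)
    stop("positives need target_contact_pairs >= 9 to pass the pair filter")
  structure(list(len_A = as.integer(len_A), len_B = as.integer(len_B),
                 interacting = isTRUE(interacting),
                 target_contact_pairs = as.integer(target_contact_pairs),
                 step = step, plddt_interface = plddt_interface,
                 plddt_background = plddt_background,
                 plddt_negative = plddt_negative, plddt_sd = plddt_sd,
                 motif = isTRUE(motif), seed = as.integer(seed)),
            class = "synthetic_complex_spec")
}

#' Generate a self-avoiding C-alpha trace
#'
#' Random walk with exact consecutive spacing `step` and every
#' non-consecutive residue pair at least `min_sep` apart; residue identities
#' are uniform over the 20 standard amino acids.
#'
#' @param length Number of residues (>= 1).
#' @param step Consecutive C-alpha distance. Default 3.8.
#' @param seed Integer seed.
#' @param chain_id Chain identifier. Default "A".
#' @param min_sep Minimum non-consecutive separation. Default 2.
#' @return A `protein_chain` (pLDDT initialised to 0).
#' @export
generate_chain <- function(length, step = 3.8, seed = 1L, chain_id = "A",
                           min_sep = 2) {
  stopifnot(length >= 1L)
  with_local_seed(seed, {
    for (restart in seq_len(25L)) {
      coords <- matrix(0, length, 3L)
      ok <- TRUE
      for (i in seq_len(length)[-1]) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          d <- stats::rnorm(3)
          d <- d / sqrt(sum(d^2))
          cand <- coords[i - 1L, ] + step * d
          if (i <= 2L ||
              min(sqrt(colSums((t(coords[seq_len(i - 2L), , drop = FALSE]) -
                                cand)^2))) >= min_sep) {
            coords[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        aa <- sample(AA_ALPHABET, length, replace = TRUE)
        return(protein_chain(chain_id, aa, coords))
      }
    }
    stop("chain placement failed after bounded retries; try another seed")
  })
}

random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

min_cross_dist <- function(a, b) min(cross_dist(a, b))

#' Generate a labeled synthetic complex
#'
#' Positives are built by posing chain B against chain A (random rotations
#' and approach translations) until the planted number of inter-chain
#' contact pairs is met without steric clash; interface residues then
#' receive the sequence motif and the interface pLDDT regime. Negatives are
#' translated apart so that every inter-chain C-alpha distance is at least
#' 12 Angstrom (zero contacts) and receive the lower uniform pLDDT regime.
#'
#' @param spec A [synthetic_complex_spec()].
#' @return List with `chainA`, `chainB` (`protein_chain`s) and `label`
#'   (integer 0/1).
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  chainA <- generate_chain(spec$len_A, spec$step, seed = spec$seed * 2L + 1L,
                           chain_id = "A")
  chainB <- generate_chain(spec$len_B, spec$step, seed = spec$seed * 2L + 2L,
                           chain_id = "B")
  with_local_seed(spec$seed, {
    if (spec$interacting) {
      posed <- NULL
      for (attempt in seq_len(300L)) {
        R <- random_rotation()
        bc <- chainB$coords %*% R
        ia <- sample.int(spec$len_A, 1L)
        ib <- sample.int(spec$len_B, 1L)
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        for (t in seq(7.5, 3, by = -0.5)) {
          shift <- chainA$coords[ia, ] + t * d - bc[ib, ]
          cand <- sweep(bc, 2, shift, "+")
          dm <- cross_dist(chainA$coords, cand)
          if (min(dm) >= 2 && sum(dm < 8) >= spec$target_contact_pairs) {
            posed <- cand
            break
          }
        }
        if (!is.null(posed)) break
      }
      if (is.null(posed))
        stop("could not reach the target contact count; try another seed")
      chainB$coords <- posed
      cc <- count_contacts(chainA, chainB)
      iA <- grep("^A:", cc$contact_residues, value = TRUE)
      iB <- grep("^B:", cc$contact_residues, value = TRUE)
      iA <- as.integer(sub("^A:", "", iA))
      iB <- as.integer(sub("^B:", "", iB))
      if (spec$motif) {
        chainA$aa[iA] <- sample(c("K", "R", "H"), length(iA), replace = TRUE)
        chainB$aa[iB] <- sample(c("D", "E"), length(iB), replace = TRUE)
      }
      pl <- function(n, mean) pmin(100, pmax(0,
        stats::rnorm(n, mean, spec$plddt_sd)))
      chainA$plddt <- pl(spec$len_A, spec$plddt_background)
      chainB$plddt <- pl(spec$len_B, spec$plddt_background)
      chainA$plddt[iA] <- pl(length(iA), spec$plddt_interface)
      chainB$plddt[iB] <- pl(length(iB), spec$plddt_interface)
      list(chainA = chainA, chainB = chainB, label = 1L)
    } else {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      span <- max(cross_dist(chainA$coords, chainB$coords))
      off <- span + 12
      repeat {
        cand <- sweep(chainB$coords, 2, off * d, "+")
        if (min_cross_dist(chainA$coords, cand) >= 12) break
        off <- off + 6
      }
      chainB$coords <- cand
      chainA$plddt <- pmin(100, pmax(0, stats::rnorm(spec$len_A,
        spec$plddt_negative, spec$plddt_sd)))
      chainB$plddt <- pmin(100, pmax(0, stats::rnorm(spec$len_B,
        spec$plddt_negative, spec$plddt_sd)))
      list(chainA = chainA, chainB = chainB, label = 0L)
    }
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_pos + n_neg` two-chain complexes as pairs of single-chain PDB
#' files plus a manifest TSV and a JSON echo of the generator settings.
#' Per-complex seeds are derived from the master seed, so directory contents
#' are fully deterministic.
#'
#' @param n_pos,n_neg Numbers of interacting / non-interacting complexes.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param len_range Inclusive range chain lengths are drawn from.
#'   Default c(40, 60).
#' @param ... Further arguments passed to [synthetic_complex_spec()].
#' @return The manifest data frame (`pathA`, `pathB`, `label`), invisibly;
#'   also written to `<out_dir>/manifest.tsv`.
#' @export
generate_dataset <- function(n_pos, n_neg, out_dir, seed = 1L,
                             len_range = c(40L, 60L), ...) {
  stopifnot(n_pos >= 0L, n_neg >= 0L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    si <- (as.numeric(seed) * 100003 + i * 7907) %% 2147483647
    lens <- with_local_seed(si + 1,
      sample(seq(len_range[1], len_range[2]), 2L, replace = TRUE))
    spec <- synthetic_complex_spec(len_A = lens[1], len_B = lens[2],
                                   interacting = labels[i] == 1L,
                                   seed = as.integer(si), ...)
    cx <- generate_complex(spec)
    pa <- file.path(out_dir, sprintf("pair%04d_A.pdb", i))
    pb <- file.path(out_dir, sprintf("pair%04d_B.pdb", i))
    write_chain(cx$chainA, pa)
    write_chain(cx$chainB, pb)
    rows[[i]] <- data.frame(pathA = pa, pathB = pb, label = cx$label,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(pathA = character(), pathB = character(),
                              label = integer())
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  jsonlite::write_json(
    c(list(n_pos = n_pos, n_neg = n_neg, seed = seed,
           len_range = len_range),
      list(...)),
    file.path(out_dir, "dataset_spec.json"), auto_unbox = TRUE)
  invisible(manifest)
}
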