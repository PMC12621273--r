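#' pDockQ sigmoid constants
#'
#' The published calibration of the pDockQ score:
#' `pDockQ = L_max / (1 + exp(-k (x - x0))) + b` with
#' `x = if_plddt * ln(n_contacts)`. `L_max` is the sigmoid ceiling (named to
#' avoid collision with the embedding dimension L).
#'
#' @param L_max Sigmoid amplitude. Default 0.724.
#' @param x0 Sigmoid midpoint. Default 152.611.
#' @param k Sigmoid steepness. Default 0.052.
#' @param b Baseline offset. Default 0.018.
#' @return A `pdockq_params` list.
#' @export
pdockq_params <- function(L_max = 0.724, x0 = 152.611, k = 0.052, b = 0.018) {
  structure(list(L_max = L_max, x0 = x0, k = k, b = b),
            class = "pdockq_params")
}

#' Evaluate the pDockQ sigmoid
#'
#' @param if_plddt Mean pLDDT of the interface residues.
#' @param n_contacts Number of contacted residues; 0 returns the floor `b`.
#' @param params A [pdockq_params()].
#' @return The pDockQ score.
#' @export
pdockq_score <- function(if_plddt, n_contacts, params = pdockq_params()) {
  if (n_contacts == 0) return(params$b)
  x <- if_plddt * log(n_contacts)
  params$L_max / (1 + exp(-params$k * (x - params$x0))) + params$b
}

#' Interface summary and pDockQ of a two-chain complex
#'
#' Finds the inter-chain contact residues (C-alpha pairs below `cutoff`,
#' strictly), averages their pLDDT, and evaluates the pDockQ sigmoid on
#' `x = if_plddt * ln(n_contacts)` (natural logarithm). `n_contacts` counts
#' contact residues (the union over both chains) by default; set
#' `count = "pairs"` to count contact pairs instead. With zero contacts the
#' score is the analytic floor `b` and `x` is undefined.
#'
#' @param chainA,chainB `protein_chain` objects carrying pLDDT values.
#' @param cutoff Contact cutoff in Angstrom. Default 8.
#' @param params A [pdockq_params()].
#' @param count `"residues"` (default) or `"pairs"`.
#' @return An `interface_summary` list: `n_contacts`, `if_plddt`, `x`,
#'   `pdockq`.
#' @export
interface_summary <- function(chainA, chainB, cutoff = 8,
                              params = pdockq_params(),
                              count = c("residues", "pairs")) {
  count <- match.arg(count)
  if (identical(chainA$chain_id, chainB$chain_id)) {
    # disambiguate contact-residue labels when both chains share an id
    chainA$chain_id <- "A"; chainB$chain_id <- "B"
  }
  cc <- count_contacts(chainA, chainB, cutoff)
  res <- cc$contact_residues
  if (length(res) == 0L) {
    return(structure(list(n_contacts = 0L, if_plddt = NA_real_,
                          x = NA_real_, pdockq = params$b),
                     class = "interface_summary"))
  }
  plddt_all <- c(chainA$plddt, chainB$plddt)
  nA <- length(chainA$plddt)
  idx <- vapply(strsplit(res, ":", fixed = TRUE), function(p) {
    i <- as.integer(p[2])
    if (p[1] == chainA$chain_id) i else nA + i
  }, integer(1))
  if (all(plddt_all == 0))
    warning("all pLDDT values are zero; the B-factor column may be missing")
  if_plddt <- mean(plddt_all[idx])
  n_contacts <- if (count == "pairs") cc$n_pairs else length(res)
  structure(list(n_contacts = as.integer(n_contacts), if_plddt = if_plddt,
                 x = if_plddt * log(n_contacts),
                 pdockq = pdockq_score(if_plddt, n_contacts, params)),
            class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  cat(sprintf("pDockQ %.3f  (n_contacts = %d, if_plddt = %s)\n",
              x$pdockq, x$n_contacts,
              if (is.na(x$if_plddt)) "NA" else sprintf("%.1f", x$if_plddt)))
  invisible(x)
}

#' Classify pDockQ scores
#'
#' The published decision threshold is the empirical 0.23 (0.21 was optimal
#' on the authors' own data); scores at or above the threshold are called
#' interacting.
#'
#' @param scores Numeric pDockQ scores.
#' @param threshold Decision threshold. Default 0.23.
#' @return Integer vector of 0/1 labels.
#' @export
pdockq_classify <- function(scores, threshold = 0.23) {
  as.integer(scores >= threshold)
}
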