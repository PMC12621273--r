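# shared fixtures and independent oracles

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random chain with arbitrary (not walk-constrained) coordinates
random_chain <- function(n, id = "A", seed = 1, spread = 10) {
  set.seed(seed)
  protein_chain(id, sample(AA20, n, replace = TRUE),
                matrix(rnorm(n * 3, sd = spread), n, 3),
                runif(n, 40, 95))
}

# brute-force double-loop distance matrix
brute_distance_matrix <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      m[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  m
}

# brute-force inter-chain contact count and residue set
brute_contacts <- function(chainA, chainB, cutoff = 8) {
  n_pairs <- 0L
  ra <- integer(); rb <- integer()
  for (i in seq_along(chainA$aa))
    for (j in seq_along(chainB$aa)) {
      d <- sqrt(sum((chainA$coords[i, ] - chainB$coords[j, ])^2))
      if (d < cutoff) {
        n_pairs <- n_pairs + 1L
        ra <- union(ra, i); rb <- union(rb, j)
      }
    }
  list(n_pairs = n_pairs,
       contact_residues = c(paste0(chainA$chain_id, ":", sort(ra)),
                            paste0(chainB$chain_id, ":", sort(rb))))
}

# dense per-node, per-head reference implementation of the attention layer
brute_gat_layer <- function(h, edges, layer, config) {
  n <- nrow(h)
  fo <- layer$f_out
  E <- rbind(cbind(edges$i, edges$j), cbind(seq_len(n), seq_len(n)))
  w <- c(edges$w, rep(8, n))
  out <- matrix(0, n, fo)
  attn <- vector("list", config$n_heads)
  for (hd in seq_len(config$n_heads)) {
    W <- layer$W[, (hd - 1) * fo + seq_len(fo), drop = FALSE]
    a <- layer$a[, hd]
    attn[[hd]] <- matrix(0, n, n)
    for (i in seq_len(n)) {
      sel <- which(E[, 1] == i)
      z <- vapply(sel, function(e) {
        u <- c(as.vector(h[i, ] %*% W), as.vector(h[E[e, 2], ] %*% W))
        if (config$edge_weight_mode == "append") u <- c(u, w[e] / 8)
        v <- sum(a * u)
        if (v > 0) v else config$leaky_slope * v
      }, numeric(1))
      al <- exp(z - max(z)); al <- al / sum(al)
      acc <- rep(0, fo)
      for (k in seq_along(sel)) {
        acc <- acc + al[k] * as.vector(h[E[sel[k], 2], ] %*% W)
        attn[[hd]][i, E[sel[k], 2]] <- attn[[hd]][i, E[sel[k], 2]] + al[k]
      }
      out[i, ] <- out[i, ] + acc
    }
  }
  list(out = out / config$n_heads, attn = attn)
}

# trapezoidal AUROC from an explicit threshold sweep (independent of the
# rank-based implementation)
trapezoid_auroc <- function(labels, scores) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# pairwise Mann-Whitney AUROC oracle
pairwise_auroc <- function(labels, scores) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# step-sum average precision oracle via explicit threshold sweep
sweep_ap <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_r <- 0; ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    r <- tp / P
    pr <- tp / sum(pred)
    ap <- ap + (r - prev_r) * pr
    prev_r <- r
  }
  ap
}

# random small node-feature matrix + symmetric weighted edge list
small_graph <- function(seed, n = 7, dim_L = 8, edge_p = 0.4) {
  set.seed(seed)
  h <- matrix(rnorm(n * dim_L), n, dim_L)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pairs[runif(nrow(pairs)) < edge_p, , drop = FALSE]
  w <- runif(nrow(keep), 2, 8)
  edges <- data.frame(i = c(keep[, 1], keep[, 2]),
                      j = c(keep[, 2], keep[, 1]), w = c(w, w))
  list(h = h, edges = edges)
}

# two small posed chains with a known interface
toy_pair <- function(seed = 1) {
  cx <- generate_complex(synthetic_complex_spec(len_A = 40, len_B = 40,
                                                seed = seed))
  cx
}

toy_graph <- function(seed = 1, dim_L = 32) {
  cx <- toy_pair(seed)
  emb <- get_embedder("onehot", dim_L)
  build_pair_graph(cx$chainA, cx$chainB,
                   emb$embed(chain_sequence(cx$chainA)),
                   emb$embed(chain_sequence(cx$chainB)))
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  q <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(chain, motion) {
  chain$coords <- sweep(chain$coords %*% motion$R, 2, motion$t, "+")
  chain
}
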