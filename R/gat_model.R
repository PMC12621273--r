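#' Model configuration
#'
#' Architecture hyperparameters of the graph-attention classifier. The four
#' hidden dimensions form a U-shape `[L/2, L/4, L/2, L]` derived from the
#' embedding dimension `dim_L`, each layer runs `n_heads` attention heads
#' whose outputs are averaged, and batch normalisation (followed by the
#' inter-layer activation) is applied between the attention layers.
#'
#' @param dim_L Embedding dimension (node-feature width); must be divisible
#'   by 4 so the U-shaped dimensions are integers. Default 32.
#' @param n_heads Attention heads per layer. Default 4.
#' @param hidden_dims Optional explicit output dims of the four layers;
#'   default `c(L/2, L/4, L/2, L)`.
#' @param edge_weight_mode How edge weights enter the attention logits:
#'   `"append"` (default) appends the scalar `w/8` to the concatenated
#'   transformed features before the attention dot product; `"none"` is the
#'   vanilla attention with no edge term.
#' @param leaky_slope Negative slope of the LeakyReLU inside the attention
#'   logits. Default 0.2.
#' @param activation Inter-layer activation applied after batch
#'   normalisation on layers 1-3: `"elu"` (default) or `"none"`.
#' @param batch_norm Whether to batch-normalise between layers. Default TRUE.
#' @return A `gat_config` list.
#' @export
gat_config <- function(dim_L = 32L, n_heads = 4L, hidden_dims = NULL,
                       edge_weight_mode = c("append", "none"),
                       leaky_slope = 0.2,
                       activation = c("elu", "none"),
                       batch_norm = TRUE) {
  edge_weight_mode <- match.arg(edge_weight_mode)
  activation <- match.arg(activation)
  dim_L <- as.integer(dim_L)
  if (is.null(hidden_dims)) {
    if (dim_L %% 4L != 0L)
      stop("dim_L must be divisible by 4 for the default U-shaped dims")
    hidden_dims <- c(dim_L %/% 2L, dim_L %/% 4L, dim_L %/% 2L, dim_L)
  }
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) != 4L) stop("hidden_dims must have length 4")
  structure(
    list(dim_L = dim_L, n_heads = as.integer(n_heads),
         hidden_dims = hidden_dims, edge_weight_mode = edge_weight_mode,
         leaky_slope = leaky_slope, activation = activation,
         batch_norm = isTRUE(batch_norm)),
    class = "gat_config"
  )
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Attention-layer weights use Glorot-uniform initialisation; the fully
#' connected head is zero-initialised so the untrained classifier outputs
#' exactly probability 0.5 and early optimisation is driven by the loss
#' gradient rather than by head-initialisation noise (the attention layers
#' behind it are random, so no symmetry is created).
#'
#' @param config A [gat_config()].
#' @param seed Integer seed.
#' @return A `gat_params` list (layers, batch-norm state, fc head).
#' @export
gat_init <- function(config, seed = 1L) {
  with_local_seed(seed, {
    L <- config$dim_L
    dims <- c(L, config$hidden_dims)
    Hh <- config$n_heads
    ew <- if (config$edge_weight_mode == "append") 1L else 0L
    layers <- lapply(seq_len(4L), function(l) {
      fi <- dims[l]; fo <- dims[l + 1L]
      W <- do.call(cbind, lapply(seq_len(Hh), function(h) glorot(fi, fo)))
      a <- glorot(2L * fo + ew, Hh)
      list(W = W, a = a, f_in = fi, f_out = fo)
    })
    bn <- lapply(seq_len(3L), function(l) {
      d <- config$hidden_dims[l]
      list(gamma = rep(1, d), beta = rep(0, d),
           rmean = rep(0, d), rvar = rep(1, d))
    })
    fc <- list(w = rep(0, 4L * L), b = 0)
    structure(list(layers = layers, bn = bn, fc = fc, config = config),
              class = "gat_params")
  })
}

# directed edges incl. self-loops at the neutral fictional weight 8, plus
# sparse node-aggregation operators over edge targets / sources (built once
# per graph and reused by every layer and the backward pass)
edges_with_self_loops <- function(edges, n_nodes, self_weight = 8) {
  tgt <- c(edges$i, seq_len(n_nodes))
  src <- c(edges$j, seq_len(n_nodes))
  ne <- length(tgt)
  list(tgt = tgt, src = src,
       w = c(edges$w, rep(self_weight, n_nodes)), ne = ne,
       agg_tgt = Matrix::sparseMatrix(i = tgt, j = seq_len(ne), x = 1,
                                      dims = c(n_nodes, ne)),
       agg_src = Matrix::sparseMatrix(i = src, j = seq_len(ne), x = 1,
                                      dims = c(n_nodes, ne)))
}

# sum edge values into nodes: sparse aggregator %*% dense block
agg <- function(A, x) {
  y <- A %*% x
  matrix(y@x, nrow = y@Dim[1L])
}

# fast column-wise ops (sweep without the aperm overhead)
cmul <- function(x, v) x * rep(v, each = nrow(x))
cadd <- function(x, v) x + rep(v, each = nrow(x))

# per-(target node, head) max of logits, for a numerically stable softmax
group_max <- function(z, tgt, n_nodes) {
  H <- ncol(z)
  out <- matrix(0, n_nodes, H)
  for (h in seq_len(H)) {
    o <- order(tgt, z[, h])
    st <- tgt[o]
    last <- o[c(st[-1L] != st[-length(st)], TRUE)]
    out[tgt[last], h] <- z[last, h]
  }
  out
}

#' One graph-attention layer, forward
#'
#' Implements multi-head graph attention: per head, node features are
#' linearly transformed, attention logits for every directed edge (including
#' an internally added self-loop per node) are formed as
#' `LeakyReLU(a^T [W h_i || W h_j || w_ij/8])` (the edge-weight term only in
#' `"append"` mode), normalised by a softmax over each node's in-neighbours,
#' and used to average the transformed neighbour features. Head outputs are
#' averaged.
#'
#' @param h N x F_in node-feature matrix.
#' @param edges Edge data frame (`i`, `j`, `w`); `i` attends over `j`.
#' @param layer One element of `gat_params$layers`.
#' @param config The [gat_config()].
#' @param keep_cache Keep intermediates for backpropagation.
#' @param keep_attn Build the per-head attention maps (skipped in training
#'   for speed).
#' @return List with `out` (N x F_out), `attn` (per-head list of data frames
#'   `i`, `j`, `alpha`, or NULL when `keep_attn = FALSE`), and optionally
#'   `cache`.
#' @export
gat_layer_forward <- function(h, edges, layer, config, keep_cache = FALSE,
                              keep_attn = TRUE, es = NULL) {
  n <- nrow(h)
  if (is.null(n) || n == 0L) stop("empty node-feature matrix")
  if (!all(is.finite(h))) stop("non-finite node features")
  if (nrow(edges) && (max(edges$i, edges$j) > n || min(edges$i, edges$j) < 1L))
    stop("edge list references invalid node ids")
  Hh <- config$n_heads
  fo <- layer$f_out
  if (is.null(es)) es <- edges_with_self_loops(edges, n)
  tgt <- es$tgt; src <- es$src
  wn <- es$w / 8
  ne <- es$ne
  G <- h %*% layer$W                       # N x (fo*H), head-major blocks
  ew <- config$edge_weight_mode == "append"
  A1 <- layer$a[seq_len(fo), , drop = FALSE]           # (fo x H)
  A2 <- layer$a[fo + seq_len(fo), , drop = FALSE]
  head_cols <- lapply(seq_len(Hh), function(hd) (hd - 1L) * fo + seq_len(fo))
  # attention logits, per head: E x H
  Z <- matrix(0, ne, Hh)
  Gjh <- vector("list", Hh)
  for (hd in seq_len(Hh)) {
    cols <- head_cols[[hd]]
    Gjh[[hd]] <- G[src, cols, drop = FALSE]
    Z[, hd] <- G[tgt, cols, drop = FALSE] %*% A1[, hd] +
      Gjh[[hd]] %*% A2[, hd]
  }
  if (ew) Z <- Z + outer(wn, layer$a[2L * fo + 1L, ])
  neg <- Z < 0
  Zl <- Z
  Zl[neg] <- config$leaky_slope * Z[neg]
  mx <- group_max(Zl, tgt, n)
  P <- exp(Zl - mx[tgt, , drop = FALSE])
  S <- agg(es$agg_tgt, P)                               # N x H
  alpha <- P / S[tgt, , drop = FALSE]
  out <- matrix(0, n, fo)
  for (hd in seq_len(Hh)) out <- out + agg(es$agg_tgt, alpha[, hd] * Gjh[[hd]])
  out <- out / Hh
  attn <- if (keep_attn)
    lapply(seq_len(Hh), function(hd)
      data.frame(i = tgt, j = src, alpha = alpha[, hd]))
  res <- list(out = out, attn = attn)
  if (keep_cache)
    res$cache <- list(h = h, G = G, es = es, wn = wn, Gjh = Gjh,
                      neg = neg, alpha = alpha, n = n, ne = ne,
                      head_cols = head_cols, A1 = A1, A2 = A2,
                      ew = ew, fo = fo, Hh = Hh)
  res
}

# backward through one attention layer; returns grads for W, a and the input.
# The attention-vector contributions to node gradients are rank-1 per head
# (edge gradients grouped by node, outer with a), avoiding E x (F*H)
# intermediates.
gat_layer_backward <- function(dout, layer, config, cache) {
  Hh <- cache$Hh; fo <- cache$fo
  es <- cache$es
  tgt <- es$tgt; src <- es$src
  G <- cache$G; alpha <- cache$alpha
  dout_e <- (dout / Hh)[tgt, , drop = FALSE]            # E x fo, shared
  dG <- matrix(0, cache$n, fo * Hh)
  da <- matrix(0, nrow(layer$a), Hh)
  dalpha <- matrix(0, cache$ne, Hh)
  for (hd in seq_len(Hh))
    dalpha[, hd] <- rowSums(dout_e * cache$Gjh[[hd]])
  # softmax then LeakyReLU backward
  sm <- agg(es$agg_tgt, alpha * dalpha)                 # N x H
  dZ <- alpha * (dalpha - sm[tgt, , drop = FALSE])
  dZ[cache$neg] <- config$leaky_slope * dZ[cache$neg]
  rt_all <- agg(es$agg_tgt, dZ)                         # N x H
  rs_all <- agg(es$agg_src, dZ)
  for (hd in seq_len(Hh)) {
    cols <- cache$head_cols[[hd]]
    rt <- rt_all[, hd]
    rs <- rs_all[, hd]
    Gh <- G[, cols, drop = FALSE]
    da[seq_len(fo), hd] <- crossprod(Gh, rt)
    da[fo + seq_len(fo), hd] <- crossprod(Gh, rs)
    dG[, cols] <- agg(es$agg_src, alpha[, hd] * dout_e) +
      tcrossprod(rt, cache$A1[, hd]) + tcrossprod(rs, cache$A2[, hd])
  }
  if (cache$ew) da[2L * fo + 1L, ] <- colSums(dZ * cache$wn)
  list(dW = crossprod(cache$h, dG), da = da,
       dh = tcrossprod(dG, layer$W))
}

bn_forward <- function(x, bn, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    xc <- cadd(x, -mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + eps)
    xhat <- cmul(xc, istd)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v
    cache <- list(xhat = xhat, istd = istd, xc = xc)
  } else {
    xhat <- cmul(cadd(x, -bn$rmean), 1 / sqrt(bn$rvar + eps))
    cache <- NULL
  }
  y <- cadd(cmul(xhat, bn$gamma), bn$beta)
  list(y = y, bn = bn, cache = cache)
}

bn_backward <- function(dy, bn, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- cmul(dy, bn$gamma)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dx <- cadd(dxhat, -t1 / n) - cmul(cache$xhat, t2 / n)
  dx <- cmul(dx, cache$istd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

elu_forward <- function(x) {
  neg <- x < 0
  y <- x
  y[neg] <- exp(x[neg]) - 1
  list(y = y, neg = neg)
}

elu_backward <- function(dy, y, neg) {
  dx <- dy
  dx[neg] <- dy[neg] * (y[neg] + 1)
  dx
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Full model forward pass
#'
#' Runs the four attention layers (with batch normalisation and the
#' inter-layer activation after layers 1-3), concatenates the final node
#' features with the input embeddings, applies chain mean pooling (global
#' mean per chain, then concatenation, giving a 4L graph feature), and maps
#' through the fully connected head and a sigmoid to an interaction
#' probability.
#'
#' @param graph A `pair_graph`.
#' @param params A `gat_params`.
#' @param training Use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch normalisation; training mode also updates the running
#'   statistics and keeps the backward cache.
#' @param keep_attn Build the per-layer, per-head attention maps. Default
#'   TRUE; the training loop disables it for speed.
#' @return List with `prob`, `attn` (per-layer, per-head attention maps),
#'   and in training mode `cache` and the updated `params` (running
#'   batch-norm statistics).
#' @export
gat_forward <- function(graph, params, training = FALSE,
                        keep_attn = !training, es = NULL) {
  config <- params$config
  x0 <- graph$node_features
  if (ncol(x0) != config$dim_L)
    stop(sprintf("graph features have dim %d but the model expects %d",
                 ncol(x0), config$dim_L))
  x <- x0
  attn <- vector("list", 4L)
  caches <- if (training) vector("list", 4L) else NULL
  if (is.null(es)) es <- edges_with_self_loops(graph$edges, nrow(x0))
  for (l in seq_len(4L)) {
    lf <- gat_layer_forward(x, graph$edges, params$layers[[l]], config,
                            keep_cache = training, keep_attn = keep_attn,
                            es = es)
    attn[[l]] <- lf$attn
    x <- lf$out
    cc <- list(gat = lf$cache)
    if (l <= 3L) {
      if (config$batch_norm) {
        bf <- bn_forward(x, params$bn[[l]], training)
        params$bn[[l]] <- bf$bn
        cc$bn <- bf$cache
        x <- bf$y
      }
      if (config$activation == "elu") {
        ef <- elu_forward(x)
        cc$elu_neg <- ef$neg
        x <- ef$y
        cc$elu_y <- x
      }
    }
    if (training) caches[[l]] <- cc
  }
  xc <- cbind(x, x0)                       # per-node [x4 || x0], dim 2L
  isA <- graph$chain == "A"
  pooled <- c(colMeans(xc[isA, , drop = FALSE]),
              colMeans(xc[!isA, , drop = FALSE]))
  logit <- sum(params$fc$w * pooled) + params$fc$b
  prob <- sigmoid(logit)
  res <- list(prob = prob, attn = attn)
  if (training) {
    res$cache <- list(caches = caches, pooled = pooled, isA = isA,
                      n = nrow(x0), L = config$dim_L, prob = prob)
    res$params <- params
  }
  res
}

# backward from dloss/dlogit; returns gradient structure mirroring params
gat_backward <- function(dlogit, params, cache) {
  config <- params$config
  L <- cache$L
  n <- cache$n
  grads <- list(layers = vector("list", 4L), bn = vector("list", 3L),
                fc = list(w = dlogit * cache$pooled, b = dlogit))
  dpool <- dlogit * params$fc$w
  dxc <- matrix(0, n, 2L * L)
  nA <- sum(cache$isA); nB <- n - nA
  dxc[cache$isA, ] <- rep(dpool[seq_len(2L * L)] / nA, each = nA)
  dxc[!cache$isA, ] <- rep(dpool[2L * L + seq_len(2L * L)] / nB, each = nB)
  dx <- dxc[, seq_len(L), drop = FALSE]
  dx0_skip <- dxc[, L + seq_len(L), drop = FALSE]
  for (l in 4:1) {
    cc <- cache$caches[[l]]
    if (l <= 3L) {
      if (config$activation == "elu")
        dx <- elu_backward(dx, cc$elu_y, cc$elu_neg)
      if (config$batch_norm) {
        bb <- bn_backward(dx, params$bn[[l]], cc$bn)
        grads$bn[[l]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
        dx <- bb$dx
      }
    }
    lb <- gat_layer_backward(dx, params$layers[[l]], config, cc$gat)
    grads$layers[[l]] <- list(W = lb$dW, a = lb$da)
    dx <- lb$dh
  }
  grads$dx0 <- dx + dx0_skip
  grads
}

#' Extract attention weights as dense matrices
#'
#' Runs the forward pass and returns, for each of the four layers and each
#' head, an N x N matrix with the attention weight alpha_ij at position
#' (i, j) for every directed edge j -> i (self-loops included) and 0
#' elsewhere. With the chain-A-then-B node ordering the four quadrants are
#' the A-intra, B-intra and the two inter-chain blocks.
#'
#' @param graph A `pair_graph`.
#' @param params A `gat_params`.
#' @param out_dir Optional directory; when given, each matrix is written to
#'   `attention_layer<l>_head<h>.tsv`.
#' @return List `[[layer]][[head]]` of N x N matrices (plus `prob`).
#' @export
extract_attention <- function(graph, params, out_dir = NULL) {
  fw <- gat_forward(graph, params, training = FALSE)
  n <- nrow(graph$node_features)
  mats <- lapply(fw$attn, function(per_layer)
    lapply(per_layer, function(df) {
      m <- matrix(0, n, n)
      m[cbind(df$i, df$j)] <- df$alpha
      m
    }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (l in seq_along(mats))
      for (h in seq_along(mats[[l]]))
        utils::write.table(
          mats[[l]][[h]],
          file.path(out_dir, sprintf("attention_layer%d_head%d.tsv", l, h)),
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(matrices = mats, prob = fw$prob)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the parameters with the
#' model configuration embedded.
#'
#' @param params A `gat_params`.
#' @param path Checkpoint path.
#' @return `path` (save) or the `gat_params` (load).
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "gat_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  params <- readRDS(path)
  if (!inherits(params, "gat_params")) stop("not a model checkpoint")
  params
}
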