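#' Training configuration
#'
#' Defaults follow the published recipe: binary cross-entropy loss, Adam at
#' learning rate 1e-4, 10 epochs, batch size 8 with gradient accumulation
#' over 4 batches (effective batch size 32).
#'
#' @param learning_rate Adam learning rate. Default 1e-4.
#' @param epochs Training epochs. Default 10.
#' @param batch_size Pairs per batch. Default 8.
#' @param accumulation_steps Batches accumulated per optimizer update.
#'   Default 4.
#' @param seed Seed controlling initialisation and per-epoch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 10L, batch_size = 8L,
                         accumulation_steps = 4L, seed = 1L) {
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 accumulation_steps = as.integer(accumulation_steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Read / write a pair manifest
#'
#' Manifests are TSV files with a header and columns `pathA`, `pathB`,
#' `label` (and optionally `contactsA`, `contactsB` pointing at predicted
#' contact-probability matrices for the sequence-only graph mode).
#'
#' @param path Manifest path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("pathA", "pathB", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns pathA, pathB, label")
  df
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# build the pair graph for one manifest row
manifest_graph <- function(row, embedder, graph_mode = "structure") {
  ca <- tryCatch(read_chains(row$pathA)[[1]],
                 error = function(e) stop(sprintf(
                   "pair (%s, %s): %s", row$pathA, row$pathB,
                   conditionMessage(e))))
  cb <- tryCatch(read_chains(row$pathB)[[1]],
                 error = function(e) stop(sprintf(
                   "pair (%s, %s): %s", row$pathA, row$pathB,
                   conditionMessage(e))))
  embA <- embedder$embed(chain_sequence(ca), row$pathA)
  embB <- embedder$embed(chain_sequence(cb), row$pathB)
  if (graph_mode == "esm2ac") {
    for (col in c("contactsA", "contactsB"))
      if (is.null(row[[col]]) || is.na(row[[col]]) || !nzchar(row[[col]]))
        stop(sprintf("contact-map graph mode needs %s for chain file %s",
                     col, row$pathA))
    iA <- contact_map_edges(read_contact_map(row$contactsA))
    iB <- contact_map_edges(read_contact_map(row$contactsB))
    build_pair_graph(ca, cb, embA, embB, intra_A = iA, intra_B = iB)
  } else {
    build_pair_graph(ca, cb, embA, embB)
  }
}

manifest_graphs <- function(manifest, embedder, graph_mode = "structure") {
  lapply(seq_len(nrow(manifest)), function(k)
    manifest_graph(manifest[k, , drop = FALSE], embedder, graph_mode))
}

# ---- Adam over the nested parameter structure -------------------------------

trainable_paths <- function(params) {
  out <- list()
  for (l in seq_along(params$layers))
    for (nm in c("W", "a")) out[[length(out) + 1L]] <- c("layers", l, nm)
  if (params$config$batch_norm)
    for (l in seq_along(params$bn))
      for (nm in c("gamma", "beta")) out[[length(out) + 1L]] <- c("bn", l, nm)
  for (nm in c("w", "b")) out[[length(out) + 1L]] <- c("fc", nm)
  out
}

get_path <- function(x, p) {
  for (k in p) x <- x[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
  x
}

set_path <- function(x, p, value) {
  k <- p[1]
  k <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
  if (length(p) == 1L) x[[k]] <- value
  else x[[k]] <- set_path(x[[k]], p[-1], value)
  x
}

# gradient path in the grads structure (bn grads live under gamma/beta too)
adam_init <- function(params) {
  paths <- trainable_paths(params)
  list(paths = paths,
       m = lapply(paths, function(p) get_path(params, p) * 0),
       v = lapply(paths, function(p) get_path(params, p) * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in seq_along(state$paths)) {
    p <- state$paths[[k]]
    g <- get_path(grads, p)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params <- set_path(params, p,
                       get_path(params, p) - lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

grad_zero <- function(params) {
  g <- list(layers = lapply(params$layers,
                            function(l) list(W = l$W * 0, a = l$a * 0)),
            fc = list(w = params$fc$w * 0, b = 0))
  if (params$config$batch_norm)
    g$bn <- lapply(params$bn, function(b)
      list(gamma = b$gamma * 0, beta = b$beta * 0))
  g
}

grad_accumulate <- function(acc, g) {
  for (l in seq_along(acc$layers)) {
    acc$layers[[l]]$W <- acc$layers[[l]]$W + g$layers[[l]]$W
    acc$layers[[l]]$a <- acc$layers[[l]]$a + g$layers[[l]]$a
  }
  if (!is.null(acc$bn))
    for (l in seq_along(acc$bn)) {
      acc$bn[[l]]$gamma <- acc$bn[[l]]$gamma + g$bn[[l]]$gamma
      acc$bn[[l]]$beta <- acc$bn[[l]]$beta + g$bn[[l]]$beta
    }
  acc$fc$w <- acc$fc$w + g$fc$w
  acc$fc$b <- acc$fc$b + g$fc$b
  acc
}

# ---- training loop ----------------------------------------------------------

#' Train the graph-attention classifier
#'
#' Optimises binary cross-entropy with Adam, shuffling the pairs each epoch
#' with the configured seed and accumulating gradients over
#' `accumulation_steps` batches before each optimizer update, so the number
#' of updates per epoch is `floor(n_batches / accumulation_steps)`.
#'
#' @param manifest Data frame with columns `pathA`, `pathB`, `label`.
#' @param model_config A [gat_config()].
#' @param tconf A [train_config()].
#' @param embedder An embedder from [get_embedder()].
#' @param graph_mode `"structure"` (distance-derived intra-chain edges) or
#'   `"esm2ac"` (edges from predicted contact-probability matrices).
#' @param graphs Optional precomputed list of pair graphs (skips file I/O).
#' @param verbose Print per-update losses.
#' @return List with `params` (trained `gat_params`) and `history` (data
#'   frame `step`, `epoch`, `loss`; one row per optimizer update).
#' @export
train <- function(manifest, model_config, tconf = train_config(),
                  embedder = get_embedder("onehot", model_config$dim_L),
                  graph_mode = c("structure", "esm2ac"),
                  graphs = NULL, verbose = FALSE) {
  graph_mode <- match.arg(graph_mode)
  if (nrow(manifest) == 0L) stop("manifest is empty")
  labels <- as.numeric(manifest$label)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(unique(labels)) < 2L)
    warning("manifest contains a single class; training proceeds")
  if (is.null(graphs)) graphs <- manifest_graphs(manifest, embedder, graph_mode)
  ess <- lapply(graphs, function(g)
    edges_with_self_loops(g$edges, nrow(g$node_features)))
  params <- gat_init(model_config, seed = tconf$seed)
  state <- adam_init(params)
  n <- nrow(manifest)
  bs <- tconf$batch_size
  acc_steps <- tconf$accumulation_steps
  history <- list()
  for (epoch in seq_len(tconf$epochs)) {
    ord <- with_local_seed(tconf$seed + 7919L * epoch, sample.int(n))
    n_batches <- ceiling(n / bs)
    batch_of <- function(b) ord[((b - 1L) * bs + 1L):min(b * bs, n)]
    n_updates <- n_batches %/% acc_steps
    for (u in seq_len(n_updates)) {
      idx <- unlist(lapply(((u - 1L) * acc_steps + 1L):(u * acc_steps),
                           batch_of))
      m <- length(idx)
      acc <- grad_zero(params)
      loss <- 0
      for (k in idx) {
        fw <- gat_forward(graphs[[k]], params, training = TRUE,
                          es = ess[[k]])
        params <- fw$params           # running batch-norm statistics
        p <- min(max(fw$prob, 1e-12), 1 - 1e-12)
        y <- labels[k]
        loss <- loss - (y * log(p) + (1 - y) * log(1 - p)) / m
        g <- gat_backward((fw$prob - y) / m, params, fw$cache)
        acc <- grad_accumulate(acc, g)
      }
      st <- adam_step(params, acc, state, tconf$learning_rate)
      params <- st$params
      state <- st$state
      history[[length(history) + 1L]] <-
        data.frame(step = state$t, epoch = epoch, loss = loss)
      if (verbose)
        message(sprintf("epoch %d update %d loss %.4f", epoch, state$t, loss))
    }
  }
  list(params = params,
       history = if (length(history)) do.call(rbind, history)
                 else data.frame(step = integer(), epoch = integer(),
                                 loss = numeric()))
}

#' Predict interaction probabilities for a manifest of pairs
#'
#' @param manifest Data frame with `pathA`, `pathB` (and contact-map columns
#'   in `"esm2ac"` mode).
#' @param params Trained `gat_params`.
#' @param embedder Embedder from [get_embedder()]; its dimension must match
#'   the model.
#' @param graph_mode Intra-chain edge source; see [train()].
#' @param graphs Optional precomputed pair graphs.
#' @return Numeric vector of probabilities, one per row, order-preserving.
#' @export
predict_pairs <- function(manifest, params,
                          embedder = get_embedder("onehot",
                                                  params$config$dim_L),
                          graph_mode = c("structure", "esm2ac"),
                          graphs = NULL) {
  graph_mode <- match.arg(graph_mode)
  if (nrow(manifest) == 0L) return(numeric())
  if (is.null(graphs)) graphs <- manifest_graphs(manifest, embedder, graph_mode)
  vapply(graphs, function(g)
    gat_forward(g, params, keep_attn = FALSE)$prob, numeric(1))
}
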