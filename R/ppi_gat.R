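#' Fit the graph-attention interaction classifier
#'
#' The main fitting function. Each labeled chain pair in the manifest is
#' turned into a residue graph (intra-chain edges below the 8 Angstrom
#' C-alpha cutoff weighted by distance, fully connected inter-chain edges at
#' fixed weight 8), node features come from the chosen embedder, and a
#' four-layer multi-head graph-attention network with chain mean pooling and
#' a fully connected head is trained with binary cross-entropy, Adam
#' (learning rate 1e-4) and gradient accumulation (effective batch 32).
#'
#' @param manifest A data frame with columns `pathA`, `pathB`, `label`
#'   (paths to single-chain PDB files), or the path of a manifest TSV.
#' @param dim_L Embedding dimension. Default 32.
#' @param embedder Embedder name ("onehot", "synthetic", "file") or an
#'   embedder object from [get_embedder()].
#' @param graph_mode `"structure"` or `"esm2ac"`; see [train()].
#' @param model_config Optional [gat_config()] (built from `dim_L`
#'   otherwise).
#' @param control A [train_config()] with the optimisation settings.
#' @param seed Convenience override of `control$seed`.
#' @param verbose Print training progress.
#' @return An object of class `ppi_gat` with components `params` (trained
#'   weights with the configuration embedded), `history` (per-update loss),
#'   `fitted.values` (training-set probabilities), `labels`, and the
#'   configurations used. Supports `print`, `summary`, `coef`, `predict`,
#'   `plot`, `fitted`, `residuals` and `simulate`.
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "toy_ppi")
#' man <- generate_dataset(10, 10, dir, seed = 42)
#' fit <- ppi_gat(man, dim_L = 32, control = train_config(epochs = 2))
#' summary(fit)
#' predict(fit, man[1:2, ])
#' }
#' @export
ppi_gat <- function(manifest, dim_L = 32L, embedder = "onehot",
                    graph_mode = c("structure", "esm2ac"),
                    model_config = NULL, control = train_config(),
                    seed = NULL, verbose = FALSE) {
  cl <- match.call()
  graph_mode <- match.arg(graph_mode)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(seed)) control$seed <- as.integer(seed)
  if (is.null(model_config)) model_config <- gat_config(dim_L = dim_L)
  if (is.character(embedder))
    embedder <- get_embedder(embedder, dim_L = model_config$dim_L,
                             seed = control$seed)
  graphs <- manifest_graphs(manifest, embedder, graph_mode)
  tr <- train(manifest, model_config, control, embedder,
              graph_mode = graph_mode, graphs = graphs, verbose = verbose)
  fitted <- predict_pairs(manifest, tr$params, embedder,
                          graph_mode = graph_mode, graphs = graphs)
  structure(
    list(params = tr$params, history = tr$history,
         fitted.values = fitted, labels = as.integer(manifest$label),
         manifest = manifest, model_config = model_config,
         control = control, embedder_name = embedder$name,
         graph_mode = graph_mode, call = cl),
    class = "ppi_gat")
}

#' @export
print.ppi_gat <- function(x, ...) {
  cat("Graph-attention interaction classifier\n")
  cat("Call: "); print(x$call)
  cfg <- x$model_config
  cat(sprintf("  %d pairs (%d positive), embedder '%s', dim_L = %d\n",
              length(x$labels), sum(x$labels), x$embedder_name, cfg$dim_L))
  cat(sprintf("  hidden dims [%s], %d heads, edge weights '%s'\n",
              paste(cfg$hidden_dims, collapse = ", "), cfg$n_heads,
              cfg$edge_weight_mode))
  if (nrow(x$history))
    cat(sprintf("  %d optimizer updates, final loss %.4f\n",
                max(x$history$step), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.ppi_gat <- function(object, threshold = 0.5, ...) {
  structure(list(fit = object,
                 metrics = binary_metrics(object$labels,
                                          object$fitted.values, threshold)),
            class = "summary.ppi_gat")
}

#' @export
print.summary.ppi_gat <- function(x, ...) {
  print(x$fit)
  cat("\nTraining-set performance:\n")
  print(x$metrics)
  invisible(x)
}

#' @export
coef.ppi_gat <- function(object, ...) object$params

#' Predict interaction probabilities from a fitted classifier
#'
#' @param object A fitted `ppi_gat`.
#' @param newdata Manifest data frame or TSV path (`pathA`, `pathB`); when
#'   omitted, the fitted training probabilities are returned.
#' @param type `"response"` (probabilities) or `"class"` (0/1 at
#'   `threshold`).
#' @param threshold Decision threshold for `type = "class"`. Default 0.5.
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per pair.
#' @export
predict.ppi_gat <- function(object, newdata = NULL,
                            type = c("response", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) p <- object$fitted.values
  else {
    if (is.character(newdata)) newdata <- read_manifest(newdata)
    emb <- get_embedder(object$embedder_name,
                        dim_L = object$model_config$dim_L,
                        seed = object$control$seed)
    p <- predict_pairs(newdata, object$params, emb,
                       graph_mode = object$graph_mode)
  }
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
fitted.ppi_gat <- function(object, ...) object$fitted.values

#' @export
residuals.ppi_gat <- function(object, ...) {
  object$labels - object$fitted.values
}

#' @export
plot.ppi_gat <- function(x, ...) {
  if (!nrow(x$history)) {
    warning("no optimizer updates recorded; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(x$history$step, x$history$loss, type = "l",
                 xlab = "optimizer update", ylab = "binary cross-entropy",
                 main = "Training loss", ...)
  invisible(x)
}

#' @export
simulate.ppi_gat <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted.values
  draw <- function() stats::rbinom(length(p), 1L, p)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_local_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}
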