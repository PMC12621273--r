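test_that("the attention layer matches the dense per-node reference", {
  for (mode in c("append", "none")) {
    cfg <- gat_config(8, edge_weight_mode = mode)
    for (s in 1:6) {
      g <- small_graph(s)
      params <- gat_init(cfg, seed = s + 10)
      got <- gat_layer_forward(g$h, g$edges, params$layers[[1]], cfg)
      ref <- brute_gat_layer(g$h, g$edges, params$layers[[1]], cfg)
      expect_equal(got$out, ref$out, tolerance = 1e-5)
      for (hd in seq_len(cfg$n_heads)) {
        dense <- matrix(0, nrow(g$h), nrow(g$h))
        dense[cbind(got$attn[[hd]]$i, got$attn[[hd]]$j)] <-
          got$attn[[hd]]$alpha
        expect_equal(dense, ref$attn[[hd]], tolerance = 1e-5)
      }
    }
  }
})

test_that("attention over identical neighbours is uniform and a singleton is 1", {
  cfg <- gat_config(8, edge_weight_mode = "append")
  params <- gat_init(cfg, seed = 2)
  # node 1 attends over nodes 2..4 with identical features and weights
  h <- rbind(matrix(rnorm(8), 1), matrix(1, 3, 8))
  h[1, ] <- 1  # self-loop feature also identical
  edges <- data.frame(i = c(1, 1, 1, 2, 3, 4), j = c(2, 3, 4, 1, 1, 1),
                      w = rep(8, 6))
  fw <- gat_layer_forward(h, edges, params$layers[[1]], cfg)
  for (hd in 1:4) {
    a1 <- fw$attn[[hd]]
    expect_equal(a1$alpha[a1$i == 1], rep(1 / 4, 4), tolerance = 1e-12)
  }

  # isolated node: self-loop only, alpha = 1, output = mean over heads of W h
  h1 <- matrix(rnorm(8), 1)
  fw1 <- gat_layer_forward(h1, data.frame(i = integer(), j = integer(),
                                          w = numeric()),
                           params$layers[[1]], cfg)
  expect_equal(fw1$attn[[1]]$alpha, 1)
  fo <- params$layers[[1]]$f_out
  want <- rowMeans(vapply(1:4, function(hd)
    as.vector(h1 %*% params$layers[[1]]$W[, (hd - 1) * fo + seq_len(fo)]),
    numeric(fo)))
  expect_equal(as.vector(fw1$out), want, tolerance = 1e-12)
})

test_that("attention weights normalise to 1 per node, head and layer", {
  for (s in 1:5) {
    g <- toy_graph(seed = s)
    params <- gat_init(gat_config(32), seed = s)
    fw <- gat_forward(g, params)
    n <- nrow(g$node_features)
    for (l in 1:4) for (hd in 1:4) {
      df <- fw$attn[[l]][[hd]]
      sums <- tapply(df$alpha, df$i, sum)
      expect_equal(as.numeric(sums), rep(1, n), tolerance = 1e-5)
    }
  }
})

test_that("forward output is a probability and is deterministic", {
  g <- toy_graph(seed = 3)
  params <- gat_init(gat_config(32), seed = 4)
  p1 <- gat_forward(g, params)$prob
  p2 <- gat_forward(g, params)$prob
  expect_gt(p1, 0); expect_lt(p1, 1)
  expect_identical(p1, p2)
})

test_that("forward is invariant to within-chain node permutation", {
  cx <- toy_pair(seed = 6)
  emb <- get_embedder("onehot", 32)
  g <- build_pair_graph(cx$chainA, cx$chainB,
                        emb$embed(chain_sequence(cx$chainA)),
                        emb$embed(chain_sequence(cx$chainB)))
  # a trained-ish parameter set (random but after one forward, BN running
  # stats are defaults either way)
  params <- gat_init(gat_config(32), seed = 5)
  p0 <- gat_forward(g, params)$prob

  set.seed(8)
  nA <- g$n_A; nB <- g$n_B
  pa <- sample(nA); pb <- sample(nB)
  permA <- cx$chainA; permB <- cx$chainB
  permA$aa <- permA$aa[pa]; permA$coords <- permA$coords[pa, ]
  permA$plddt <- permA$plddt[pa]
  permB$aa <- permB$aa[pb]; permB$coords <- permB$coords[pb, ]
  permB$plddt <- permB$plddt[pb]
  g2 <- build_pair_graph(permA, permB,
                         emb$embed(chain_sequence(permA)),
                         emb$embed(chain_sequence(permB)))
  expect_equal(gat_forward(g2, params)$prob, p0, tolerance = 1e-5)
})

test_that("forward is invariant to independent rigid motions of either chain", {
  cx <- toy_pair(seed = 9)
  emb <- get_embedder("onehot", 32)
  g0 <- build_pair_graph(cx$chainA, cx$chainB,
                         emb$embed(chain_sequence(cx$chainA)),
                         emb$embed(chain_sequence(cx$chainB)))
  params <- gat_init(gat_config(32), seed = 1)
  p0 <- gat_forward(g0, params)$prob
  a2 <- apply_rigid(cx$chainA, random_rigid_motion(11))
  b2 <- apply_rigid(cx$chainB, random_rigid_motion(12))
  g1 <- build_pair_graph(a2, b2,
                         emb$embed(chain_sequence(a2)),
                         emb$embed(chain_sequence(b2)))
  expect_equal(gat_forward(g1, params)$prob, p0, tolerance = 1e-5)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(31)
  cfg <- gat_config(8)
  ca <- random_chain(4, "A", seed = 1, spread = 4)
  cb <- random_chain(3, "B", seed = 2, spread = 4)
  emb <- get_embedder("synthetic", 8, seed = 2)
  g <- build_pair_graph(ca, cb, emb$embed(chain_sequence(ca)),
                        emb$embed(chain_sequence(cb)))
  params <- gat_init(cfg, seed = 3)
  y <- 1
  loss_fn <- function(pp) {
    pr <- gat_forward(g, pp, training = TRUE)$prob
    -(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fw <- gat_forward(g, params, training = TRUE)
  gr <- ppigat:::gat_backward(fw$prob - y, fw$params, fw$cache)
  eps <- 1e-6
  check_block <- function(val, gval, poke) {
    for (i in sample(length(val), min(5, length(val)))) {
      up <- poke(i, eps); dn <- poke(i, -eps)
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(gval[i], num, tolerance = 1e-4)
    }
  }
  for (l in 1:4) {
    check_block(params$layers[[l]]$W, gr$layers[[l]]$W, function(i, e) {
      p <- params; p$layers[[l]]$W[i] <- p$layers[[l]]$W[i] + e; p })
    check_block(params$layers[[l]]$a, gr$layers[[l]]$a, function(i, e) {
      p <- params; p$layers[[l]]$a[i] <- p$layers[[l]]$a[i] + e; p })
  }
  for (l in 1:3)
    check_block(params$bn[[l]]$gamma, gr$bn[[l]]$gamma, function(i, e) {
      p <- params; p$bn[[l]]$gamma[i] <- p$bn[[l]]$gamma[i] + e; p })
  check_block(params$fc$w, gr$fc$w, function(i, e) {
    p <- params; p$fc$w[i] <- p$fc$w[i] + e; p })
})

test_that("attention extraction exports 16 matrices with the block structure", {
  # two chains with no intra-chain contacts: only inter-chain blocks and the
  # self-loop diagonal may be nonzero
  a <- protein_chain("A", c("A", "C", "D"),
                     rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0)))
  b <- protein_chain("B", c("K", "R"), rbind(c(0, 0, 3), c(30, 0, 3)))
  emb <- get_embedder("onehot", 32)
  g <- build_pair_graph(a, b, emb$embed("ACD"), emb$embed("KR"))
  params <- gat_init(gat_config(32), seed = 2)
  out_dir <- withr::local_tempdir()
  ex <- extract_attention(g, params, out_dir = out_dir)
  files <- list.files(out_dir, pattern = "^attention_layer")
  expect_length(files, 16)
  m <- ex$matrices[[1]][[1]]
  expect_equal(dim(m), c(5, 5))
  intraA <- m[1:3, 1:3]; intraB <- m[4:5, 4:5]
  expect_equal(intraA[upper.tri(intraA) | lower.tri(intraA)], rep(0, 6))
  expect_equal(intraB[upper.tri(intraB) | lower.tri(intraB)], rep(0, 2))
  expect_true(all(m[1:3, 4:5] > 0))
  # row sums over edge positions are 1
  expect_equal(rowSums(m), rep(1, 5), tolerance = 1e-5)
  back <- as.matrix(read.table(file.path(out_dir, files[1]), sep = "\t"))
  expect_equal(dim(back), c(5, 5))
})

test_that("checkpoints round-trip parameters and embedded configuration", {
  params <- gat_init(gat_config(32, edge_weight_mode = "none"), seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, path)
  back <- load_checkpoint(path)
  expect_identical(back, params)
  expect_identical(back$config$edge_weight_mode, "none")
  expect_error(load_checkpoint("nope.rds"), "not found")
})

test_that("model dimensions are validated", {
  g <- toy_graph(seed = 2, dim_L = 32)
  params <- gat_init(gat_config(64), seed = 1)
  expect_error(gat_forward(g, params), "expects 64")
  expect_error(gat_config(30), "divisible")
})
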