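test_that("distance matrix matches the brute-force double loop", {
  ch <- protein_chain("A", c("A", "C"), rbind(c(0, 0, 0), c(3, 4, 0)))
  dm <- distance_matrix(ch)
  expect_equal(dm, matrix(c(0, 5, 5, 0), 2))

  single <- protein_chain("A", "G", matrix(1:3, 1))
  expect_equal(distance_matrix(single), matrix(0, 1, 1), ignore_attr = TRUE)

  ch <- random_chain(50, seed = 21)
  expect_equal(unname(distance_matrix(ch)), brute_distance_matrix(ch$coords),
               tolerance = 1e-12)
})

test_that("intra-chain edges use a strict cutoff and carry distances", {
  co <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 7.9, 0))
  dm <- brute_distance_matrix(co)
  dm[1, 3] <- dm[3, 1] <- 9  # force pair (1,3) out
  e <- intra_edges(dm)
  key <- paste(e$i, e$j)
  expect_setequal(key, c("1 2", "2 1", "2 3", "3 2"))
  expect_equal(sort(unique(e$w)), c(5, 7.9))

  # boundary: exactly 8 is excluded
  dm2 <- matrix(c(0, 8, 8, 0), 2)
  expect_equal(nrow(intra_edges(dm2)), 0)
  # all-isolated
  expect_equal(nrow(intra_edges(matrix(c(0, 12, 12, 0), 2))), 0)
  expect_error(intra_edges(dm2, cutoff = 0), "positive")
})

test_that("inter-chain fictional edges form the complete bipartite set at weight 8", {
  e <- inter_edges(2, 3)
  expect_equal(nrow(e), 12)
  expect_true(all(e$w == 8))
  e11 <- inter_edges(1, 1)
  expect_setequal(paste(e11$i, e11$j), c("1 2", "2 1"))
  e10 <- inter_edges(10, 10)
  expect_equal(nrow(e10), 200)
  expect_equal(anyDuplicated(paste(e10$i, e10$j)), 0)
  # all edges cross chains
  expect_true(all((e10$i <= 10) != (e10$j <= 10)))
})

test_that("contact counting matches brute force on the worked example", {
  a <- protein_chain("A", c("A", "C"), rbind(c(0, 0, 0), c(3.8, 0, 0)))
  b <- protein_chain("B", c("D", "E"), rbind(c(0, 0, 5), c(100, 100, 100)))
  cc <- count_contacts(a, b)
  expect_equal(cc$n_pairs, 2)
  expect_setequal(cc$contact_residues, c("A:1", "A:2", "B:1"))
})

test_that("contact counting equals brute force on random geometries", {
  for (s in 1:30) {
    a <- random_chain(sample(3:25, 1), "A", seed = s, spread = 6)
    b <- random_chain(sample(3:25, 1), "B", seed = s + 1000, spread = 6)
    cc <- count_contacts(a, b)
    bf <- brute_contacts(a, b)
    expect_equal(cc$n_pairs, bf$n_pairs)
    expect_setequal(cc$contact_residues, bf$contact_residues)
    # symmetry of the pair count
    expect_equal(count_contacts(b, a)$n_pairs, cc$n_pairs)
  }
  far_b <- random_chain(10, "B", seed = 2)
  far_b$coords <- far_b$coords + 1000
  cc0 <- count_contacts(random_chain(10, "A", seed = 3), far_b)
  expect_equal(cc0$n_pairs, 0)
  expect_length(cc0$contact_residues, 0)
})

test_that("the pair graph combines intra, offset intra and inter edges", {
  emb <- get_embedder("onehot", 32)
  # two 2-residue chains, everything farther than 8 within each chain
  a <- protein_chain("A", c("A", "C"), rbind(c(0, 0, 0), c(20, 0, 0)))
  b <- protein_chain("B", c("D", "E"), rbind(c(0, 0, 50), c(20, 0, 50)))
  g <- build_pair_graph(a, b, emb$embed("AC"), emb$embed("DE"))
  expect_equal(nrow(g$edges), 8)
  expect_true(all(g$edges$w == 8))
  expect_equal(g$chain, c("A", "A", "B", "B"))
  expect_equal(g$node_features[1, ], emb$embed("AC")[1, ])

  for (s in 1:5) {
    ca <- random_chain(15, "A", seed = s, spread = 5)
    cb <- random_chain(12, "B", seed = s + 50, spread = 5)
    g <- build_pair_graph(ca, cb, emb$embed(chain_sequence(ca)),
                          emb$embed(chain_sequence(cb)))
    nA <- nrow(intra_edges(distance_matrix(ca)))
    nB <- nrow(intra_edges(distance_matrix(cb)))
    expect_equal(nrow(g$edges), nA + nB + 2 * 15 * 12)
    # symmetric storage
    expect_setequal(paste(g$edges$i, g$edges$j, signif(g$edges$w, 10)),
                    paste(g$edges$j, g$edges$i, signif(g$edges$w, 10)))
  }
  expect_error(build_pair_graph(ca, cb, emb$embed("AC"),
                                emb$embed(chain_sequence(cb))),
               "do not match")
})

test_that("pair graphs are invariant under independent rigid motions", {
  emb <- get_embedder("onehot", 32)
  ca <- random_chain(12, "A", seed = 7, spread = 5)
  cb <- random_chain(10, "B", seed = 8, spread = 5)
  g0 <- build_pair_graph(ca, cb, emb$embed(chain_sequence(ca)),
                         emb$embed(chain_sequence(cb)))
  ca2 <- apply_rigid(ca, random_rigid_motion(1))
  cb2 <- apply_rigid(cb, random_rigid_motion(2))
  g1 <- build_pair_graph(ca2, cb2, emb$embed(chain_sequence(ca)),
                         emb$embed(chain_sequence(cb)))
  o0 <- order(g0$edges$i, g0$edges$j)
  o1 <- order(g1$edges$i, g1$edges$j)
  expect_equal(g0$edges$i[o0], g1$edges$i[o1])
  expect_equal(g0$edges$w[o0], g1$edges$w[o1], tolerance = 1e-9)
  expect_equal(g0$node_features, g1$node_features)
})

test_that("contact-map edges threshold strictly and validate input", {
  cpm <- matrix(0, 3, 3)
  cpm[1, 2] <- cpm[2, 1] <- 0.6
  cpm[1, 3] <- cpm[3, 1] <- 0.5
  cpm[2, 3] <- cpm[3, 2] <- 0.49
  e <- contact_map_edges(cpm)
  expect_setequal(paste(e$i, e$j), c("1 2", "2 1"))
  expect_true(all(e$w == 8))
  expect_equal(nrow(contact_map_edges(matrix(0, 5, 5))), 0)
  expect_error(contact_map_edges(cpm, threshold = 1.2), "inside")
  expect_error(contact_map_edges(matrix(c(0, 0.9, 0.1, 0), 2)), "symmetric")
  expect_error(contact_map_edges(cpm * 3), "0, 1|\\[0, 1\\]")

  for (s in 1:10) {
    set.seed(s)
    p <- matrix(runif(400), 20, 20)
    p <- (p + t(p)) / 2
    diag(p) <- 0
    e <- contact_map_edges(p, threshold = 0.5)
    want <- sum(p[upper.tri(p)] > 0.5) * 2
    expect_equal(nrow(e), want)
    if (nrow(e)) expect_true(all(p[cbind(e$i, e$j)] > 0.5))
  }
})
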