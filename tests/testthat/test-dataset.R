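# chains of given lengths with exactly n_pairs inter-chain contact pairs:
# contact pairs are (i, i) overlaps 3 apart in z, all other residues far away
pair_with_contacts <- function(n_pairs, len_A = 50, len_B = 50) {
  mk <- function(id, len, zoff) {
    near <- if (n_pairs > 0)
      cbind(seq_len(n_pairs) * 20, 0, zoff) else NULL
    # far residues of the two chains live in disjoint distant regions
    far <- cbind(seq_len(len - n_pairs) * 20 + 10000 + zoff * 10000, 0, zoff)
    protein_chain(id, rep("G", len), rbind(near, far),
                  plddt = rep(70, len))
  }
  list(a = mk("A", len_A, 0), b = mk("B", len_B, 3))
}

test_that("the positive-pair filter applies strict contacts and inclusive lengths", {
  cfg <- pair_filter_config()
  p9 <- pair_with_contacts(9, 35, 50)
  p9$b <- pair_with_contacts(9, 35, 300)$b
  expect_equal(count_contacts(p9$a, p9$b)$n_pairs, 9)
  f <- filter_positive_pair(p9$a, p9$b, cfg)
  expect_true(f$keep)
  expect_length(f$reasons, 0)

  p8 <- pair_with_contacts(8)
  f8 <- filter_positive_pair(p8$a, p8$b, cfg)
  expect_false(f8$keep)
  expect_equal(f8$reasons, "contacts")

  short <- pair_with_contacts(9, len_A = 34)
  fs <- filter_positive_pair(short$a, short$b, cfg)
  expect_false(fs$keep)
  expect_true("length" %in% fs$reasons)

  long <- pair_with_contacts(9, len_B = 301)
  fl <- filter_positive_pair(long$a, long$b, cfg)
  expect_false(fl$keep)
  expect_true("length" %in% fl$reasons)

  # both criteria can fail at once, and the filter is symmetric
  bad <- pair_with_contacts(2, len_A = 20)
  fb <- filter_positive_pair(bad$a, bad$b, cfg)
  expect_setequal(fb$reasons, c("contacts", "length"))
  expect_equal(filter_positive_pair(bad$b, bad$a, cfg)$keep, fb$keep)
})

test_that("negative sampling enumerates exactly the admissible pairs", {
  neg <- sample_negatives(c("P1", "P2", "P3"),
                          exclusion = list(c("P1", "P2")), n = 2, seed = 1)
  got <- sort(paste(pmin(neg$p, neg$q), pmax(neg$p, neg$q)))
  expect_equal(got, c("P1 P3", "P2 P3"))

  expect_equal(nrow(sample_negatives(c("P1", "P2"), NULL, n = 0)), 0)
  expect_error(sample_negatives(c("P1", "P2", "P3"),
                                list(c("P1", "P2")), n = 3, seed = 1),
               "2 admissible")
  expect_error(sample_negatives("P1", NULL, n = 1), "at least 2")
})

test_that("large negative draws avoid self-pairs, duplicates and excluded pairs", {
  pool <- sprintf("P%03d", 1:200)
  excl <- list(c("P001", "P002"), c("P005", "P100"), c("P199", "P200"))
  neg <- sample_negatives(pool, excl, n = 10000, seed = 42)
  expect_equal(nrow(neg), 10000)
  expect_true(all(neg$p != neg$q))
  key <- paste(pmin(neg$p, neg$q), pmax(neg$p, neg$q))
  expect_equal(anyDuplicated(key), 0)
  bad <- vapply(excl, function(e) paste(min(e), max(e)), "")
  expect_length(intersect(key, bad), 0)
  # seeded reproducibility
  neg2 <- sample_negatives(pool, excl, n = 10000, seed = 42)
  expect_identical(neg, neg2)
})

test_that("balanced manifests pair every positive with a fresh negative", {
  positives <- data.frame(pathA = sprintf("prot%02d", 1:10),
                          pathB = sprintf("prot%02d", 11:20))
  man <- build_balanced_manifest(positives, seed = 3)
  expect_equal(nrow(man), 20)
  expect_equal(sum(man$label == 1), 10)
  expect_equal(sum(man$label == 0), 10)
  # negatives never replicate a positive pair
  posk <- paste(pmin(positives$pathA, positives$pathB),
                pmax(positives$pathA, positives$pathB))
  negs <- man[man$label == 0, ]
  negk <- paste(pmin(negs$pathA, negs$pathB), pmax(negs$pathA, negs$pathB))
  expect_length(intersect(negk, posk), 0)
  expect_true(all(negs$pathA != negs$pathB))
  # deterministic given the seed
  expect_identical(man, build_balanced_manifest(positives, seed = 3))
  # extra exclusions are respected
  excl <- list(c("prot01", "prot03"))
  man2 <- build_balanced_manifest(positives, exclusion = excl, seed = 3)
  negs2 <- man2[man2$label == 0, ]
  negk2 <- paste(pmin(negs2$pathA, negs2$pathB),
                 pmax(negs2$pathA, negs2$pathB))
  expect_false("prot01 prot03" %in% negk2)
})

test_that("exclusion lists round-trip through TSV symmetrically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tP2", "P9\tP3"), path)
  keys <- read_exclusion(path)
  expect_length(keys, 2)
  # unordered membership: (P3, P9) hits the stored (P9, P3)
  neg <- sample_negatives(c("P3", "P9", "P4"), keys, n = 2, seed = 1)
  got <- paste(pmin(neg$p, neg$q), pmax(neg$p, neg$q))
  expect_false("P3 P9" %in% got)
})

test_that("filter reports cover every manifest row with reasons", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(2, 2, dir, seed = 31, len_range = c(35, 40))
  rep <- filter_report(man)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$keep[man$label == 1]))
  expect_true(all(!rep$keep[man$label == 0]))
  expect_true(all(grepl("contacts", rep$reasons[man$label == 0])))
})
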