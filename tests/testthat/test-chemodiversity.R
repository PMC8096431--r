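make_features <- function(intensities, ids = rownames(intensities)) {
  df <- tibble::tibble(feature_id = ids,
                       mz = seq(200, 300, length.out = length(ids)),
                       rt = seq_len(length(ids)))
  for (s in colnames(intensities)) {
    df[[paste0("intensity_", s)]] <- intensities[, s]
  }
  df
}

test_that("blank filtering removes exactly the blank-detected features", {
  m <- cbind(blank1 = c(5e6, 0, 0), s1 = c(1e7, 2e6, 3e6),
             s2 = c(0, 0, 2e6))
  rownames(m) <- c("contam", "keep1", "keep2")
  feats <- make_features(m)
  kept <- filter_blanks(feats, "blank1")
  expect_setequal(kept$feature_id, c("keep1", "keep2"))
  expect_error(filter_blanks(feats, "nope"), "unknown blank")
  # generator ground truth: spiked contaminants all removed, spikes kept
  sim <- simulate_features(seed = 3)
  kept <- filter_blanks(sim$features, sim$blank_ids)
  expect_true(all(sim$truth$feature_id %in% kept$feature_id))
  blank_cols <- paste0("intensity_", sim$blank_ids)
  expect_true(all(rowSums(kept[, blank_cols] > 0) == 0))
})

test_that("presence/absence uses a strict threshold", {
  m <- cbind(s1 = c(1e6, 1e6 + 1, 0), s2 = c(2e6, 5e5, 0))
  rownames(m) <- c("f1", "f2", "f3")
  pa <- to_presence_absence(make_features(m))
  expect_equal(pa["s1", ], c(f1 = 0L, f2 = 1L, f3 = 0L)) # exactly 1e6 absent
  expect_equal(pa["s2", ], c(f1 = 1L, f2 = 0L, f3 = 0L))
  expect_error(to_presence_absence(make_features(m), sample_ids = "sX"),
               "unknown sample")
})

test_that("Jaccard distance matches hand values, vegan, and metric axioms", {
  a <- c(1, 1, 1, 0); b <- c(0, 1, 1, 1)
  expect_equal(jaccard_distance(a, b), 0.5) # 1 - 2/4
  expect_equal(jaccard_distance(a, a), 0)
  expect_equal(jaccard_distance(c(1, 0), c(0, 1)), 1)
  expect_warning(d0 <- jaccard_distance(c(0, 0), c(0, 0)), "empty")
  expect_equal(d0, 0)
  expect_error(jaccard_distance(1, c(1, 0)), "length mismatch")
  skip_if_not_installed("vegan")
  set.seed(41)
  m <- matrix(rbinom(8 * 30, 1, 0.4), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  expect_equal(jaccard_matrix(m),
               as.matrix(vegan::vegdist(m, "jaccard", binary = TRUE)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # triangle inequality on random triples
  jm <- jaccard_matrix(m)
  for (k in 1:50) {
    idx <- sample(8, 3)
    expect_lte(jm[idx[1], idx[2]],
               jm[idx[1], idx[3]] + jm[idx[3], idx[2]] + 1e-12)
  }
})

test_that("UPGMA reproduces hand-worked merges and independent oracles", {
  # 3 leaves: merge (A,B) at 2, then C joins at 6
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cm <- cophenetic_matrix(upgma(d))
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 6)
  expect_equal(cm["B", "C"], 6)
  # two leaves merge at their distance (height = d, not d/2)
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(cophenetic_matrix(upgma(d2))["x", "y"], 0.4)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # random matrices: equality with brute-force agglomeration and hclust
  set.seed(99)
  for (k in 1:25) {
    m <- random_dist_matrix(8)
    cm <- cophenetic_matrix(upgma(m))
    expect_equal(cm, upgma_bruteforce_cophenetic(m)[rownames(cm), colnames(cm)],
                 tolerance = 1e-9)
    hc <- as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(m),
                                                    "average")))
    expect_equal(cm, hc[rownames(cm), colnames(cm)], tolerance = 1e-9)
  }
})

test_that("cophenetic output is ultrametric and round-trips through UPGMA", {
  set.seed(7)
  m <- random_dist_matrix(10)
  tree <- upgma(m)
  cm <- cophenetic_matrix(tree)
  # three-point condition on all triples
  expect_lte(max_ultrametric_violation(cm), 1e-12)
  # an ultrametric matrix is a fixed point of UPGMA
  rt <- cophenetic_matrix(upgma(cm))
  expect_equal(rt, cm[rownames(rt), colnames(rt)], tolerance = 1e-12)
  # heights nondecreasing leaf-to-root along every path
  check <- function(node, child_max = 0) {
    expect_gte(node$height, child_max - 1e-12)
    if (is.null(node$label)) {
      check(node$left, 0)
      check(node$right, 0)
      expect_gte(node$height, node$left$height)
      expect_gte(node$height, node$right$height)
    }
  }
  check(tree)
})

test_that("the clustering pipeline is deterministic end to end", {
  sim <- simulate_features(seed = 21)
  t1 <- chemo_dendrogram(sim$features, sim$blank_ids)
  t2 <- chemo_dendrogram(sim$features, sim$blank_ids)
  expect_identical(dendro_leaves(t1), dendro_leaves(t2))
  expect_equal(cophenetic_matrix(t1), cophenetic_matrix(t2))
  expect_setequal(dendro_leaves(t1),
                  unlist(lapply(sim$sample_groups, unlist), use.names = FALSE))
})
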