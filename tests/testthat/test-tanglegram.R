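test_that("entanglement endpoints, hand value, symmetry and relabeling", {
  expect_equal(entanglement(letters[1:6], letters[1:6]), 0)
  expect_equal(entanglement(letters[1:6], rev(letters[1:6])), 1)
  # single adjacent swap, n = 4, L = 1: 2 / 8
  expect_equal(entanglement(c("a", "b", "c", "d"), c("b", "a", "c", "d"),
                            L = 1), 0.25)
  set.seed(5)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    o1 <- sample(letters[1:n])
    o2 <- sample(letters[1:n])
    expect_equal(entanglement(o1, o2), entanglement(o2, o1))
    e <- entanglement(o1, o2)
    expect_gte(e, 0); expect_lte(e, 1)
    # relabeling invariance
    map <- setNames(LETTERS[1:n], letters[1:n])
    expect_equal(entanglement(unname(map[o1]), unname(map[o2])), e)
  }
  expect_error(entanglement(c("a", "b"), c("a", "c")), "permutations")
})

test_that("untangling reaches zero on concordant trees and never worsens", {
  sim <- simulate_tree_pair(n_leaves = 10, discordance = 0, seed = 2)
  res <- untangle_step2side(sim$tree_left, sim$tree_right)
  expect_equal(res$entanglement, 0)
  # mirror-image trees: same topology, reversed ladderization
  mirror <- function(node) {
    if (!is.null(node$label)) return(node)
    out <- node
    out$left <- mirror(node$right)
    out$right <- mirror(node$left)
    out
  }
  res_m <- untangle_step2side(sim$tree_left, mirror(sim$tree_left))
  expect_equal(res_m$entanglement, 0)
  # never worse than the initial ladderized orderings
  set.seed(10)
  for (s in 1:10) {
    sim <- simulate_tree_pair(n_leaves = 12, discordance = 0.6, seed = s)
    init <- entanglement(dendro_leaves(ladderize_dendro(sim$tree_left)),
                         dendro_leaves(ladderize_dendro(sim$tree_right)))
    res <- untangle_step2side(sim$tree_left, sim$tree_right)
    expect_lte(res$entanglement, init + 1e-12)
    expect_setequal(res$ordering_left, res$ordering_right)
  }
  expect_error(untangle_step2side(sim$tree_left,
                                  upgma(random_dist_matrix(5))),
               "leaf sets")
})

test_that("untangling equals the exhaustive-rotation optimum on small trees", {
  for (s in 1:25) {
    sim <- simulate_tree_pair(n_leaves = 6, discordance = 0.5, n_items = 30,
                              seed = s)
    res <- untangle_step2side(sim$tree_left, sim$tree_right)
    expect_equal(res$entanglement,
                 exhaustive_min_entanglement(sim$tree_left, sim$tree_right),
                 tolerance = 1e-12)
  }
  for (s in 1:10) {
    sim <- simulate_tree_pair(n_leaves = 5, discordance = 1, n_items = 25,
                              seed = s + 100)
    res <- untangle_step2side(sim$tree_left, sim$tree_right)
    expect_equal(res$entanglement,
                 exhaustive_min_entanglement(sim$tree_left, sim$tree_right),
                 tolerance = 1e-12)
  }
})

test_that("mean post-untangle entanglement grows with simulated discordance", {
  means <- vapply(c(0, 0.25, 0.5, 0.75), function(d) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_tree_pair(n_leaves = 12, discordance = d, seed = s)
      untangle_step2side(sim$tree_left, sim$tree_right)$entanglement
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("newick round trip preserves topology and heights", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_newick(f)
  expect_setequal(dendro_leaves(tr), c("A", "B"))
  expect_equal(cophenetic_matrix(tr)["A", "B"], 1)
  set.seed(3)
  for (k in 1:10) {
    tree <- upgma(random_dist_matrix(sample(4:12, 1)))
    write_newick(tree, f)
    back <- read_newick(f)
    cm <- cophenetic_matrix(tree)
    expect_equal(cophenetic_matrix(back)[rownames(cm), colnames(cm)], cm,
                 tolerance = 1e-9)
  }
  writeLines("((A:1,B:1):1,(A:1,C:1):1);", f)
  expect_error(read_newick(f), "duplicate")
})
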