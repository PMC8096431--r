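# Independent oracles used across the suite.

# Welch t statistic and two-sided p from the textbook formulas.
welch_oracle <- function(x, y) {
  se2 <- var(x) / length(x) + var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                   (var(y) / length(y))^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F from between/within sums of squares.
anova_f_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - mean(y))^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Two-sided permutation p-value for a difference in means.
permutation_p <- function(x, y, n_draws = 10000, seed = 42) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  hits <- replicate(n_draws, {
    idx <- sample(length(pool), length(x))
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  })
  mean(hits)
}

# Brute-force UPGMA agglomeration, written independently of upgma():
# matrix-indexed clusters, unweighted average linkage via explicit member
# enumeration over the original distance matrix.
upgma_bruteforce_cophenetic <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  heights <- matrix(0, n, n)
  repeat {
    k <- length(members)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k)) for (j in seq_len(i - 1)) {
      avg <- mean(d[members[[i]], members[[j]]])
      if (avg < best[1]) best <- c(avg, j, i)
    }
    i <- best[3]; j <- best[2]
    heights[members[[i]], members[[j]]] <- best[1]
    heights[members[[j]], members[[i]]] <- best[1]
    members[[j]] <- c(members[[j]], members[[i]])
    members[[i]] <- NULL
  }
  dimnames(heights) <- dimnames(d)
  heights
}

# Largest violation of the ultrametric three-point condition
# d(x,y) <= max(d(x,z), d(y,z)) over all triples (vectorized over z).
max_ultrametric_violation <- function(cm) {
  v <- -Inf
  for (z in seq_len(ncol(cm))) {
    v <- max(v, max(cm - outer(cm[, z], cm[, z], pmax)))
  }
  v
}

random_dist_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m + t(m)
}

# Exhaustive minimum entanglement over all rotations of both trees.
exhaustive_min_entanglement <- function(tree_left, tree_right, L = 1.5) {
  best <- Inf
  for (a in dendro_all_orderings(tree_left)) {
    for (b in dendro_all_orderings(tree_right)) {
      best <- min(best, entanglement(a, b, L))
    }
  }
  best
}
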