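# Minimal rooted-binary ultrametric dendrogram structure with the rotation
# machinery needed for tanglegram comparison: ladderization, leaf orderings,
# entanglement, and alternating-side untangling in which each one-sided step
# is solved exactly by dynamic programming over subtree flips.

dendro_leaf <- function(label) {
  structure(list(label = label, height = 0), class = "chem_dendro")
}

dendro_node <- function(left, right, height) {
  if (height < max(dendro_height(left), dendro_height(right)) - 1e-12) {
    stop("merge height below a child's height; heights must be nondecreasing")
  }
  structure(list(left = left, right = right, height = height),
            class = "chem_dendro")
}

is_dendro_leaf <- function(node) !is.null(node$label)

dendro_height <- function(node) node$height

#' Leaf labels of a dendrogram in plotting order
#'
#' @param tree A `chem_dendro`.
#' @return Character vector of leaf labels, left to right.
#' @export
dendro_leaves <- function(tree) {
  if (is_dendro_leaf(tree)) return(tree$label)
  c(dendro_leaves(tree$left), dendro_leaves(tree$right))
}

dendro_size <- function(tree) {
  if (is_dendro_leaf(tree)) return(1L)
  dendro_size(tree$left) + dendro_size(tree$right)
}

#' Ladderize a dendrogram
#'
#' Reorders every internal node so the larger subtree comes last (ties by
#' lexicographically smaller leading leaf label first), giving a canonical
#' starting ordering for untangling.
#'
#' @param tree A `chem_dendro`.
#' @return The ladderized tree.
#' @export
ladderize_dendro <- function(tree) {
  if (is_dendro_leaf(tree)) return(tree)
  l <- ladderize_dendro(tree$left)
  r <- ladderize_dendro(tree$right)
  sl <- dendro_size(l)
  sr <- dendro_size(r)
  swap <- sl > sr ||
    (sl == sr && dendro_leaves(l)[1] > dendro_leaves(r)[1])
  if (swap) { tmp <- l; l <- r; r <- tmp }
  dendro_node(l, r, tree$height)
}

#' All leaf orderings reachable by internal-node rotations
#'
#' Exhaustive enumeration (2^(n-1) orderings for n leaves); intended for
#' small trees, e.g. as an optimality oracle for [untangle_step2side()].
#'
#' @param tree A `chem_dendro`.
#' @return List of character vectors.
#' @export
dendro_all_orderings <- function(tree) {
  if (is_dendro_leaf(tree)) return(list(tree$label))
  ls <- dendro_all_orderings(tree$left)
  rs <- dendro_all_orderings(tree$right)
  out <- list()
  for (a in ls) for (b in rs) {
    out[[length(out) + 1L]] <- c(a, b)
    out[[length(out) + 1L]] <- c(b, a)
  }
  out
}

# --- entanglement -----------------------------------------------------------

#' Entanglement of two leaf orderings
#'
#' Sum over leaves of |position in left ordering - position in right
#' ordering|^L, normalized by the value attained when one ordering is the
#' exact reversal of the other; 0 for identical orderings, 1 for a
#' reversal, symmetric in its arguments and invariant under relabeling.
#'
#' @param ordering_left,ordering_right Permutations of the same label set,
#'   length >= 2.
#' @param L Positive exponent (default 1.5).
#' @return Entanglement in \[0, 1\].
#' @export
entanglement <- function(ordering_left, ordering_right, L = 1.5) {
  n <- length(ordering_left)
  stopifnot(n >= 2, L > 0)
  if (!setequal(ordering_left, ordering_right) ||
      length(ordering_right) != n || anyDuplicated(ordering_left)) {
    stop("orderings must be permutations of the same label set")
  }
  pos_r <- match(ordering_left, ordering_right)
  num <- sum(abs(seq_len(n) - pos_r)^L)
  denom <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  num / denom
}

# --- one-sided exact untangling ---------------------------------------------

# Flatten a dendro into parallel arrays for the DP.
flatten_dendro <- function(tree) {
  env <- new.env()
  env$left <- integer(0); env$right <- integer(0)
  env$size <- integer(0); env$label <- character(0)
  rec <- function(node) {
    id <- length(env$size) + 1L
    env$left[id] <- 0L; env$right[id] <- 0L
    env$size[id] <- 0L; env$label[id] <- NA_character_
    if (is_dendro_leaf(node)) {
      env$label[id] <- node$label
      env$size[id] <- 1L
    } else {
      lid <- rec(node$left)
      rid <- rec(node$right)
      env$left[id] <- lid
      env$right[id] <- rid
      env$size[id] <- env$size[lid] + env$size[rid]
    }
    id
  }
  root <- rec(tree)
  list(left = env$left, right = env$right, size = env$size,
       label = env$label, root = root)
}

# Optimal leaf ordering of `tree` (over all internal-node rotations) against
# fixed target positions `target_pos` (named integer vector), minimizing
# sum |pos - target|^L. Exact dynamic programming: once ancestor flips are
# fixed, a subtree's leaves occupy a contiguous block with a known start, so
# cost(node, start) decomposes over the two child orders.
optimal_one_side <- function(tree, target_pos, L) {
  f <- flatten_dendro(tree)
  n_nodes <- length(f$size)
  n <- f$size[f$root]
  cost <- matrix(NA_real_, n_nodes, n)
  choice <- matrix(NA, n_nodes, n)
  solve <- function(id, start) {
    if (!is.na(cost[id, start])) return(cost[id, start])
    if (f$left[id] == 0L) {
      c0 <- abs(start - target_pos[[f$label[id]]])^L
      cost[id, start] <<- c0
      return(c0)
    }
    l <- f$left[id]; r <- f$right[id]
    c_lr <- solve(l, start) + solve(r, start + f$size[l])
    c_rl <- solve(r, start) + solve(l, start + f$size[r])
    flip <- c_rl < c_lr
    cost[id, start] <<- if (flip) c_rl else c_lr
    choice[id, start] <<- flip
    cost[id, start]
  }
  total <- solve(f$root, 1L)
  order_out <- character(n)
  emit <- function(id, start) {
    if (f$left[id] == 0L) {
      order_out[start] <<- f$label[id]
      return(invisible())
    }
    l <- f$left[id]; r <- f$right[id]
    if (isTRUE(choice[id, start])) {
      emit(r, start); emit(l, start + f$size[r])
    } else {
      emit(l, start); emit(r, start + f$size[l])
    }
  }
  emit(f$root, 1L)
  list(ordering = order_out, cost = total)
}

#' Untangle a tanglegram by alternating exact one-sided rotation
#'
#' Starting from both trees ladderized, alternately fixes one tree's leaf
#' ordering and rotates the internal nodes of the other to minimize the
#' entanglement, until a full round yields no improvement or `max_rounds`
#' rounds have run. Each one-sided step is solved exactly (dynamic
#' programming over subtree flips), so the entanglement is non-increasing
#' across steps and never exceeds that of the initial ladderized orderings.
#' Both alternation orders are tried and the better result returned.
#'
#' @param dend_left,dend_right `chem_dendro` trees over the same leaf set.
#' On small trees (`n <= exact_leaves`) the joint optimum over all rotations
#' of both trees is computed exactly instead: every rotation of the left
#' tree is enumerated and the right tree's best response found by the same
#' dynamic program, since plain alternation can stall in a local optimum on
#' tiny instances.
#'
#' @param L Entanglement exponent (default 1.5).
#' @param max_rounds Maximum optimize-left/optimize-right rounds.
#' @param exact_leaves Leaf-count threshold up to which the joint optimum
#'   is computed exactly by enumeration (default 8).
#' @return List of class `tanglegram_result`: `ordering_left`,
#'   `ordering_right`, `entanglement`, `exponent_L`.
#' @export
untangle_step2side <- function(dend_left, dend_right, L = 1.5,
                               max_rounds = 25L, exact_leaves = 8L) {
  leaves_l <- dendro_leaves(dend_left)
  leaves_r <- dendro_leaves(dend_right)
  if (!setequal(leaves_l, leaves_r)) {
    stop("trees have different leaf sets: ",
         paste(union(setdiff(leaves_l, leaves_r),
                     setdiff(leaves_r, leaves_l)), collapse = ", "))
  }
  init_l <- dendro_leaves(ladderize_dendro(dend_left))
  init_r <- dendro_leaves(ladderize_dendro(dend_right))
  n <- length(init_l)
  denom <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)

  if (n <= exact_leaves) {
    best <- list(ol = init_l, or = init_r,
                 ent = entanglement(init_l, init_r, L))
    for (ol in dendro_all_orderings(dend_left)) {
      res <- optimal_one_side(dend_right,
                              stats::setNames(seq_along(ol), ol), L)
      ent <- res$cost / denom
      if (ent < best$ent) best <- list(ol = ol, or = res$ordering, ent = ent)
    }
    return(structure(list(ordering_left = best$ol, ordering_right = best$or,
                          entanglement = best$ent, exponent_L = L),
                     class = "tanglegram_result"))
  }

  run <- function(first) {
    ol <- init_l
    or <- init_r
    ent <- entanglement(ol, or, L)
    side <- first
    for (round in seq_len(2L * max_rounds)) {
      if (side == "right") {
        res <- optimal_one_side(dend_right,
                                stats::setNames(seq_along(ol), ol), L)
        or <- res$ordering
      } else {
        res <- optimal_one_side(dend_left,
                                stats::setNames(seq_along(or), or), L)
        ol <- res$ordering
      }
      new_ent <- entanglement(ol, or, L)
      if (new_ent >= ent - 1e-15) {
        ent <- min(ent, new_ent)
        if (round > 1L) break
      }
      ent <- new_ent
      side <- if (side == "right") "left" else "right"
    }
    list(ol = ol, or = or, ent = ent)
  }
  a <- run("right")
  b <- run("left")
  best <- if (a$ent <= b$ent) a else b
  structure(list(ordering_left = best$ol, ordering_right = best$or,
                 entanglement = best$ent, exponent_L = L),
            class = "tanglegram_result")
}

# --- newick interchange via ape ---------------------------------------------

dendro_to_newick <- function(tree, digits = 12) {
  rec <- function(node, parent_h) {
    bl <- format(parent_h - node$height, digits = digits, scientific = FALSE)
    if (is_dendro_leaf(node)) return(paste0(node$label, ":", bl))
    paste0("(", rec(node$left, node$height), ",",
           rec(node$right, node$height), "):", bl)
  }
  if (is_dendro_leaf(tree)) stop("cannot serialize a single-leaf tree")
  paste0("(", rec(tree$left, tree$height), ",",
         rec(tree$right, tree$height), ");")
}

#' Write a dendrogram as newick
#'
#' Branch lengths encode the ultrametric heights (a child's branch length is
#' its parent's height minus its own).
#'
#' @param tree A `chem_dendro`.
#' @param path Output file path.
#' @export
write_newick <- function(tree, path) {
  writeLines(dendro_to_newick(tree), path)
  invisible(path)
}

#' Read a rooted binary ultrametric dendrogram from newick
#'
#' Parses with \pkg{ape} and reconstructs node heights from root-to-tip
#' depths (height = max leaf depth minus node depth). Errors on duplicate
#' leaf labels or non-binary nodes.
#'
#' @param path Newick file path (or a `phylo` object).
#' @return A `chem_dendro`.
#' @export
read_newick <- function(path) {
  phy <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick file: ", path)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  if (!ape::is.binary(phy)) stop("tree is not binary")
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  max_depth <- max(depth[seq_len(n_tip)])
  children <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(node) {
    if (node <= n_tip) return(dendro_leaf(phy$tip.label[node]))
    kids <- children[[as.character(node)]]
    dendro_node(build(kids[1]), build(kids[2]),
                height = max_depth - depth[node])
  }
  build(n_tip + 1L)
}
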