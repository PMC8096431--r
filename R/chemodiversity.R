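# Chemical-dissimilarity clustering: blank filtering, presence/absence
# conversion of feature intensities, Jaccard distances between strain
# chemotypes, and UPGMA agglomeration into an ultrametric dendrogram.

#' Remove blank-derived features
#'
#' Drops every feature whose intensity exceeds `detection_threshold` in any
#' blank run (solvent and medium extraction controls); all other features
#' pass through unchanged.
#'
#' @param features Feature table with `intensity_<run>` columns.
#' @param blank_sample_ids Run ids of the blank samples.
#' @param detection_threshold Intensity above which a feature counts as
#'   detected in a blank (default 0).
#' @return The filtered feature table.
#' @export
filter_blanks <- function(features, blank_sample_ids,
                          detection_threshold = 0) {
  cols <- paste0("intensity_", blank_sample_ids)
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stop("unknown blank sample id(s): ",
         paste(sub("^intensity_", "", missing), collapse = ", "))
  }
  if (!length(cols)) return(features)
  in_blank <- Reduce(`|`, lapply(cols, function(cn)
    features[[cn]] > detection_threshold))
  features[!in_blank, , drop = FALSE]
}

#' Convert feature intensities to a presence/absence chemotype matrix
#'
#' An item (feature) is present in a strain's profile iff its peak intensity
#' is strictly greater than `intensity_threshold` (default 1e6, the
#' presence threshold used throughout the workflow; an intensity exactly at
#' the threshold is absent).
#'
#' @param features Feature table with `intensity_<run>` columns.
#' @param intensity_threshold Strict presence threshold (> 0).
#' @param sample_ids Optional subset/ordering of run ids; defaults to every
#'   `intensity_` column.
#' @return Binary integer matrix, strains (samples) in rows, features in
#'   columns.
#' @export
to_presence_absence <- function(features, intensity_threshold = 1e6,
                                sample_ids = NULL) {
  stopifnot(intensity_threshold > 0)
  all_ids <- sub("^intensity_", "", grep("^intensity_", names(features),
                                         value = TRUE))
  if (is.null(sample_ids)) sample_ids <- all_ids
  missing <- setdiff(sample_ids, all_ids)
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  m <- vapply(sample_ids, function(s)
    as.integer(features[[paste0("intensity_", s)]] > intensity_threshold),
    integer(nrow(features)))
  m <- t(matrix(m, nrow = nrow(features),
                dimnames = list(features$feature_id, sample_ids)))
  storage.mode(m) <- "integer"
  m
}

#' Jaccard distance between two binary profiles
#'
#' `1 - |A intersect B| / |A union B|` on the supports of two equal-length
#' binary vectors. Two empty profiles are defined to be at distance 0 (with
#' a warning), so that all-blank strains do not poison the matrix.
#'
#' @param row_a,row_b Binary (0/1) vectors of equal length.
#' @return Distance in \[0, 1\].
#' @export
jaccard_distance <- function(row_a, row_b) {
  if (length(row_a) != length(row_b)) {
    stop("profile length mismatch: ", length(row_a), " vs ", length(row_b))
  }
  a <- row_a > 0
  b <- row_b > 0
  un <- sum(a | b)
  if (un == 0) {
    warning("both profiles empty; Jaccard distance defined as 0")
    return(0)
  }
  1 - sum(a & b) / un
}

#' Pairwise Jaccard distance matrix of a presence/absence matrix
#'
#' @param presence Binary matrix, strains in rows.
#' @return Symmetric numeric matrix with zero diagonal and the strain ids
#'   as dimnames.
#' @export
jaccard_matrix <- function(presence) {
  n <- nrow(presence)
  d <- matrix(0, n, n, dimnames = list(rownames(presence),
                                       rownames(presence)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- jaccard_distance(presence[i, ], presence[j, ])
    }
  }
  d
}

# --- UPGMA ------------------------------------------------------------------

#' UPGMA (average-linkage) agglomeration
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the two
#' clusters at minimal distance; the distance from the merged cluster to any
#' other is the size-weighted arithmetic mean of its members' distances.
#' A merged node's height equals the merging distance itself (not d/2),
#' matching the height convention of `hclust(method = "average")`. Ties are
#' broken by the lexicographically smallest pair of cluster labels, a
#' cluster's label being its smallest member label, so the output is fully
#' deterministic.
#'
#' @param dist_matrix Symmetric nonnegative matrix with zero diagonal;
#'   dimnames supply the leaf labels (defaults to `L1..Ln`).
#' @return A `chem_dendro`: recursive list with elements `label`/`height`
#'   at leaves and `left`/`right`/`height` at internal nodes.
#' @export
upgma <- function(dist_matrix) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  stopifnot(n >= 2)
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be nonnegative")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  clusters <- lapply(labels, function(l)
    list(node = dendro_leaf(l), size = 1L, label = l))
  active <- rep(TRUE, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    # minimal distance with lexicographic tie-break on cluster labels
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        i <- idx[ii]; j <- idx[jj]
        lab <- sort(c(clusters[[i]]$label, clusters[[j]]$label))
        cand <- list(i = i, j = j, d = d[i, j], lab = lab)
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d &&
             (cand$lab[1] < best$lab[1] ||
              (cand$lab[1] == best$lab[1] && cand$lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    si <- clusters[[i]]$size; sj <- clusters[[j]]$size
    merged <- list(
      node = dendro_node(clusters[[i]]$node, clusters[[j]]$node,
                         height = best$d),
      size = si + sj,
      label = min(clusters[[i]]$label, clusters[[j]]$label)
    )
    for (k in which(active)) {
      if (k != i && k != j) {
        d[i, k] <- d[k, i] <- (si * d[i, k] + sj * d[j, k]) / (si + sj)
      }
    }
    clusters[[i]] <- merged
    active[j] <- FALSE
  }
  clusters[[which(active)]]$node
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance of two leaves is the height of their lowest
#' common ancestor; for an ultrametric tree it satisfies the three-point
#' condition max(d(x,z), d(y,z)) >= d(x,y).
#'
#' @param tree A `chem_dendro`.
#' @return Symmetric matrix over the leaf labels.
#' @export
cophenetic_matrix <- function(tree) {
  labs <- dendro_leaves(tree)
  d <- matrix(0, length(labs), length(labs),
              dimnames = list(labs, labs))
  fill <- function(node) {
    if (is_dendro_leaf(node)) return(node$label)
    l <- fill(node$left)
    r <- fill(node$right)
    d[l, r] <<- node$height
    d[r, l] <<- node$height
    c(l, r)
  }
  fill(tree)
  d
}

#' Chemical-dissimilarity dendrogram from a feature table
#'
#' The composed clustering stage: drop blank-derived features, binarise the
#' remaining intensities at the presence threshold, compute pairwise Jaccard
#' distances between strain chemotypes, and agglomerate by UPGMA.
#'
#' @param features Feature table with `intensity_<run>` columns.
#' @param blank_sample_ids Run ids of blank samples (may be empty).
#' @param config A [chem_config()]; `intensity_threshold` is used.
#' @param sample_ids Strain run ids to cluster (default: all non-blank).
#' @return A `chem_dendro`, with the Jaccard matrix in attribute
#'   `"distance"`.
#' @export
chemo_dendrogram <- function(features, blank_sample_ids = character(),
                             config = chem_config(), sample_ids = NULL) {
  kept <- filter_blanks(features, blank_sample_ids)
  all_ids <- sub("^intensity_", "", grep("^intensity_", names(kept),
                                         value = TRUE))
  if (is.null(sample_ids)) sample_ids <- setdiff(all_ids, blank_sample_ids)
  pa <- to_presence_absence(kept, config$intensity_threshold, sample_ids)
  d <- jaccard_matrix(pa)
  tree <- upgma(d)
  attr(tree, "distance") <- d
  tree
}
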