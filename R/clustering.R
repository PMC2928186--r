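# Cross-species tissue clustering: do homologous tissues of the two
# species pair up as nearest neighbours under a given distance measure?

#' Cross-species sample (tissue) distance matrix
#'
#' Restricts both expression matrices to the ortholog pairs (rows aligned
#' so row k of each matrix is the k-th pair), applies the per-gene
#' transform appropriate to the measure (relative expression for
#' `euclidean`/`correlation`, binarization for `binary_correlation`/`ga`)
#' to each species matrix, and then computes the chosen distance between
#' every pair of the 2T tissue-sample columns. Transforms are per gene
#' across tissues, so they are applied before column extraction.
#'
#' @param exprA,exprB linear-scale gene x tissue matrices for the two
#'   species.
#' @param pairs ortholog map (`species1`, `species2` columns).
#' @param measure,lambda as in [pairwise_distances()].
#' @param species labels for the two species used in the
#'   `tissue@species` sample names; defaults to the matrices'
#'   `species` attributes, falling back to `"species1"`/`"species2"`.
#' @return symmetric 2T x 2T matrix with zero diagonal and
#'   `tissue@species` dimnames.
#' @export
sample_distance_matrix <- function(exprA, exprB, pairs,
                                   measure = DISTANCE_MEASURES,
                                   lambda = NULL,
                                   species = NULL) {
  measure <- match.arg(measure)
  if (is.null(species))
    species <- c(attr(exprA, "species") %||% "species1",
                 attr(exprB, "species") %||% "species2")
  A <- exprA[pairs$species1, , drop = FALSE]
  B <- exprB[pairs$species2, , drop = FALSE]
  if (measure %in% c("euclidean", "correlation")) {
    A <- to_relative(A); B <- to_relative(B)
  } else {
    A <- to_binary(A); B <- to_binary(B)
  }
  cols <- cbind(A, B)
  labels <- c(paste0(colnames(exprA), "@", species[1]),
              paste0(colnames(exprB), "@", species[2]))
  ns <- ncol(cols)
  D <- matrix(0, ns, ns, dimnames = list(labels, labels))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      d <- switch(measure,
        euclidean = euclidean_distance(cols[, i], cols[, j]),
        correlation = correlation_distance(cols[, i], cols[, j]),
        binary_correlation = correlation_distance(cols[, i], cols[, j]),
        ga = ga_distance(cols[, i], cols[, j], lambda))
      if (is.na(d))
        stop("distance undefined between samples ", labels[i], " and ",
             labels[j], " (degenerate column)", call. = FALSE)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average-link (UPGMA-style) hierarchical clustering
#'
#' Agglomerates the samples of a dissimilarity matrix by repeatedly
#' merging the two closest clusters, with the distance between clusters
#' defined as the unweighted arithmetic mean of all cross-pair
#' dissimilarities (maintained by the exact size-weighted update). Ties
#' are broken deterministically by the lowest (smaller, larger) position
#' pair in the current cluster ordering, in which a merged cluster takes
#' the position of its first member, so trees are bit-reproducible.
#' Average-link merge heights are monotone non-decreasing.
#'
#' @param D symmetric non-negative matrix with zero diagonal and sample
#'   labels as dimnames.
#' @return an object of class `hclust` (merge, height, order, labels),
#'   usable with [stats::cutree()], [as_newick()] etc.
#' @export
average_link_cluster <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("`D` must be a square matrix", call. = FALSE)
  if (any(D < 0)) stop("negative dissimilarities", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12)) stop("`D` is not symmetric", call. = FALSE)
  if (any(diag(D) != 0)) stop("`D` must have a zero diagonal", call. = FALSE)
  ns <- nrow(D)
  if (ns < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- rownames(D) %||% as.character(seq_len(ns))

  # active clusters, in creation order; a merge takes its first member's slot
  id <- -seq_len(ns)          # hclust convention: negatives are leaves
  size <- rep(1L, ns)
  W <- D
  merge <- matrix(0L, ns - 1, 2)
  height <- numeric(ns - 1)

  for (step in seq_len(ns - 1)) {
    k <- length(id)
    U <- W
    U[lower.tri(U, diag = TRUE)] <- Inf
    hits <- which(U == min(U), arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], ]  # (smaller, larger) pair
    i <- hit[1]; j <- hit[2]
    height[step] <- W[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))

    # unweighted-average update: new cluster distance is the size-weighted
    # mean of the two members' distances to every other cluster
    newd <- (size[i] * W[i, ] + size[j] * W[j, ]) / (size[i] + size[j])
    W[i, ] <- newd
    W[, i] <- newd
    W[i, i] <- 0
    keep <- setdiff(seq_len(k), j)
    W <- W[keep, keep, drop = FALSE]
    id[i] <- step
    size[i] <- size[i] + size[j]
    id <- id[keep]
    size <- size[keep]
  }
  # average link guarantees monotone heights (up to float error in the
  # running averages); snap tiny inversions, fail loudly on real ones
  stopifnot(all(diff(height) >= -1e-8 * pmax(1, abs(height[-1]))))
  height <- cummax(height)

  tree <- structure(list(
    merge = merge, height = height,
    order = leaf_order(merge), labels = labels,
    method = "average", dist.method = "precomputed",
    call = match.call()
  ), class = "hclust")
  tree
}

# left-to-right leaf order from a merge matrix (for plotting/identity)
leaf_order <- function(merge) {
  expand <- function(node)
    if (node < 0) -node
    else c(expand(merge[node, 1]), expand(merge[node, 2]))
  expand(nrow(merge))
}

#' Count homologous tissues recovered as cherries
#'
#' A tissue is counted as correctly clustered when its two samples
#' `tissue@species1` and `tissue@species2` form a cherry (a two-leaf
#' clade) of the tree, i.e. are each other's nearest neighbours in the
#' agglomeration. This is the strict criterion: a tissue whose two
#' samples only share a larger clade (e.g. `((thymus@rat, spleen@rat),
#' thymus@human)` joined by `spleen@human`) scores 0.
#'
#' @param tree an `hclust` tree whose leaf labels have the form
#'   `tissue@species`, with exactly two species.
#' @return integer in \[0, T\]: the number of tissues whose two
#'   cross-species samples form a cherry.
#' @export
homologous_pairing_score <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  labs <- tree$labels
  parts <- strsplit(labs, "@", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("leaf labels must have the form tissue@species", call. = FALSE)
  tissue <- vapply(parts, `[[`, "", 1)
  species <- vapply(parts, `[[`, "", 2)
  if (length(unique(species)) != 2)
    stop("expected exactly two species in leaf labels", call. = FALSE)

  cherry_rows <- which(tree$merge[, 1] < 0 & tree$merge[, 2] < 0)
  score <- 0L
  for (r in cherry_rows) {
    a <- -tree$merge[r, 1]; b <- -tree$merge[r, 2]
    if (tissue[a] == tissue[b] && species[a] != species[b])
      score <- score + 1L
  }
  score
}

#' Export a clustering tree as a Newick string
#'
#' Converts the agglomeration tree to `ape`'s `phylo` representation
#' (branch lengths derived from merge heights, ultrametric) and renders
#' Newick text; [write_newick()] writes it to a file.
#'
#' @param tree an `hclust` object.
#' @return a single Newick string.
#' @export
as_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' @rdname as_newick
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
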