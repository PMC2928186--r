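# Independent oracles used to cross-check the implementation.

# Naive GA distance straight from the defining formula, with no shared
# code with the package: B is the plain power mean of the one-counts.
naive_ga <- function(u, v, lambda) {
  m <- sum(u); n <- sum(v); x <- sum(u * v)
  if (m == 0 || n == 0) return(NA_real_)
  B <- if (is.infinite(lambda) && lambda > 0) max(m, n)
  else if (is.infinite(lambda)) min(m, n)
  else if (lambda == 0) sqrt(m * n)
  else ((m^lambda + n^lambda) / 2)^(1 / lambda)
  1 - x / B
}

# All 255 nonzero binary vectors of length 8, as a matrix (rows).
all_binary8 <- function() {
  g <- as.matrix(expand.grid(rep(list(0:1), 8)))
  dimnames(g) <- NULL
  g[rowSums(g) > 0, , drop = FALSE]
}

# Naive average-link agglomerator: at every step recompute all
# cross-cluster mean dissimilarities from the original matrix, merge the
# closest pair with ties to the lowest (smaller, larger) position in the
# current cluster list (merged cluster takes the first member's slot).
# Returns the merge heights and the member sets merged at each step.
naive_average_link <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, list(merged))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Member sets merged at each step of an hclust tree, for comparison with
# the naive agglomerator.
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  members <- function(node)
    if (node < 0) -node else sets[[node]]
  for (r in seq_len(nrow(tree$merge))) {
    sets[[r]] <- sort(c(members(tree$merge[r, 1]),
                        members(tree$merge[r, 2])))
  }
  sets
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dissimilarity <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2)
  D <- D + t(D)
  rownames(D) <- colnames(D) <- paste0("s", seq_len(n))
  D
}

# Small default-model simulation for unit tests.
small_sim <- function(seed = 1, n_genes = 120, ...) {
  generate_paired_expression(
    synthetic_config(n_genes = n_genes, seed = seed, ...))
}
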