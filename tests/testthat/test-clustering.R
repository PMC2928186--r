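test_that("hand-worked three-sample agglomeration is reproduced", {
  D <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- average_link_cluster(D)
  expect_equal(tree$height, c(1, 10))
  expect_identical(sort(tree$merge[1, ]), c(-2L, -1L))
  expect_identical(hclust_merge_sets(tree)[[2]], 1:3)
})

test_that("equidistant samples merge at the common height throughout", {
  D <- matrix(0.7, 5, 5); diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("s", 1:5)
  tree <- average_link_cluster(D)
  expect_equal(tree$height, rep(0.7, 4))
})

test_that("agglomeration matches the naive re-averaging oracle", {
  set.seed(14)
  for (i in 1:30) {
    D <- random_dissimilarity(sample(6:10, 1))
    tree <- average_link_cluster(D)
    oracle <- naive_average_link(D)
    expect_equal(tree$height, oracle$heights)
    expect_identical(hclust_merge_sets(tree), oracle$merges)
  }
})

test_that("agglomeration agrees with stats::hclust average linkage", {
  set.seed(15)
  for (i in 1:10) {
    D <- random_dissimilarity(9)
    ours <- average_link_cluster(D)
    ref <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(ours$height, ref$height)
    expect_identical(hclust_merge_sets(ours), hclust_merge_sets(ref))
  }
})

test_that("merge heights are monotone and bad input is rejected", {
  set.seed(16)
  for (i in 1:20) {
    tree <- average_link_cluster(random_dissimilarity(8))
    expect_false(is.unsorted(tree$height))
  }
  D <- random_dissimilarity(4)
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- -0.1
  expect_error(average_link_cluster(Dn), "negative")
  Da <- D; Da[1, 2] <- Da[1, 2] + 1
  expect_error(average_link_cluster(Da), "symmetric")
})

test_that("sample distances match explicit column extraction", {
  sim <- small_sim(seed = 41, n_genes = 40, n_tissues = 4)
  for (ms in c("euclidean", "correlation", "binary_correlation", "ga")) {
    lam <- if (ms == "ga") 0 else NULL
    D <- sample_distance_matrix(sim$expr1, sim$expr2, sim$pairs, ms, lam)
    expect_identical(dim(D), c(8L, 8L))
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 8))
    tf <- if (ms %in% c("euclidean", "correlation")) to_relative
          else to_binary
    A <- tf(sim$expr1[sim$pairs$species1, ])
    B <- tf(sim$expr2[sim$pairs$species2, ])
    # spot-check a within-species and a cross-species entry
    fn <- switch(ms, euclidean = euclidean_distance,
                 ga = function(u, v) ga_distance(u, v, 0),
                 correlation_distance)
    expect_equal(D[1, 3], fn(A[, 1], A[, 3]))
    expect_equal(D[2, 4 + 3], fn(A[, 2], B[, 3]))
  }
})

test_that("a tissue and its exact copy are at distance zero everywhere", {
  sim <- small_sim(seed = 42, n_genes = 30)
  idp <- data.frame(species1 = rownames(sim$expr1),
                    species2 = rownames(sim$expr1))
  copy <- sim$expr1
  attr(copy, "species") <- "copy"
  for (ms in c("euclidean", "correlation", "binary_correlation", "ga")) {
    D <- sample_distance_matrix(sim$expr1, copy, idp, ms,
                                if (ms == "ga") Inf else NULL)
    nt <- ncol(sim$expr1)
    expect_equal(unname(D[cbind(1:nt, nt + 1:nt)]), rep(0, nt),
                 tolerance = 1e-12)
  }
})

test_that("sample distances are invariant to consistent gene reordering", {
  sim <- small_sim(seed = 43, n_genes = 50)
  D1 <- sample_distance_matrix(sim$expr1, sim$expr2, sim$pairs,
                               "correlation")
  perm <- sample(nrow(sim$pairs))
  D2 <- sample_distance_matrix(sim$expr1, sim$expr2, sim$pairs[perm, ],
                               "correlation")
  expect_equal(D1, D2)
})

test_that("cherry score counts exactly the homologous two-leaf clades", {
  # perfect recovery: T cherries
  lab <- function(t, s) paste0(t, "@", s)
  tiss <- paste0("t", 1:4)
  D <- matrix(1, 8, 8)
  nm <- c(lab(tiss, "h"), lab(tiss, "r"))
  dimnames(D) <- list(nm, nm)
  for (i in 1:4) D[i, 4 + i] <- D[4 + i, i] <- 0.05
  diag(D) <- 0
  perfect <- average_link_cluster(D)
  expect_identical(homologous_pairing_score(perfect), 4L)

  # caterpillar alternating species scores zero: build a chain
  Dc <- matrix(0, 6, 6)
  nmc <- c(lab("a", "h"), lab("a", "r"), lab("b", "h"),
           lab("b", "r"), lab("c", "h"), lab("c", "r"))
  dimnames(Dc) <- list(nmc, nmc)
  chain <- c(1, 3, 5, 2, 4, 6)  # join order: all @h first, then @r
  # chain distances: the k-th leaf joins the growing clade at 0.1 * k
  Dc[] <- 1
  for (i in seq_along(chain)) for (j in seq_along(chain)) {
    if (i != j) Dc[chain[i], chain[j]] <- 0.1 * max(i, j)
  }
  diag(Dc) <- 0
  cat_tree <- average_link_cluster(Dc)
  expect_identical(homologous_pairing_score(cat_tree), 0L)

  # the thymus/spleen error pattern: nested, no cherry for either tissue
  Dn <- matrix(1, 4, 4)
  nmn <- c(lab("thymus", "r"), lab("spleen", "r"),
           lab("thymus", "h"), lab("spleen", "h"))
  dimnames(Dn) <- list(nmn, nmn)
  Dn[1, 2] <- Dn[2, 1] <- 0.1
  Dn[1, 3] <- Dn[3, 1] <- 0.3; Dn[2, 3] <- Dn[3, 2] <- 0.3
  diag(Dn) <- 0
  nested <- average_link_cluster(Dn)
  expect_identical(hclust_merge_sets(nested),
                   list(1:2, 1:3, 1:4))
  expect_identical(homologous_pairing_score(nested), 0L)

  expect_error(homologous_pairing_score(
    average_link_cluster(matrix(c(0, 1, 1, 0), 2, 2,
                                dimnames = list(c("x", "y"),
                                                c("x", "y"))))),
    "tissue@species")
})

test_that("cherry score is invariant to sample-order rotation", {
  sim <- small_sim(seed = 44, n_genes = 60)
  D <- sample_distance_matrix(sim$expr1, sim$expr2, sim$pairs,
                              "correlation")
  s1 <- homologous_pairing_score(average_link_cluster(D))
  perm <- sample(nrow(D))
  s2 <- homologous_pairing_score(average_link_cluster(D[perm, perm]))
  expect_identical(s1, s2)
})

test_that("Newick export round-trips topology and heights", {
  sim <- small_sim(seed = 45, n_genes = 40)
  D <- sample_distance_matrix(sim$expr1, sim$expr2, sim$pairs, "euclidean")
  tree <- average_link_cluster(D)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- ape::read.tree(path)
  expect_identical(
    suppressWarnings(ape::dist.topo(ape::unroot(back),
                                    ape::unroot(ape::as.phylo(tree))))[1],
    0)
  expect_equal(sort(back$tip.label), sort(tree$labels))
  expect_equal(max(ape::node.depth.edgelength(back)),
               max(tree$height) / 2, tolerance = 1e-8)
})
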