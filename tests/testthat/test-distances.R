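test_that("Euclidean distance matches direct evaluation", {
  expect_equal(euclidean_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(euclidean_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(euclidean_distance(c(0.25, 0.75), c(0.5, 0.5)), sqrt(0.125))
  expect_error(euclidean_distance(1:3, 1:4), "mismatch")
})

test_that("correlation distance covers its range and undefined marker", {
  u <- c(1, 2, 3, 4)
  expect_equal(correlation_distance(u, 2 * u + 3), 0)
  expect_equal(correlation_distance(u, -u + 10), 2)
  expect_equal(correlation_distance(u, c(1, 3, 2, 4)), 0.2)
  expect_true(is.na(correlation_distance(c(1, 1, 1), c(1, 2, 3))))
})

test_that("correlation distance is invariant to positive affine rescaling", {
  set.seed(3)
  for (i in 1:20) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(correlation_distance(3 * u + 1, 0.2 * v - 5),
                 correlation_distance(u, v))
  }
})

test_that("GA distance reproduces the worked binary example", {
  u <- c(1, 1, 1, 0, 0, 0, 0, 0)
  v <- c(1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(ga_distance(u, v, -Inf), 0)       # Simpson: X = min(m, n)
  expect_equal(ga_distance(u, v, 1), 0.2)        # Dice
  expect_equal(ga_distance(u, v, Inf), 1 - 2 / 3)
  expect_equal(ga_distance(u, u, 7), 0)          # identity at any lambda
  w <- c(0, 0, 0, 1, 1, 0, 0, 0)                 # disjoint support
  expect_equal(ga_distance(u, w, -3), 1)
  expect_true(is.na(ga_distance(u, rep(0, 8), 1)))
  expect_error(ga_distance(u, c(2, v[-1]), 1), "binary")
})

test_that("GA agrees with the naive formula over the full enumeration", {
  vecs <- all_binary8()
  m <- rowSums(vecs)
  set.seed(11)
  idx <- cbind(sample(nrow(vecs), 400, replace = TRUE),
               sample(nrow(vecs), 400, replace = TRUE))
  for (lam in c(-Inf, -7, -2, 0, 0.5, 1, 3, 50, Inf)) {
    got <- apply(idx, 1, function(ij)
      ga_distance(vecs[ij[1], ], vecs[ij[2], ], lam))
    want <- apply(idx, 1, function(ij)
      naive_ga(vecs[ij[1], ], vecs[ij[2], ], lam))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= -1e-12 & got <= 1 + 1e-12))
  }
})

test_that("huge finite exponents approach the infinite limits without overflow", {
  vecs <- all_binary8()
  set.seed(12)
  idx <- cbind(sample(nrow(vecs), 200), sample(nrow(vecs), 200))
  for (s in c(-1, 1)) {
    d_lim <- apply(idx, 1, function(ij)
      ga_distance(vecs[ij[1], ], vecs[ij[2], ], s * Inf))
    d_big <- apply(idx, 1, function(ij)
      ga_distance(vecs[ij[1], ], vecs[ij[2], ], s * 1e7))
    expect_true(all(is.finite(d_big)))
    expect_lt(max(abs(d_big - d_lim)), 1e-6)
  }
})

test_that("all four measures are symmetric", {
  set.seed(4)
  u <- runif(8); v <- runif(8)
  bu <- rbinom(8, 1, 0.5); bv <- c(1, rbinom(7, 1, 0.5))
  bu[1] <- 1
  expect_identical(euclidean_distance(u, v), euclidean_distance(v, u))
  expect_identical(correlation_distance(u, v), correlation_distance(v, u))
  for (lam in c(-Inf, -2, 0, 1, 2, Inf))
    expect_identical(ga_distance(bu, bv, lam), ga_distance(bv, bu, lam))
})

test_that("pairwise_distances matches a scalar loop and preserves order", {
  sim <- small_sim(seed = 21, n_genes = 5)
  relA <- to_relative(sim$expr1); relB <- to_relative(sim$expr2)
  binA <- to_binary(sim$expr1); binB <- to_binary(sim$expr2)
  for (case in list(list("euclidean", relA, relB, NULL),
                    list("correlation", relA, relB, NULL),
                    list("binary_correlation", binA, binB, NULL),
                    list("ga", binA, binB, 2))) {
    d <- pairwise_distances(case[[2]], case[[3]], sim$pairs, case[[1]],
                            case[[4]])
    loop <- vapply(seq_len(5), function(k) {
      u <- case[[2]][sim$pairs$species1[k], ]
      v <- case[[3]][sim$pairs$species2[k], ]
      switch(case[[1]],
             euclidean = euclidean_distance(u, v),
             correlation = correlation_distance(u, v),
             binary_correlation = correlation_distance(u, v),
             ga = ga_distance(u, v, case[[4]]))
    }, 0)
    expect_identical(d$pairs$species1, sim$pairs$species1)
    expect_equal(d$pairs$distance, loop)
    expect_identical(nrow(d$excluded), 0L)
  }
})

test_that("identical matrices under identity pairing give all zeros", {
  sim <- small_sim(seed = 22, n_genes = 10)
  rel <- to_relative(sim$expr1)
  idp <- data.frame(species1 = rownames(rel), species2 = rownames(rel))
  for (ms in c("euclidean", "correlation")) {
    d <- pairwise_distances(rel, rel, idp, ms)
    expect_equal(d$pairs$distance, rep(0, nrow(d$pairs)), tolerance = 1e-12)
  }
})

test_that("undefined pairs are excluded and counted, unknown ids error", {
  relA <- rbind(g1 = c(0.5, 0.5), g2 = c(0.2, 0.8))
  relB <- rbind(h1 = c(0.5, 0.5), h2 = c(0.3, 0.7))
  pairs <- data.frame(species1 = c("g1", "g2"), species2 = c("h1", "h2"))
  d <- pairwise_distances(relA, relB, pairs, "correlation")
  # 2-tissue relative rows (0.5, 0.5) are constant: both pairs involve one
  expect_identical(nrow(d$pairs), 1L)
  expect_identical(nrow(d$excluded), 1L)
  expect_identical(d$excluded$species1, "g1")
  expect_error(pairwise_distances(relA, relB,
                                  data.frame(species1 = "gX",
                                             species2 = "h1"),
                                  "euclidean"), "gX")
})
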