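test_that("pairwise_euclidean satisfies metric axioms and a double-loop oracle", {
  expect_equal(pairwise_euclidean(rbind(c(1, 0), c(0, 1)))[1, 2], sqrt(2))
  expect_equal(pairwise_euclidean(rbind(c(2, 2), c(2, 2)))[1, 2], 0)
  withr::with_seed(21, {
    m <- matrix(rnorm(40), 10, 4)
    d <- pairwise_euclidean(m)
    ref <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) ref[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    expect_equal(unname(d), ref)
  })
})

test_that("ward linkage reproduces degenerate closed forms", {
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  dend <- ward_d2_linkage(pairwise_euclidean(two))
  expect_equal(dend$height, 5)   # two singletons merge at their distance
  same <- matrix(1, 4, 3)
  dend0 <- ward_d2_linkage(pairwise_euclidean(same))
  expect_equal(dend0$height, rep(0, 3))
  expect_error(ward_d2_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ward merge sequence and heights match the exhaustive coordinate oracle", {
  withr::with_seed(22, {
    for (case in 1:10) {
      n <- sample(4:8, 1)
      f <- sample(2:4, 1)
      m <- matrix(rnorm(n * f), n, f)
      dend <- ward_d2_linkage(pairwise_euclidean(m))
      oracle <- oracle_ward(m)
      sets <- dendrogram_merge_sets(dend)
      for (s in seq_along(oracle)) {
        expect_equal(sets[[s]], oracle[[s]]$members)
        expect_equal(dend$height[s], oracle[[s]]$height, tolerance = 1e-9)
      }
      # independent cross-check against the reference implementation
      ref <- stats::hclust(stats::dist(m), method = "ward.D2")
      expect_equal(dend$height, ref$height, tolerance = 1e-9)
    }
  })
})

test_that("tree cutting behaves at the extremes and k/h modes agree", {
  withr::with_seed(23, {
    m <- matrix(rnorm(60), 12, 5)
    dend <- ward_d2_linkage(pairwise_euclidean(m))
    expect_equal(unname(cut_dendrogram(dend, k = 1)), rep(1L, 12))
    expect_equal(unname(cut_dendrogram(dend, k = 12)), 1:12)
    expect_error(cut_dendrogram(dend, k = 13), "between 1 and")
    expect_error(cut_dendrogram(dend), "exactly one")
    hs <- sort(dend$height, decreasing = TRUE)
    for (k in 2:6) {
      h <- (hs[k - 1] + hs[k]) / 2
      expect_equal(cut_dendrogram(dend, k = k), cut_dendrogram(dend, h = h))
    }
    # labels are numbered by first-leaf order
    labs <- cut_dendrogram(dend, k = 4)
    expect_equal(unname(labs[1]), 1L)
    expect_equal(sort(unique(cummax(unname(labs)))), 1:4)
  })
})

test_that("lloyd k-means handles the closed-form extremes", {
  withr::with_seed(24, {
    m <- matrix(rnorm(30), 10, 3)
    all_k <- lloyd_kmeans(m, k = 10, seed = 1)
    expect_equal(all_k$wss, 0)
    expect_equal(sort(unname(all_k$labels)), 1:10)
    one <- lloyd_kmeans(m, k = 1, seed = 1)
    expect_equal(unname(one$centers[1, ]), unname(colMeans(m)))
    expect_equal(one$wss, sum(sweep(m, 2, colMeans(m))^2))
    # WSS invariant: equals recomputed assignment cost
    k3 <- lloyd_kmeans(m, k = 3, seed = 2)
    expect_equal(k3$wss,
                 sum((m - k3$centers[k3$labels, , drop = FALSE])^2))
    expect_true(all(tabulate(k3$labels, 3) > 0))
  })
})

test_that("k-means separates well-separated blobs in every seeded run", {
  withr::with_seed(25, {
    truth <- rep(1:2, each = 20)
    m <- matrix(rnorm(80, sd = 1), 40, 2)
    m[truth == 2, ] <- m[truth == 2, ] + 10   # 10-sigma separation
  })
  aris <- vapply(1:200, function(s) {
    adjusted_rand(lloyd_kmeans(m, 2, seed = s, n_init = 2)$labels, truth)
  }, numeric(1))
  expect_equal(aris, rep(1, 200))
})

test_that("hybrid hkmeans refines its hierarchical initialization deterministically", {
  withr::with_seed(26, {
    m <- matrix(rnorm(200), 40, 5)
  })
  a <- hybrid_hkmeans(m, 5)
  b <- hybrid_hkmeans(m, 5)
  expect_identical(a$labels, b$labels)
  expect_identical(a$wss, b$wss)
  expect_lte(a$wss, partition_wss(m, a$hierarchical_labels))

  withr::with_seed(27, {
    truth <- rep(1:2, each = 15)
    blobs <- matrix(rnorm(60), 30, 2) + 10 * (truth - 1)
  })
  hier <- cut_dendrogram(ward_d2_linkage(pairwise_euclidean(blobs)), k = 2)
  hyb <- hybrid_hkmeans(blobs, 2)$labels
  km <- lloyd_kmeans(blobs, 2, seed = 1)$labels
  expect_equal(adjusted_rand(hier, truth), 1)
  expect_equal(adjusted_rand(hyb, truth), 1)
  expect_equal(adjusted_rand(km, truth), 1)
})

test_that("clustering is invariant to feature column permutation", {
  withr::with_seed(28, {
    m <- matrix(rnorm(120), 20, 6)
    perm <- sample(6)
  })
  d1 <- ward_d2_linkage(pairwise_euclidean(m))
  d2 <- ward_d2_linkage(pairwise_euclidean(m[, perm]))
  expect_equal(d1$merge, d2$merge)
  expect_equal(d1$height, d2$height)
  k1 <- lloyd_kmeans(m, 3, seed = 9)
  k2 <- lloyd_kmeans(m[, perm], 3, seed = 9)
  expect_equal(k1$labels, k2$labels)
})

test_that("purity and ARI match exhaustive counting oracles", {
  classes <- c("a", "a", "b", "b", "c")
  expect_equal(cluster_purity(classes, classes)$purity, 1)
  expect_equal(cluster_purity(rep(1, 5), classes)$purity, 2 / 5)
  expect_error(cluster_purity(integer(0), character(0)), "Empty")

  expect_equal(adjusted_rand(1:5, 1:5), 1)
  withr::with_seed(29, {
    for (i in 1:20) {
      a <- sample(1:3, 12, replace = TRUE)
      b <- sample(1:4, 12, replace = TRUE)
      expect_equal(adjusted_rand(a, b), oracle_ari(a, b), tolerance = 1e-12)
      p <- cluster_purity(a, b)
      manual <- sum(apply(table(a, b), 1, max)) / 12
      expect_equal(p$purity, manual)
    }
  })
})

test_that("ARI is centred at zero under random label permutations", {
  withr::with_seed(30, {
    base <- rep(1:4, each = 10)
    aris <- vapply(1:1000, function(i) {
      adjusted_rand(base, sample(base))
    }, numeric(1))
  })
  expect_lt(abs(mean(aris)), 0.01)
})
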