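# GAP-statistic homogeneity rule and approximate-Dunn k selection.

test_that("within-cluster dispersion matches hand arithmetic", {
  same <- matrix(1, 10, 3)
  expect_equal(withinDispersion(same, rep(1L, 10), "euclidean"), 0)
  m <- matrix(c(0, 2, 10, 14, 0, 0, 0, 0), ncol = 2)
  expect_equal(withinDispersion(m, seq_len(4), "euclidean"), 0)  # singletons
  # clusters {(0,0),(2,0)} and {(10,0),(14,0)}: centroids (1,0),(12,0)
  expect_equal(withinDispersion(m, c(1L, 1L, 2L, 2L), "euclidean"),
               1 + 1 + 2 + 2)
})

test_that("GAP is near zero for uniform data and favours the true split", {
  set.seed(12)
  m <- matrix(runif(400 * 4), 400, 4)
  g1 <- gapStatistic(m, 1, nReference = 20, rngSeed = 3, metric = "euclidean")
  expect_lt(abs(g1$gap), 3 * g1$se)  # reference distribution == data
  expect_equal(g1$logW, log(withinDispersion(m, rep(1L, 400), "euclidean")))

  blobs <- makeBlobs(200, rbind(c(0, 0), c(12, 0)), seed = 4)
  gap1 <- gapStatistic(blobs$m, 1, nReference = 10, rngSeed = 5,
                       metric = "euclidean")
  gap2 <- gapStatistic(blobs$m, 2, nReference = 10, rngSeed = 5,
                       metric = "euclidean")
  expect_gt(gap2$gap, gap1$gap)
})

test_that("GAP standard error shrinks with the reference count", {
  set.seed(13)
  m <- matrix(runif(200 * 3), 200, 3)
  ses <- vapply(c(5, 10, 50), function(B) {
    gapStatistic(m, 2, nReference = B, rngSeed = 7, metric = "euclidean")$se
  }, numeric(1))
  expect_lt(ses[3], ses[1])
})

test_that("the homogeneity vote separates one blob from two", {
  cfg <- fastConfig(distance = "euclidean", subsampleSize = 250L,
                    nSubsamples = 10L, gapNReference = 8L,
                    applyGlobalAbundanceFilter = FALSE)
  one <- makeBlobs(500, matrix(0, 1, 20), seed = 31)
  d1 <- isHomogeneous(one$m, cfg, rngSeed = 1L)
  expect_true(d1@homogeneous)
  two <- makeBlobs(250, rbind(rep(0, 20), c(6, rep(0, 19))), seed = 32)
  d2 <- isHomogeneous(two$m, cfg, rngSeed = 1L)
  expect_false(d2@homogeneous)
  # small data: the subsample is the full dataset, decision is reproducible
  d1b <- isHomogeneous(one$m, cfg, rngSeed = 1L)
  expect_identical(d1b@votesHomogeneous, d1@votesHomogeneous)
})

test_that("approximate Dunn matches hand arithmetic and degenerates to Inf", {
  m <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 10), c(11, 10), c(10, 11))
  lab <- c(0L, 0L, 0L, 1L, 1L, 1L)
  cents <- rowsum(m, lab + 1) / 3
  split <- new("SplitResult", labels = lab, centroids = cents, k = 2L,
               nIter = 1L, dunn = NA_real_)
  num <- sqrt(sum((cents[1, ] - cents[2, ])^2))
  dists <- sqrt(rowSums((m - cents[lab + 1, ])^2))
  den <- 2 * max(tapply(dists, lab, mean))
  expect_equal(dunnIndex(m, split, "euclidean"), num / den)

  sing <- new("SplitResult", labels = 0:1, centroids = rbind(c(0, 0), c(5, 5)),
              k = 2L, nIter = 1L, dunn = NA_real_)
  expect_identical(dunnIndex(rbind(c(0, 0), c(5, 5)), sing, "euclidean"), Inf)
  expect_error(dunnIndex(m, new("SplitResult", labels = rep(0L, 6),
                                centroids = cents[1, , drop = FALSE], k = 1L,
                                nIter = 1L, dunn = NA_real_), "euclidean"),
               "two clusters")
})

test_that("approximate Dunn orders separations like the exact Dunn", {
  seps <- seq(1, 8, length.out = 8)
  approx <- exact <- numeric(length(seps) * 2)
  i <- 0
  for (sep in seps) for (r in 1:2) {
    i <- i + 1
    blobs <- makeBlobs(100, rbind(rep(0, 10), c(sep, rep(0, 9))),
                       seed = 100 * r + round(sep * 10))
    lab <- blobs$labels - 1L
    cents <- rowsum(blobs$m, lab + 1) / 100
    split <- new("SplitResult", labels = lab, centroids = cents, k = 2L,
                 nIter = 1L, dunn = NA_real_)
    approx[i] <- dunnIndex(blobs$m, split, "euclidean")
    exact[i] <- exactDunn(blobs$m, lab + 1)
  }
  expect_gte(cor(approx, exact, method = "spearman"), 0.8)
  expect_gt(approx[length(approx)], approx[1])  # far > overlapping
})

test_that("selectK recovers the planted number of clusters", {
  cfg <- divikPreset("oscc", minClusterSize = 30L, subsampleSize = 200L,
                     maxK = 7L, rngSeed = 3L)
  for (k in 2:5) {
    h <- hierarchySplit(lapply(rep(150, k), hierarchyLeaf),
                        nInformative = 30, effect = 1)
    g <- generateHierarchy(h, nNoiseFeatures = 170, seed = 13 * k)
    sub <- abundances(g$matrix)[, varianceFilter(g$matrix, 0.01)@mask]
    sel <- selectK(sub, cfg, rngSeed = 17L)
    expect_identical(sel$selection@bestK, as.integer(k))
    expect_gte(adjustedRand(sel$split@labels, g$leafLabels), 0.95)
  }
})

test_that("selectK is invariant to duplicating the data", {
  h <- hierarchySplit(lapply(rep(120, 3), hierarchyLeaf),
                      nInformative = 30, effect = 1)
  g <- generateHierarchy(h, nNoiseFeatures = 170, seed = 39)
  sub <- abundances(g$matrix)[, varianceFilter(g$matrix, 0.01)@mask]
  cfg <- divikPreset("oscc", minClusterSize = 30L, subsampleSize = 200L,
                     maxK = 5L, rngSeed = 3L)
  a <- selectK(sub, cfg, rngSeed = 17L)
  b <- selectK(sub[rep(seq_len(nrow(sub)), 2), ], cfg, rngSeed = 17L)
  expect_identical(b$selection@bestK, a$selection@bestK)
})

test_that("maxK = 2 yields k = 2 for heterogeneous data", {
  blobs <- makeBlobs(150, rbind(rep(0, 5), c(10, rep(0, 4))), seed = 21)
  cfg <- fastConfig(distance = "euclidean", maxK = 2L, subsampleSize = 100L)
  sel <- selectK(blobs$m, cfg, rngSeed = 2L)
  expect_identical(sel$selection@bestK, 2L)
})
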