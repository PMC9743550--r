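# GMM-based feature filtering: log statistics, mixture fitting, crossing
# points, abundance and variance filters.

test_that("log feature statistics match textbook formulas", {
  m <- matrix(c(10, 10, 10, 1, 2, 3), nrow = 3)
  expect_equal(logFeatureStats(m, "mean")[1], 1)  # log10 of 10
  expect_identical(logFeatureStats(m, "variance")[1], -Inf)  # zero variance
  col <- c(1, 2, 3, 4)
  # two-pass sample variance as independent oracle
  oracle <- sum((col - mean(col))^2) / (length(col) - 1)
  expect_equal(logFeatureStats(matrix(col, ncol = 1), "variance")[1],
               log10(oracle))
  expect_error(logFeatureStats(matrix(1, 1, 2), "variance"), "two")
})

test_that("BIC selects the generating component count", {
  set.seed(11)
  oneMode <- rnorm(1000)
  expect_identical(fitGmm1d(oneMode)@nComponents, 1L)
  twoMode <- c(rnorm(500, 0), rnorm(500, 10))
  g <- fitGmm1d(twoMode)
  expect_identical(g@nComponents, 2L)
  # quantile-split oracle for the component means
  split <- sort(twoMode)
  expect_equal(g@means[1], mean(split[1:500]), tolerance = 0.05)
  expect_equal(g@means[2], mean(split[501:1000]), tolerance = 0.05)
  expect_equal(sum(g@weights), 1)
  expect_error(fitGmm1d(rep(3, 100)), "degenerate")
  expect_error(fitGmm1d(1:5), "10")
})

test_that("tiny components are discarded and weights renormalised", {
  set.seed(4)
  x <- c(rnorm(2000, 0, 0.5), rnorm(8, 30, 0.5))  # 0.4% outlier mode
  g <- fitGmm1d(x)
  expect_true(all(g@componentShares >= 0.01))
  expect_true(all(g@means < 10))  # the outlier mode is gone
  expect_equal(sum(g@weights), 1)
})

test_that("crossing points sit at equal weighted density", {
  sym <- new("GaussianMixture1D", weights = c(.5, .5), means = c(-1, 1),
             sds = c(1, 1), nComponents = 2L, bic = 0,
             componentShares = c(.5, .5))
  expect_equal(crossingThresholds(sym), 0, tolerance = 1e-8)
  single <- new("GaussianMixture1D", weights = 1, means = 0, sds = 1,
                nComponents = 1L, bic = 0, componentShares = 1)
  expect_identical(crossingThresholds(single), numeric(0))
  g <- new("GaussianMixture1D", weights = c(.7, .3), means = c(0, 5),
           sds = c(1, 2), nComponents = 2L, bic = 0,
           componentShares = c(.7, .3))
  expect_equal(crossingThresholds(g), gridCrossing(.7, 0, 1, .3, 5, 2),
               tolerance = 1e-3)
})

test_that("thresholds strictly increase and lie between their means", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    means <- sort(rnorm(k, sd = 6))
    while (min(diff(means)) < 0.8) means <- sort(rnorm(k, sd = 6))
    g <- new("GaussianMixture1D",
             weights = as.vector(prop.table(runif(k, 0.2, 1))),
             means = means, sds = runif(k, 0.3, 1.2),
             nComponents = as.integer(k), bic = 0,
             componentShares = rep(1 / k, k))
    thr <- crossingThresholds(g)
    expect_length(thr, k - 1L)
    expect_true(all(diff(thr) > 0))
    expect_true(all(thr > means[-k] & thr < means[-1]))
  }
})

test_that("abundance filter removes the planted noise floor", {
  nf <- generateNoiseFloor(150, 600, lowModeFraction = 0.3,
                           separation = 3, seed = 1)
  flt <- abundanceFilter(nf$matrix)
  expect_gte(sum(!flt@mask & nf$lowMode) / sum(nf$lowMode), 0.95)
  expect_lte(sum(!flt@mask & !nf$lowMode) / sum(!nf$lowMode), 0.05)
  # grid-scan oracle agrees with the applied threshold
  g <- flt@model
  i <- which.max(diff(g@means))  # widest gap hosts the noise/signal split
  expect_equal(flt@thresholds[1],
               gridCrossing(g@weights[1], g@means[1], g@sds[1],
                            g@weights[2], g@means[2], g@sds[2]),
               tolerance = 1e-3)
})

test_that("unimodal abundance keeps everything, zero columns never survive", {
  uni <- generateNoiseFloor(100, 300, lowModeFraction = 0, seed = 2)
  expect_true(all(abundanceFilter(uni$matrix)@mask))
  vals <- abundances(uni$matrix)
  vals[, 7] <- 0
  flt <- abundanceFilter(AbundanceMatrix(vals))
  expect_false(flt@mask[7])
})

test_that("variance filter walks down the thresholds to honour the bound", {
  set.seed(9)
  n <- 60
  # three variance modes: 20 very high (2%, survives the 1%-share rule but
  # falls short of the 5% retention bound), 200 mid, 780 low
  sds <- c(rep(1000, 20), rep(31.6, 200), rep(1, 780))
  m <- matrix(rnorm(n * 1000), n, 1000) *
    matrix(sds, n, 1000, byrow = TRUE)
  flt <- varianceFilter(m, minFeatureFraction = 0.05)  # needs >= 50
  expect_gte(sum(flt@mask), 50)
  expect_lte(sum(flt@mask), 300)      # second topmost threshold, not all
  expect_lt(flt@chosenThreshold, max(flt@thresholds))

  # topmost component large enough: topmost threshold is used directly
  sds2 <- c(rep(1000, 100), rep(1, 900))
  m2 <- matrix(rnorm(n * 1000), n, 1000) *
    matrix(sds2, n, 1000, byrow = TRUE)
  flt2 <- varianceFilter(m2, minFeatureFraction = 0.01)
  expect_equal(flt2@chosenThreshold, max(flt2@thresholds))
  expect_equal(sum(flt2@mask), 100, tolerance = 0.1)
})

test_that("single-component variance model keeps all features", {
  set.seed(3)
  m <- matrix(rnorm(50 * 200), 50, 200)
  flt <- varianceFilter(m, minFeatureFraction = 0.01)
  expect_true(all(flt@mask))
})

test_that("filters are invariant to global intensity scaling", {
  nf <- generateNoiseFloor(80, 400, lowModeFraction = 0.25, seed = 6)
  a1 <- abundanceFilter(nf$matrix)
  v1 <- varianceFilter(nf$matrix, 0.02)
  scaled <- AbundanceMatrix(7 * abundances(nf$matrix))
  a2 <- abundanceFilter(scaled)
  v2 <- varianceFilter(scaled, 0.02)
  expect_equal(a2@statistic, a1@statistic + log10(7))
  expect_equal(v2@statistic, v1@statistic + 2 * log10(7))
  expect_identical(a2@mask, a1@mask)
  expect_identical(v2@mask, v1@mask)
})

test_that("masks are never empty and respect the minimum fraction", {
  set.seed(14)
  for (rep in 1:5) {
    nf <- generateNoiseFloor(40, 150, lowModeFraction = runif(1, 0, 0.6),
                             seed = rep)
    flt <- varianceFilter(nf$matrix, minFeatureFraction = 0.05)
    expect_gte(sum(flt@mask), 1)
    if (!is.null(flt@model) && flt@model@nComponents > 1L) {
      expect_gte(sum(flt@mask), ceiling(0.05 * 150))
    }
  }
})
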