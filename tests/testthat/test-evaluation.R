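# Quality scoring: adjusted Rand, greedy Dice, label normalisation,
# overall quality, rank aggregation.

test_that("adjusted Rand matches brute-force pair counting", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(5, 5, 7, 7)), 1)
  expect_equal(adjustedRand(rep(1, 6), c(1, 2, 3, 1, 2, 3)), 0)
  a <- c(0, 0, 1, 1)
  b <- c(0, 1, 1, 1)
  expect_equal(adjustedRand(a, b), ariBrute(a, b))
  set.seed(17)
  for (rep in 1:10) {
    x <- sample(1:4, 25, replace = TRUE)
    y <- sample(1:3, 25, replace = TRUE)
    expect_equal(adjustedRand(x, y), ariBrute(x, y))
    expect_equal(adjustedRand(x, y), adjustedRand(y, x))
    perm <- sample(4)
    expect_equal(adjustedRand(perm[x], y), adjustedRand(x, y))
    # independent reference implementation
    expect_equal(adjustedRand(x, y), mclust::adjustedRandIndex(x, y))
  }
  expect_error(adjustedRand(1:3, 1:4), "length")
})

test_that("greedy Dice selection finds the documented optimum", {
  # cluster B: 2 obs, both in the 10-obs ROI; A: 9 obs, 8 in; C: 5 obs, 0 in
  clusters <- c(rep(2L, 2), rep(1L, 9), rep(3L, 5))
  roi <- c(rep(TRUE, 2), rep(TRUE, 8), FALSE, rep(FALSE, 5))
  res <- greedyDiceSelection(clusters, roi)
  expect_setequal(res$selected, c(1L, 2L))
  expect_equal(res$dice, 20 / 21)
  expect_equal(res$dice, diceExhaustive(clusters, roi))

  exact <- greedyDiceSelection(rep(1L, 4), rep(TRUE, 4))
  expect_equal(exact$dice, 1)
  none <- greedyDiceSelection(c(1L, 2L), c(FALSE, FALSE))
  expect_identical(none$selected, integer(0))
  expect_equal(none$dice, 0)
})

test_that("greedy Dice equals the exhaustive optimum on random instances", {
  set.seed(23)
  for (rep in 1:40) {
    k <- sample(3:8, 1)
    n <- 60
    clusters <- sample(seq_len(k), n, replace = TRUE)
    roi <- runif(n) < runif(1, 0.2, 0.6)
    expect_equal(greedyDiceSelection(clusters, roi)$dice,
                 diceExhaustive(clusters, roi))
  }
})

test_that("label normalisation resolves claims as documented", {
  # disjoint claims map directly, unclaimed clusters become "other"
  clusters <- c(rep(1L, 10), rep(2L, 10), rep(3L, 10))
  roi <- c(rep("tumour", 10), rep("epithelium", 10), rep("other", 10))
  mapping <- normalizeLabels(clusters, roi, c("tumour", "epithelium"))
  expect_identical(mapping[["1"]], "tumour")
  expect_identical(mapping[["2"]], "epithelium")
  expect_identical(mapping[["3"]], "other")

  allOther <- normalizeLabels(clusters, rep("other", 30),
                              c("tumour", "epithelium"))
  expect_true(all(allOther == "other"))
})

test_that("multi-claim resolution maximises the adjusted Rand", {
  # cluster 2 straddles tumour and epithelium and is claimed by both
  clusters <- c(rep(1L, 8), rep(2L, 8), rep(3L, 8))
  roi <- c(rep("tumour", 8), rep("tumour", 5), rep("epithelium", 3),
           rep("epithelium", 8))
  mapping <- normalizeLabels(clusters, roi, c("tumour", "epithelium"))
  # exhaustive scenario oracle
  best <- NULL
  bestAri <- -Inf
  for (choice in c("tumour", "epithelium")) {
    trial <- c("1" = "tumour", "2" = choice, "3" = "epithelium")
    ari <- adjustedRand(trial[as.character(clusters)], roi)
    if (ari > bestAri) {
      bestAri <- ari
      best <- trial
    }
  }
  expect_identical(mapping, best)
})

test_that("overall-quality distances reproduce the published arithmetic", {
  a <- overallQuality(0.5433, 0.7372, 1.0000)
  expect_equal(a$d000, 1.3560, tolerance = 1e-4)
  expect_equal(a$d111, 0.5269, tolerance = 1e-4)
  b <- overallQuality(0.7035, 0.8672, 0.6977)
  expect_equal(b$d000, 1.3167, tolerance = 1e-4)
  expect_equal(b$d111, 0.4438, tolerance = 1e-4)
  z <- overallQuality(0, 0, 0)
  expect_equal(z$d000, 0)
  expect_equal(z$d111, sqrt(3))
})

test_that("the two overall-quality distances satisfy the algebraic identity", {
  set.seed(29)
  for (rep in 1:20) {
    x <- runif(3)
    oq <- overallQuality(x[1], x[2], x[3])
    expect_equal(oq$d000^2 + oq$d111^2,
                 3 - 2 * sum(x) + 2 * sum(x^2))
  }
})

test_that("rank aggregation reproduces fractional tie ranks", {
  expect_equal(rankSummary(matrix(c(3, 1, 2), ncol = 1))$ranks[, 1],
               c(1, 3, 2))
  one <- rankSummary(matrix(c(0.4, 0.9, 0.1), nrow = 1))
  expect_true(all(one$ranks == 1))
  expect_equal(unname(one$sums), 3)

  tab <- read.csv(system.file("extdata", "oscc_quality_indices.csv",
                              package = "divikr"))
  rk <- rankSummary(as.matrix(tab[, c("ari", "dice", "exims")]),
                    higherIsBetter = TRUE)
  expect_equal(unname(rk$ranks[, 1]), tab$ari_rank)
  expect_equal(unname(rk$ranks[, 2]), tab$dice_rank)
  expect_equal(unname(rk$ranks[, 3]), tab$exims_rank)
  expect_equal(unname(rk$sums), tab$rank_sum)
})

test_that("segmentation evaluation composes the pieces", {
  clusters <- c(rep(1L, 12), rep(2L, 12), rep(3L, 6))
  roi <- c(rep("tumour", 12), rep("epithelium", 12), rep("other", 6))
  rep1 <- evaluateSegmentation(clusters, roi, c("tumour", "epithelium"),
                               relativeExims = 1)
  expect_equal(rep1@adjustedRand, 1)
  expect_equal(unname(rep1@dicePerRoi["tumour"]), 1)
  expect_equal(rep1@d000, sqrt(3))
  expect_equal(rep1@d111, 0)
})
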