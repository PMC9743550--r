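# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive (brute force, grid scans, O(n^2) definitions) and stay
# independent of the implementation paths they check.

# Gaussian blobs around given centers (one row per center), unit noise.
makeBlobs <- function(nPerBlob, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  lab <- rep(seq_len(k), each = nPerBlob)
  m <- centers[lab, , drop = FALSE] +
    matrix(rnorm(length(lab) * ncol(centers), sd = sd),
           nrow = length(lab))
  list(m = m, labels = lab)
}

# Fast configuration for desk-scale fixtures.
fastConfig <- function(distance = "correlation", maxK = 5L,
                       minClusterSize = 30L, subsampleSize = 200L,
                       nSubsamples = 6L, gapNReference = 6L,
                       rngSeed = 1L, ...) {
  DivikConfig(distance = distance, maxK = maxK,
              minClusterSize = minClusterSize,
              subsampleSize = subsampleSize, nSubsamples = nSubsamples,
              gapNReference = gapNReference, rngSeed = rngSeed, ...)
}

# Brute-force adjusted Rand: enumerate all observation pairs.
ariBrute <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sameA <- a[i] == a[j]
    sameB <- b[i] == b[j]
    if (sameA && sameB) s11 <- s11 + 1
    else if (!sameA && !sameB) s00 <- s00 + 1
    else if (sameA) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  # expected/max index in pair-count form
  a1 <- s11 + s10
  b1 <- s11 + s01
  expected <- a1 * b1 / total
  maxIdx <- (a1 + b1) / 2
  if (abs(maxIdx - expected) < 1e-12) return(if (s11 == maxIdx) 1 else 0)
  (s11 - expected) / (maxIdx - expected)
}

# Dense grid scan for the equal-density point between two weighted normals.
gridCrossing <- function(w1, m1, s1, w2, m2, s2, step = 1e-4) {
  x <- seq(m1, m2, by = step)
  d <- abs(w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2))
  x[which.min(d)]
}

# Exhaustive multi-cluster Dice optimum over all cluster subsets.
diceExhaustive <- function(clusters, roiMask) {
  ids <- sort(unique(clusters))
  R <- sum(roiMask)
  if (R == 0) return(0)
  size <- vapply(ids, function(c) sum(clusters == c), numeric(1))
  inter <- vapply(ids, function(c) sum(roiMask & clusters == c), numeric(1))
  best <- 0
  for (mask in 0:(2^length(ids) - 1)) {
    sel <- bitwAnd(bitwShiftR(mask, seq_along(ids) - 1L), 1L) == 1L
    d <- 2 * sum(inter[sel]) / (sum(size[sel]) + R)
    if (d > best) best <- d
  }
  best
}

# Exact O(n^2) Dunn index: min inter-cluster pair distance over max
# cluster diameter.
exactDunn <- function(m, labels, metric = "euclidean") {
  D <- if (metric == "correlation") 1 - cor(t(m)) else as.matrix(dist(m))
  labs <- sort(unique(labels))
  num <- Inf
  den <- 0
  for (a in labs) {
    ia <- which(labels == a)
    if (length(ia) > 1) den <- max(den, max(D[ia, ia]))
    for (b in labs[labs > a]) {
      num <- min(num, min(D[ia, which(labels == b)]))
    }
  }
  if (den == 0) Inf else num / den
}

# The two-level planted hierarchy used for recovery tests: three top-level
# groups, the middle one carrying a sub-split.
twoLevelHierarchy <- function(nTop1 = 2000, nSub = 1000, nTop3 = 1000,
                              nInformative = 25, effect = 1) {
  hierarchySplit(list(
    hierarchyLeaf(nTop1),
    hierarchySplit(list(hierarchyLeaf(nSub), hierarchyLeaf(nSub)),
                   nInformative = nInformative, effect = effect),
    hierarchyLeaf(nTop3)
  ), nInformative = nInformative, effect = effect)
}
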