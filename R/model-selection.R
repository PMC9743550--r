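# Stop rule (two-trial GAP homogeneity vote) and approximate-Dunn selection
# of the number of clusters, both estimated on subsamples.

#' Total within-cluster dispersion
#'
#' \eqn{W = \sum_c \sum_{i \in c} d(x_i, \bar x_c)} under the configured
#' metric, with centroids taken as arithmetic means of cluster members.
#'
#' @param m numeric matrix or [AbundanceMatrix-class].
#' @param labels integer cluster labels (any coding), one per row; all
#'   clusters must be non-empty.
#' @param metric `"correlation"` or `"euclidean"`.
#' @return a nonnegative number.
#' @export
withinDispersion <- function(m, labels,
                             metric = c("correlation", "euclidean")) {
  m <- .valuesOf(m)
  metric <- match.arg(metric)
  lab <- match(labels, sort(unique(labels)))
  k <- max(lab)
  centroids <- rowsum(m, lab, reorder = TRUE) / tabulate(lab, k)
  dimnames(centroids) <- NULL
  d <- .distToCentroids(m, centroids, metric)
  sum(d[cbind(seq_len(nrow(m)), lab)])
}

# Cluster a matrix at a given k with the deterministic pipeline:
# KD-tree compression, percentile seeding, Lloyd.  k = 1 needs no seeding.
.clusterAtK <- function(m, k, metric, leafFraction, percentile,
                        boxes = NULL) {
  n <- nrow(m)
  if (k == 1L) {
    centroid <- matrix(colMeans(m), nrow = 1L)
    return(new("SplitResult", labels = rep(0L, n), centroids = centroid,
               k = 1L, nIter = 1L, dunn = NA_real_))
  }
  if (is.null(boxes)) boxes <- kdtreeCompress(m, leafFraction)
  k <- min(k, nrow(boxes@centroids))
  seeds <- selectSeeds(boxes, k, percentile, metric)
  kmeansFit(m, seeds, metric)
}

#' GAP statistic at a fixed number of clusters
#'
#' Compares the log within-cluster dispersion of the data partition at `k`
#' to its expectation under `nReference` reference datasets drawn uniformly
#' within the per-feature bounds of `m`, each clustered by the same
#' deterministic seeding + K-means pipeline at the same `k`:
#' \deqn{gap(k) = mean_b \log W^*_b - \log W,}
#' with standard error \eqn{sd_b(\log W^*_b)\sqrt{1 + 1/B}}.  A zero
#' dispersion is guarded by \eqn{\log(W + 10^{-12})} (and reported via a
#' message).
#'
#' @param m numeric matrix or [AbundanceMatrix-class].
#' @param k number of clusters, at least 1.
#' @param nReference number of reference datasets.
#' @param rngSeed seed for reference sampling (the clustering itself is
#'   deterministic).
#' @param metric `"correlation"` or `"euclidean"`.
#' @param leafFraction,percentile seeding-pipeline parameters.
#' @return `list(gap =, se =, logW =, logWRef =)`.
#' @export
gapStatistic <- function(m, k, nReference = 10L, rngSeed = 0L,
                         metric = c("correlation", "euclidean"),
                         leafFraction = 0.01, percentile = 99) {
  m <- .valuesOf(m)
  metric <- match.arg(metric)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  .noteCounter("maxGapN", nrow(m))
  safeLog <- function(w) {
    if (w <= 0) {
      message("zero within-cluster dispersion; using log(W + 1e-12)")
      log(w + 1e-12)
    } else log(w)
  }
  split <- .clusterAtK(m, k, metric, leafFraction, percentile)
  logW <- safeLog(withinDispersion(m, split@labels, metric))
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  n <- nrow(m)
  p <- ncol(m)
  logWRef <- .withSeed(rngSeed, {
    vapply(seq_len(nReference), function(b) {
      ref <- matrix(stats::runif(n * p, min = rep(lo, each = n),
                                 max = rep(hi, each = n)), nrow = n)
      rsplit <- .clusterAtK(ref, k, metric, leafFraction, percentile)
      safeLog(withinDispersion(ref, rsplit@labels, metric))
    }, numeric(1))
  })
  list(gap = mean(logWRef) - logW,
       se = stats::sd(logWRef) * sqrt(1 + 1 / nReference),
       logW = logW, logWRef = logWRef)
}

#' Two-trial GAP homogeneity test
#'
#' Draws `cfg@nSubsamples` subsamples of `cfg@subsampleSize` observations
#' without replacement (or all rows when fewer are available), computes the
#' GAP statistic at k = 1 and k = 2 on each, and lets each subsample vote
#' "homogeneous" when `gap(1) >= gap(2)`.  The region is declared
#' homogeneous on a strict majority of votes.
#'
#' @param m numeric matrix or [AbundanceMatrix-class]: the observations of
#'   the region, already restricted to its locally selected features.
#' @param cfg a [DivikConfig-class].
#' @param rngSeed seed of this decision (defaults to `cfg@rngSeed`); the
#'   recursion passes a node-specific derivation.
#' @return a [GapDecision-class].
#' @export
isHomogeneous <- function(m, cfg, rngSeed = cfg@rngSeed) {
  m <- .valuesOf(m)
  stopifnot(is(cfg, "DivikConfig"))
  n <- nrow(m)
  size <- min(n, cfg@subsampleSize)
  g1 <- numeric(cfg@nSubsamples)
  g2 <- numeric(cfg@nSubsamples)
  for (s in seq_len(cfg@nSubsamples)) {
    subSeed <- .deriveSeed(rngSeed, s)
    idx <- if (size < n) {
      .withSeed(subSeed, sample.int(n, size, replace = FALSE))
    } else seq_len(n)
    sub <- m[idx, , drop = FALSE]
    g1[s] <- gapStatistic(sub, 1L, cfg@gapNReference,
                          rngSeed = .deriveSeed(subSeed, 1L),
                          metric = cfg@distance,
                          leafFraction = cfg@kdtreeLeafFraction,
                          percentile = cfg@seedPercentile)$gap
    g2[s] <- gapStatistic(sub, 2L, cfg@gapNReference,
                          rngSeed = .deriveSeed(subSeed, 2L),
                          metric = cfg@distance,
                          leafFraction = cfg@kdtreeLeafFraction,
                          percentile = cfg@seedPercentile)$gap
  }
  votes <- sum(g1 >= g2)
  new("GapDecision", gapK1 = mean(g1), gapK2 = mean(g2),
      votesHomogeneous = as.integer(votes),
      nSubsamples = cfg@nSubsamples,
      homogeneous = votes > cfg@nSubsamples / 2)
}

#' Approximate (centroid-based) Dunn index
#'
#' Separation over extent, using centroids so the cost stays O(nk):
#' numerator = the minimum metric distance between cluster centroids;
#' denominator = the maximum over clusters of twice the mean member
#' distance to the own centroid.  Returns `Inf` when the denominator is
#' zero (all clusters collapsed to points).  Higher is better.
#'
#' @param m numeric matrix or [AbundanceMatrix-class].
#' @param split a [SplitResult-class] with `k >= 2`.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param rows optional row subset on which the member extents are
#'   evaluated (clusters unrepresented in the subset are dropped from the
#'   denominator); used for subsampled evaluation.
#' @return a nonnegative number, possibly `Inf`.
#' @export
dunnIndex <- function(m, split, metric = c("correlation", "euclidean"),
                      rows = NULL) {
  m <- .valuesOf(m)
  metric <- match.arg(metric)
  stopifnot(is(split, "SplitResult"))
  if (split@k < 2L) stop("Dunn index needs at least two clusters",
                         call. = FALSE)
  centroids <- split@centroids
  cd <- .distToCentroids(centroids, centroids, metric)
  num <- min(cd[upper.tri(cd)])
  lab <- split@labels + 1L
  if (is.null(rows)) rows <- seq_len(nrow(m))
  .noteCounter("maxDunnEvalN", length(rows))
  sub <- m[rows, , drop = FALSE]
  slab <- lab[rows]
  d <- .distToCentroids(sub, centroids, metric)
  own <- d[cbind(seq_len(nrow(sub)), slab)]
  meanOwn <- vapply(seq_len(split@k), function(c) {
    members <- slab == c
    if (!any(members)) NA_real_ else mean(own[members])
  }, numeric(1))
  den <- 2 * max(meanOwn, na.rm = TRUE)
  if (den == 0) Inf else num / den
}

#' Select the number of subclusters by subsampled approximate Dunn
#'
#' For each candidate `k` in `2..cfg@maxK`, seeds deterministically, runs
#' K-means on the full node data, and scores the partition by the mean
#' approximate Dunn index over `cfg@nSubsamples` subsampled evaluations
#' (all rows when the node is no larger than a subsample).  The best `k`
#' maximises the mean Dunn, ties broken towards the smallest `k`.
#'
#' @param m numeric matrix or [AbundanceMatrix-class] (node data in its
#'   locally selected feature space).
#' @param cfg a [DivikConfig-class].
#' @param rngSeed seed for subsample draws (defaults to `cfg@rngSeed`).
#' @param boxes optional precomputed [BoxSummary-class] of `m`.
#' @return `list(selection = KSelection, split = SplitResult)` for the best
#'   `k`, or `NULL` when no candidate produced a valid split.
#' @export
selectK <- function(m, cfg, rngSeed = cfg@rngSeed, boxes = NULL) {
  m <- .valuesOf(m)
  stopifnot(is(cfg, "DivikConfig"))
  n <- nrow(m)
  if (is.null(boxes)) boxes <- kdtreeCompress(m, cfg@kdtreeLeafFraction)
  maxK <- min(cfg@maxK, nrow(boxes@centroids), n)
  if (maxK < 2L) return(NULL)
  candidates <- 2:maxK
  dunnMeans <- rep(NA_real_, length(candidates))
  splits <- vector("list", length(candidates))
  size <- min(n, cfg@subsampleSize)
  for (i in seq_along(candidates)) {
    k <- candidates[i]
    seeds <- selectSeeds(boxes, k, cfg@seedPercentile, cfg@distance)
    split <- kmeansFit(m, seeds, cfg@distance)
    if (length(unique(split@labels)) < k) {
      message("k = ", k, ": split produced an empty cluster; skipped")
      next
    }
    if (size < n) {
      vals <- vapply(seq_len(cfg@nSubsamples), function(s) {
        idx <- .withSeed(.deriveSeed(rngSeed, 100000L + 100L * k + s),
                         sample.int(n, size, replace = FALSE))
        dunnIndex(m, split, cfg@distance, rows = idx)
      }, numeric(1))
      dunnMeans[i] <- mean(vals)
    } else {
      dunnMeans[i] <- dunnIndex(m, split, cfg@distance)
    }
    split@dunn <- dunnMeans[i]
    splits[[i]] <- split
  }
  if (all(is.na(dunnMeans))) return(NULL)
  best <- which(dunnMeans >= max(dunnMeans, na.rm = TRUE) - 0)[1L]
  list(selection = new("KSelection",
                       candidateK = as.integer(candidates),
                       dunnValues = dunnMeans,
                       bestK = as.integer(candidates[best])),
       split = splits[[best]])
}

setMethod("show", "GapDecision", function(object) {
  cat("GapDecision:",
      if (object@homogeneous) "homogeneous" else "heterogeneous",
      sprintf("(%d/%d votes; mean gap k=1: %.4f, k=2: %.4f)\n",
              object@votesHomogeneous, object@nSubsamples,
              object@gapK1, object@gapK2))
})

setMethod("show", "KSelection", function(object) {
  cat("KSelection: best k =", object@bestK, "\n")
  print(data.frame(k = object@candidateK,
                   meanDunn = round(object@dunnValues, 4)))
})
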