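# Distance functions, KD-tree data compression, deterministic percentile
# seeding and Lloyd's K-means under the configured metric.

#' Correlation distance between two vectors
#'
#' `1 - Pearson correlation`, in `[0, 2]`.  Insensitive to multiplicative
#' intensity scaling, which makes it the metric of choice for spectra.
#'
#' @param a,b numeric vectors of equal length, at least 3, neither constant.
#' @return a number in `[0, 2]`.
#' @export
correlationDistance <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3L) stop("vectors must have length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate (constant) vector has no defined correlation distance",
         call. = FALSE)
  }
  1 - stats::cor(a, b)
}

# Rows centred and scaled to unit L2 norm, so that tcrossprod of two such
# matrices is the Pearson correlation.  Constant rows get a zero row and
# are flagged; any distance involving them is defined as 2 (maximally
# dissimilar).
.rowUnitCenter <- function(m) {
  mu <- rowMeans(m)
  z <- m - mu
  nrm <- sqrt(rowSums(z * z))
  zero <- nrm < 1e-300
  nrm[zero] <- 1
  list(z = z / nrm, zero = zero)
}

# n x k matrix of distances from rows of m to rows of centroids.
.distToCentroids <- function(m, centroids, metric) {
  if (metric == "correlation") {
    zm <- .rowUnitCenter(m)
    zc <- .rowUnitCenter(centroids)
    d <- 1 - tcrossprod(zm$z, zc$z)
    if (any(zm$zero)) d[zm$zero, ] <- 2
    if (any(zc$zero)) d[, zc$zero] <- 2
    d[d < 0] <- 0
    d
  } else {
    cross <- tcrossprod(m, centroids)
    d2 <- outer(rowSums(m * m), rowSums(centroids * centroids), "+") -
      2 * cross
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
}

#' Compress a dataset into KD-tree boxes
#'
#' Builds a KD-tree over the observations, splitting on the widest-spread
#' dimension at its median until each leaf holds at most
#' `ceiling(leafFraction * n_obs)` points.  Each leaf becomes a "box"
#' summarised by its centroid and member count; the weighted mean of box
#' centroids equals the global mean exactly.
#'
#' @param m numeric matrix or [AbundanceMatrix-class] (rows =
#'   observations), already restricted to the locally selected features.
#' @param leafFraction leaf capacity as a fraction of `n_obs`, in (0, 1].
#' @return a [BoxSummary-class].
#' @export
kdtreeCompress <- function(m, leafFraction) {
  m <- .valuesOf(m)
  n <- nrow(m)
  if (n == 0L) stop("cannot compress an empty matrix", call. = FALSE)
  stopifnot(leafFraction > 0, leafFraction <= 1)
  cap <- max(1L, ceiling(leafFraction * n))
  leaves <- vector("list", 0L)
  nLeaves <- 0L
  push <- function(idx) {
    nLeaves <<- nLeaves + 1L
    leaves[[nLeaves]] <<- idx
  }
  recurse <- function(idx) {
    if (length(idx) <= cap) {
      push(idx)
      return(invisible(NULL))
    }
    sub <- m[idx, , drop = FALSE]
    lo <- apply(sub, 2L, min)
    hi <- apply(sub, 2L, max)
    dimn <- which.max(hi - lo)
    if (hi[dimn] - lo[dimn] <= 0) {  # all points identical: cannot split
      push(idx)
      return(invisible(NULL))
    }
    v <- sub[, dimn]
    med <- stats::median(v)
    left <- v <= med
    if (all(left)) left <- v < med
    if (!any(left) || all(left)) {
      push(idx)
      return(invisible(NULL))
    }
    recurse(idx[left])
    recurse(idx[!left])
    invisible(NULL)
  }
  recurse(seq_len(n))
  leaves <- leaves[seq_len(nLeaves)]
  box <- integer(n)
  for (i in seq_along(leaves)) box[leaves[[i]]] <- i
  weights <- lengths(leaves)
  centroids <- rowsum(m, box, reorder = TRUE) / weights
  dimnames(centroids) <- NULL
  new("BoxSummary", centroids = centroids, weights = as.integer(weights),
      memberIndex = leaves)
}

#' Deterministic percentile seeding from KD-tree boxes
#'
#' Seed 1 is the box centroid sitting at the requested percentile of the
#' weighted CDF of box-centroid distances from the global data centroid
#' (a "moderately outlying" box).  Seed 2 repeats the procedure with
#' distances measured from seed 1, excluding seed 1's box.  Each further
#' seed is taken at the percentile of the Euclidean orthogonal distance to
#' the affine subspace spanned by the seeds found so far (a line for two
#' seeds, then hyperplanes), excluding already-used boxes.  The procedure
#' is fully deterministic.
#'
#' @param boxes a [BoxSummary-class].
#' @param k number of seeds, at most the number of boxes.
#' @param percentile CDF percentile in (0, 100].
#' @param metric `"correlation"` or `"euclidean"`; used for the
#'   centroid/seed distances of seeds 1 and 2 (subspace distances are
#'   Euclidean by construction).
#' @return a [SeedSet-class].
#' @export
selectSeeds <- function(boxes, k, percentile,
                        metric = c("correlation", "euclidean")) {
  stopifnot(is(boxes, "BoxSummary"))
  metric <- match.arg(metric)
  cents <- boxes@centroids
  w <- boxes@weights
  nBoxes <- nrow(cents)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  if (k > nBoxes) {
    stop("cannot select ", k, " seeds from ", nBoxes, " boxes", call. = FALSE)
  }
  if (percentile <= 0 || percentile > 100) {
    stop("percentile must be in (0, 100]", call. = FALSE)
  }
  globalCentroid <- colSums(cents * w) / sum(w)
  chosen <- integer(k)
  avail <- rep(TRUE, nBoxes)

  pickAt <- function(d) {
    idx <- which(avail)
    idx[.weightedPercentileIndex(d[idx], w[idx], percentile)]
  }

  d1 <- .distToCentroids(cents, matrix(globalCentroid, nrow = 1L), metric)[, 1L]
  chosen[1L] <- pickAt(d1)
  avail[chosen[1L]] <- FALSE

  if (k >= 2L) {
    d2 <- .distToCentroids(
      cents, cents[chosen[1L], , drop = FALSE], metric)[, 1L]
    chosen[2L] <- pickAt(d2)
    avail[chosen[2L]] <- FALSE
  }

  if (k >= 3L) {
    for (j in 3:k) {
      origin <- cents[chosen[1L], ]
      basis <- t(cents[chosen[2:(j - 1L)], , drop = FALSE]) - origin
      qrd <- qr(basis)
      rank <- qrd$rank
      v <- sweep(cents, 2L, origin)
      d2sub <- rowSums(v * v)
      if (rank > 0L) {
        q <- qr.Q(qrd)[, seq_len(rank), drop = FALSE]
        proj <- v %*% q
        d2sub <- d2sub - rowSums(proj * proj)
      }
      dists <- sqrt(pmax(d2sub, 0))
      if (max(dists[avail]) < 1e-12) {
        # all remaining boxes lie (numerically) in the seed subspace:
        # fall back to the distance to the nearest existing seed
        dn <- .distToCentroids(
          cents, cents[chosen[seq_len(j - 1L)], , drop = FALSE], metric)
        dists <- apply(dn, 1L, min)
      }
      chosen[j] <- pickAt(dists)
      avail[chosen[j]] <- FALSE
    }
  }
  new("SeedSet", seeds = cents[chosen, , drop = FALSE],
      sourceBoxes = chosen, percentile = percentile)
}

#' K-means from explicit seeds
#'
#' Standard Lloyd iterations under the configured metric: assignment to the
#' nearest centroid, centroid update by the arithmetic mean of members.
#' Stops when no label changes or after `maxIter` iterations.  A cluster
#' emptied during assignment is repaired by reseeding its centroid at the
#' observation currently farthest from its assigned centroid (at most `k`
#' repairs per iteration), so no empty cluster is ever returned.  Fully
#' deterministic given the seeds.
#'
#' @param m numeric matrix or [AbundanceMatrix-class].
#' @param seeds a [SeedSet-class] or a `k x n_feat` matrix of start
#'   centroids.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param maxIter iteration cap.
#' @return a [SplitResult-class] with 0-based labels.
#' @export
kmeansFit <- function(m, seeds, metric = c("correlation", "euclidean"),
                      maxIter = 300L) {
  m <- .valuesOf(m)
  metric <- match.arg(metric)
  centroids <- if (is(seeds, "SeedSet")) seeds@seeds else as.matrix(seeds)
  k <- nrow(centroids)
  n <- nrow(m)
  if (k > n) stop("more seeds than observations", call. = FALSE)
  .noteCounter("maxKmeansN", n)
  labels <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- .distToCentroids(m, centroids, metric)
    newLabels <- max.col(-d, ties.method = "first")
    counts <- tabulate(newLabels, nbins = k)
    repairs <- 0L
    while (any(counts == 0L) && repairs < k) {
      e <- which(counts == 0L)[1L]
      own <- d[cbind(seq_len(n), newLabels)]
      own[counts[newLabels] <= 1L] <- -Inf  # do not empty another cluster
      far <- which.max(own)
      centroids[e, ] <- m[far, ]
      counts[newLabels[far]] <- counts[newLabels[far]] - 1L
      newLabels[far] <- e
      counts[e] <- 1L
      d[, e] <- .distToCentroids(m, centroids[e, , drop = FALSE], metric)[, 1L]
      repairs <- repairs + 1L
    }
    converged <- identical(newLabels, labels)
    labels <- newLabels
    centroids <- rowsum(m, labels, reorder = TRUE) / tabulate(labels, k)
    dimnames(centroids) <- NULL
    if (converged || iter >= maxIter) break
  }
  new("SplitResult", labels = labels - 1L, centroids = centroids,
      k = as.integer(k), nIter = iter, dunn = NA_real_)
}
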