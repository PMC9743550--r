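# Segmentation quality against annotated regions of interest: label
# normalisation, multi-cluster Dice, adjusted Rand, overall-quality
# distances and rank aggregation.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table.  When the expected index equals the maximum index
#' (e.g. one partition has a single cluster), the value is 1 for identical
#' partitions and 0 otherwise.
#'
#' @param a,b two labelings of the same observations (any atomic coding).
#' @return a number in `[-1, 1]`.
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nPairs <- choose(sum(tab), 2)
  expected <- ai * bj / nPairs
  maxIndex <- (ai + bj) / 2
  if (abs(maxIndex - expected) < .Machine$double.eps * max(1, maxIndex)) {
    return(if (nij == maxIndex) 1 else 0)
  }
  (nij - expected) / (maxIndex - expected)
}

#' Greedy multi-cluster Dice selection for one region
#'
#' Clusters are sorted by the fraction of their area covered by the region
#' (descending, ties towards the smaller cluster label) and added
#' sequentially; a cluster is kept only if adding it strictly increases the
#' Dice coefficient between the growing union and the region,
#' \eqn{Dice = 2|U \cap R| / (|U| + |R|)}.
#'
#' @param clusters integer cluster labels, one per observation.
#' @param roiMask logical vector marking the region's observations.
#' @return `list(selected =, dice =)`: the retained cluster labels and the
#'   final Dice value (empty selection and 0 for an empty region).
#' @export
greedyDiceSelection <- function(clusters, roiMask) {
  stopifnot(length(clusters) == length(roiMask))
  roiMask <- as.logical(roiMask)
  R <- sum(roiMask)
  if (R == 0L) return(list(selected = integer(0), dice = 0))
  ids <- sort(unique(clusters))
  size <- vapply(ids, function(c) sum(clusters == c), numeric(1))
  inter <- vapply(ids, function(c) sum(roiMask & clusters == c), numeric(1))
  ord <- order(-(inter / size), ids)
  selected <- integer(0)
  unionInter <- 0
  unionSize <- 0
  dice <- 0
  for (i in ord) {
    newDice <- 2 * (unionInter + inter[i]) / (unionSize + size[i] + R)
    if (newDice > dice) {
      dice <- newDice
      unionInter <- unionInter + inter[i]
      unionSize <- unionSize + size[i]
      selected <- c(selected, ids[i])
    }
  }
  list(selected = sort(selected), dice = dice)
}

#' Normalise cluster labels against annotated regions
#'
#' The reannotation procedure: every region (in the caller-supplied
#' priority order) claims the clusters retained by its greedy Dice
#' selection.  Clusters claimed by exactly one region are assigned to it;
#' clusters claimed by several regions are resolved by enumerating the
#' assignment scenarios and keeping the one that maximises the adjusted
#' Rand index between the induced labeling and the region annotation;
#' unclaimed clusters map to `"other"`.  The enumeration is capped at
#' 100,000 scenarios (with a warning) for pathological claim structures.
#'
#' @param clusters integer cluster labels, one per observation.
#' @param roi character region name per observation (`NA` or names outside
#'   `roiNames` count as `"other"`).
#' @param roiNames region processing order (priority; e.g. tumour first).
#'   Defaults to the order of first appearance.
#' @return named character vector: cluster label to region name or
#'   `"other"`.
#' @export
normalizeLabels <- function(clusters, roi, roiNames = NULL) {
  stopifnot(length(clusters) == length(roi))
  roi <- as.character(roi)
  if (is.null(roiNames)) {
    roiNames <- unique(roi[!is.na(roi) & roi != "other"])
  }
  roiRef <- ifelse(is.na(roi) | !(roi %in% roiNames), "other", roi)
  ids <- sort(unique(clusters))
  claims <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (r in roiNames) {
    sel <- greedyDiceSelection(clusters, roiRef == r)$selected
    for (c in sel) {
      key <- as.character(c)
      claims[[key]] <- c(claims[[key]], r)
    }
  }
  mapping <- stats::setNames(rep("other", length(ids)), as.character(ids))
  nClaims <- lengths(claims)
  single <- nClaims == 1L
  mapping[single] <- vapply(claims[single], `[[`, character(1), 1L)
  multi <- which(nClaims > 1L)
  if (length(multi)) {
    options <- claims[multi]
    nScen <- prod(lengths(options))
    cap <- 1e5
    if (nScen > cap) {
      warning("scenario enumeration capped at ", format(cap, scientific = FALSE),
              " of ", format(nScen), " scenarios", call. = FALSE)
      nScen <- cap
    }
    radices <- lengths(options)
    bestAri <- -Inf
    bestChoice <- NULL
    key <- as.character(clusters)
    for (s in seq_len(nScen) - 1L) {
      digits <- integer(length(radices))
      rem <- s
      for (j in seq_along(radices)) {
        digits[j] <- rem %% radices[j]
        rem <- rem %/% radices[j]
      }
      trial <- mapping
      for (j in seq_along(multi)) {
        trial[multi[j]] <- options[[j]][digits[j] + 1L]
      }
      ari <- adjustedRand(trial[key], roiRef)
      if (ari > bestAri) {
        bestAri <- ari
        bestChoice <- trial
      }
    }
    mapping <- bestChoice
  }
  mapping
}

#' Overall-quality distances of a quality triplet
#'
#' Treats `(ARI, Dice, relative EXIMS)` as a point in the unit cube (each
#' coordinate clipped to `[0, 1]`) and returns its Euclidean distance from
#' the origin (`d000`; higher is better) and from the ideal point
#' `(1, 1, 1)` (`d111`; lower is better).
#'
#' @param ari adjusted Rand index.
#' @param dice Dice coefficient of the primary region.
#' @param exims relative spatial-structure score in `[0, 1]` (supplied
#'   externally; this package does not compute it).
#' @return `list(d000 =, d111 =)`.
#' @examples
#' overallQuality(0.5433, 0.7372, 1.0000)
#' @export
overallQuality <- function(ari, dice, exims) {
  x <- pmin(pmax(c(ari, dice, exims), 0), 1)
  list(d000 = sqrt(sum(x^2)), d111 = sqrt(sum((1 - x)^2)))
}

#' Evaluate a segmentation against region annotations
#'
#' Runs the label normalisation, then scores the normalised labeling:
#' adjusted Rand against the annotation, per-region Dice of the assigned
#' cluster unions, and the two overall-quality distances built from
#' `(ARI, Dice of the primary region, relative EXIMS)`.
#'
#' @param clusters integer cluster labels per observation.
#' @param roi character region name per observation.
#' @param roiNames region priority order; the first entry is the primary
#'   region used in the overall-quality triplet.
#' @param relativeExims externally supplied structure score (clipped to
#'   `[0, 1]`; defaults to 1, the convention for degenerate single-cluster
#'   maps).
#' @return a [QualityReport-class].
#' @export
evaluateSegmentation <- function(clusters, roi, roiNames = NULL,
                                 relativeExims = 1) {
  roi <- as.character(roi)
  if (is.null(roiNames)) {
    roiNames <- unique(roi[!is.na(roi) & roi != "other"])
  }
  roiRef <- ifelse(is.na(roi) | !(roi %in% roiNames), "other", roi)
  mapping <- normalizeLabels(clusters, roiRef, roiNames)
  normalized <- mapping[as.character(clusters)]
  ari <- adjustedRand(normalized, roiRef)
  dice <- vapply(roiNames, function(r) {
    assigned <- normalized == r
    inRoi <- roiRef == r
    denom <- sum(assigned) + sum(inRoi)
    if (denom == 0L) 0 else 2 * sum(assigned & inRoi) / denom
  }, numeric(1))
  exims <- min(max(relativeExims, 0), 1)
  oq <- overallQuality(ari, dice[[1L]], exims)
  new("QualityReport", adjustedRand = ari, dicePerRoi = dice,
      relativeExims = exims, d000 = oq$d000, d111 = oq$d111,
      clusterRoiMap = mapping)
}

#' Rank aggregation across methods and criteria
#'
#' Per-criterion ranks with average-rank tie handling (tied entries share
#' the mean of their rank positions, so fractional ranks such as 2.5 or
#' 19.5 arise naturally), plus the per-method rank sums; lower sums are
#' better.
#'
#' @param scores numeric matrix, methods in rows, criteria in columns.
#' @param higherIsBetter logical, one per criterion (recycled).
#' @return `list(ranks =, sums =)`.
#' @export
rankSummary <- function(scores, higherIsBetter = TRUE) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("scores must not contain missing values",
                          call. = FALSE)
  higherIsBetter <- rep_len(higherIsBetter, ncol(scores))
  ranks <- scores
  for (j in seq_len(ncol(scores))) {
    v <- if (higherIsBetter[j]) -scores[, j] else scores[, j]
    ranks[, j] <- rank(v, ties.method = "average")
  }
  list(ranks = ranks, sums = rowSums(ranks))
}

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport\n")
  cat(sprintf("  adjusted Rand: %.4f\n", object@adjustedRand))
  for (r in names(object@dicePerRoi)) {
    cat(sprintf("  Dice [%s]: %.4f\n", r, object@dicePerRoi[[r]]))
  }
  cat(sprintf("  relative EXIMS: %.4f (supplied)\n", object@relativeExims))
  cat(sprintf("  overall quality d(0,0,0): %.4f   d(1,1,1): %.4f\n",
              object@d000, object@d111))
})
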