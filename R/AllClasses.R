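#' @import methods
NULL

setClassUnion("matrixOrNULL", members = c("matrix", "NULL"))

#' AbundanceMatrix: observations-by-features abundance data
#'
#' Container for a dense nonnegative matrix of peak/feature abundances, one
#' row per observation (e.g. one MSI spectrum per pixel) and one column per
#' feature (e.g. one m/z peak), with unique observation and feature
#' identifiers and optional integer pixel coordinates.
#'
#' @slot values numeric matrix, `n_obs x n_feat`, nonnegative, no missing
#'   values.
#' @slot featureIds character vector of unique feature identifiers
#'   (length `n_feat`).
#' @slot obsIds character vector of unique observation identifiers
#'   (length `n_obs`).
#' @slot coords optional integer matrix of pixel coordinates
#'   (`n_obs x d`, `d` of 2 or 3), or `NULL`.
#'
#' @seealso [AbundanceMatrix()] for construction, [readMatrix()] and
#'   [writeMatrix()] for file input/output.
#' @export
setClass("AbundanceMatrix",
  representation(
    values = "matrix",
    featureIds = "character",
    obsIds = "character",
    coords = "matrixOrNULL"
  )
)

setValidity("AbundanceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) {
    msg <- c(msg, "'values' must be a numeric matrix")
  } else {
    if (anyNA(v)) msg <- c(msg, "'values' must not contain missing values")
    if (!anyNA(v) && any(v < 0)) {
      msg <- c(msg, "abundances must be nonnegative")
    }
  }
  if (length(object@featureIds) != ncol(v)) {
    msg <- c(msg, "length of 'featureIds' must equal ncol(values)")
  }
  if (anyDuplicated(object@featureIds)) {
    msg <- c(msg, "'featureIds' must be unique")
  }
  if (length(object@obsIds) != nrow(v)) {
    msg <- c(msg, "length of 'obsIds' must equal nrow(values)")
  }
  if (anyDuplicated(object@obsIds)) {
    msg <- c(msg, "'obsIds' must be unique")
  }
  if (!is.null(object@coords)) {
    if (nrow(object@coords) != nrow(v)) {
      msg <- c(msg, "'coords' must have one row per observation")
    }
    if (!ncol(object@coords) %in% c(2L, 3L)) {
      msg <- c(msg, "'coords' must have 2 or 3 columns")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DivikConfig: parameters of a divisive segmentation run
#'
#' All tunables of [divikFit()] and its building blocks.  The two published
#' parameterisations are available via [divikPreset()].
#'
#' @slot distance distance between observations: `"correlation"`
#'   (1 - Pearson) or `"euclidean"`.
#' @slot maxK maximum number of clusters swept on each segmentation level.
#' @slot minClusterSize nodes with fewer observations are never split.
#' @slot minFeatureFraction lower bound on the fraction of the feature pool
#'   that the local variance filter must retain, in (0, 1].
#' @slot kdtreeLeafFraction KD-tree leaf capacity as a fraction of the node
#'   size (compression factor of the seeding stage).
#' @slot seedPercentile percentile of the box-distance CDF used to pick each
#'   seed, in (0, 100].
#' @slot nSubsamples number of subsamples drawn for GAP / Dunn estimation.
#' @slot subsampleSize number of observations per subsample.
#' @slot gapNReference number of uniform reference datasets per GAP value.
#' @slot rngSeed master seed; every stochastic step derives its own stream
#'   from it, so runs are reproducible.
#' @slot applyGlobalAbundanceFilter whether the one-off global noise filter
#'   on log mean abundance is applied at the root.
#' @slot maxLeafSizeStop optional size (observations): clusters at or below
#'   it are not split further (`NA` disables the rule).
#' @slot maxDepth recursion depth guard.
#' @export
setClass("DivikConfig",
  representation(
    distance = "character",
    maxK = "integer",
    minClusterSize = "integer",
    minFeatureFraction = "numeric",
    kdtreeLeafFraction = "numeric",
    seedPercentile = "numeric",
    nSubsamples = "integer",
    subsampleSize = "integer",
    gapNReference = "integer",
    rngSeed = "integer",
    applyGlobalAbundanceFilter = "logical",
    maxLeafSizeStop = "integer",
    maxDepth = "integer"
  )
)

setValidity("DivikConfig", function(object) {
  msg <- character(0)
  if (!object@distance %in% c("correlation", "euclidean")) {
    msg <- c(msg, "'distance' must be \"correlation\" or \"euclidean\"")
  }
  if (object@maxK < 1L) msg <- c(msg, "'maxK' must be positive")
  if (object@minClusterSize < 2L) msg <- c(msg, "'minClusterSize' must be >= 2")
  if (object@minFeatureFraction <= 0 || object@minFeatureFraction > 1) {
    msg <- c(msg, "'minFeatureFraction' must be in (0, 1]")
  }
  if (object@kdtreeLeafFraction <= 0 || object@kdtreeLeafFraction > 1) {
    msg <- c(msg, "'kdtreeLeafFraction' must be in (0, 1]")
  }
  if (object@seedPercentile <= 0 || object@seedPercentile > 100) {
    msg <- c(msg, "'seedPercentile' must be in (0, 100]")
  }
  if (object@nSubsamples < 1L) msg <- c(msg, "'nSubsamples' must be positive")
  if (object@subsampleSize < 2L * object@maxK) {
    msg <- c(msg, "'subsampleSize' must be at least 2 * maxK")
  }
  if (object@gapNReference < 1L) msg <- c(msg, "'gapNReference' must be positive")
  if (object@maxDepth < 1L) msg <- c(msg, "'maxDepth' must be positive")
  if (length(msg)) msg else TRUE
})

#' GaussianMixture1D: fitted one-dimensional Gaussian mixture
#'
#' Result of [fitGmm1d()]: EM-fitted component parameters of the mixture
#' that minimised BIC, with components sorted by ascending mean and
#' components holding less than 1\% of the points (by maximum-posterior
#' assignment) already discarded.
#'
#' @slot weights mixing proportions, summing to one.
#' @slot means component means (log-abundance units).
#' @slot sds component standard deviations, positive.
#' @slot nComponents number of retained components.
#' @slot bic BIC of the selected model (\eqn{-2 \log L + p \log n}; lower
#'   is better).
#' @slot componentShares fraction of points assigned to each component by
#'   the maximum-posterior rule.
#' @export
setClass("GaussianMixture1D",
  representation(
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    nComponents = "integer",
    bic = "numeric",
    componentShares = "numeric"
  )
)

setValidity("GaussianMixture1D", function(object) {
  msg <- character(0)
  k <- object@nComponents
  if (length(object@weights) != k || length(object@means) != k ||
      length(object@sds) != k) {
    msg <- c(msg, "weights, means and sds must all have length nComponents")
  }
  if (abs(sum(object@weights) - 1) > 1e-9) {
    msg <- c(msg, "weights must sum to 1")
  }
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
  if (is.unsorted(object@means)) {
    msg <- c(msg, "components must be sorted by ascending mean")
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("GaussianMixture1DOrNULL", members = c("GaussianMixture1D", "NULL"))

#' FeatureFilter: data-driven feature mask
#'
#' A per-feature log statistic, the 1-D Gaussian mixture fitted to it, the
#' crossing-point thresholds derived from neighbouring components, the
#' threshold actually applied, and the resulting boolean mask.
#'
#' @slot kind `"abundance"` (filter on log mean) or `"variance"`
#'   (filter on log variance).
#' @slot statistic per-feature log10 statistic; `-Inf` marks features whose
#'   raw statistic was zero (always dropped).
#' @slot model the fitted mixture, or `NULL` when too few finite values
#'   were available to fit one.
#' @slot thresholds sorted crossing points between adjacent components
#'   (empty for a single-component model).
#' @slot chosenThreshold the threshold applied (`NA` when none was).
#' @slot mask logical vector over the features: `TRUE` = retained.
#' @export
setClass("FeatureFilter",
  representation(
    kind = "character",
    statistic = "numeric",
    model = "GaussianMixture1DOrNULL",
    thresholds = "numeric",
    chosenThreshold = "numeric",
    mask = "logical"
  )
)

setValidity("FeatureFilter", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("abundance", "variance")) {
    msg <- c(msg, "'kind' must be \"abundance\" or \"variance\"")
  }
  if (length(object@mask) != length(object@statistic)) {
    msg <- c(msg, "'mask' and 'statistic' must have equal length")
  }
  if (length(object@mask) > 0L && !any(object@mask)) {
    msg <- c(msg, "'mask' must retain at least one feature")
  }
  if (length(msg)) msg else TRUE
})

#' BoxSummary: KD-tree compression of a dataset
#'
#' "Boxes of spectra": the leaves of a KD-tree built over the observations,
#' each summarised by its centroid and a weight equal to the number of
#' member observations.
#'
#' @slot centroids `n_boxes x n_feat` matrix of box centroids.
#' @slot weights positive integer box sizes, summing to the number of
#'   observations.
#' @slot memberIndex list mapping each box to the row indices of its
#'   member observations.
#' @export
setClass("BoxSummary",
  representation(
    centroids = "matrix",
    weights = "integer",
    memberIndex = "list"
  )
)

setValidity("BoxSummary", function(object) {
  msg <- character(0)
  if (nrow(object@centroids) != length(object@weights) ||
      length(object@weights) != length(object@memberIndex)) {
    msg <- c(msg, "centroids, weights and memberIndex must agree in length")
  }
  if (any(object@weights < 1L)) msg <- c(msg, "box weights must be positive")
  n <- sum(object@weights)
  members <- unlist(object@memberIndex, use.names = FALSE)
  if (length(members) != n || anyDuplicated(members)) {
    msg <- c(msg, "every observation must belong to exactly one box")
  }
  if (length(msg)) msg else TRUE
})

#' SeedSet: deterministic initial centroids
#'
#' Ordered initial centroids produced by the percentile seeding of
#' [selectSeeds()], together with the indices of the KD-tree boxes they came
#' from.
#'
#' @slot seeds `k x n_feat` matrix of seed coordinates.
#' @slot sourceBoxes indices of the originating boxes (pairwise distinct).
#' @slot percentile the CDF percentile used.
#' @export
setClass("SeedSet",
  representation(
    seeds = "matrix",
    sourceBoxes = "integer",
    percentile = "numeric"
  )
)

setValidity("SeedSet", function(object) {
  msg <- character(0)
  if (nrow(object@seeds) < 1L) msg <- c(msg, "at least one seed is required")
  if (nrow(object@seeds) != length(object@sourceBoxes)) {
    msg <- c(msg, "one source box per seed is required")
  }
  if (anyDuplicated(object@sourceBoxes)) {
    msg <- c(msg, "seeds must come from distinct boxes")
  }
  if (length(msg)) msg else TRUE
})

#' SplitResult: one K-means partition
#'
#' @slot labels integer cluster labels in `0:(k-1)`, one per observation.
#' @slot centroids `k x n_feat` matrix of cluster centroids.
#' @slot k number of clusters.
#' @slot nIter Lloyd iterations executed.
#' @slot dunn approximate Dunn index of the split (`NA` until evaluated).
#' @export
setClass("SplitResult",
  representation(
    labels = "integer",
    centroids = "matrix",
    k = "integer",
    nIter = "integer",
    dunn = "numeric"
  )
)

setValidity("SplitResult", function(object) {
  msg <- character(0)
  if (any(object@labels < 0L) || any(object@labels >= object@k)) {
    msg <- c(msg, "labels must lie in [0, k)")
  }
  if (length(unique(object@labels)) != object@k) {
    msg <- c(msg, "every cluster must be non-empty")
  }
  if (nrow(object@centroids) != object@k) {
    msg <- c(msg, "one centroid per cluster is required")
  }
  if (length(msg)) msg else TRUE
})

#' GapDecision: two-trial GAP homogeneity verdict
#'
#' @slot gapK1 mean GAP statistic at k = 1 across subsamples.
#' @slot gapK2 mean GAP statistic at k = 2 across subsamples.
#' @slot votesHomogeneous number of subsamples with `gap(1) >= gap(2)`.
#' @slot nSubsamples number of subsamples drawn.
#' @slot homogeneous majority verdict.
#' @export
setClass("GapDecision",
  representation(
    gapK1 = "numeric",
    gapK2 = "numeric",
    votesHomogeneous = "integer",
    nSubsamples = "integer",
    homogeneous = "logical"
  )
)

setValidity("GapDecision", function(object) {
  if (object@votesHomogeneous > object@nSubsamples) {
    "votesHomogeneous cannot exceed nSubsamples"
  } else TRUE
})

#' KSelection: Dunn-index sweep over candidate cluster counts
#'
#' @slot candidateK candidate numbers of clusters evaluated.
#' @slot dunnValues mean approximate Dunn index per candidate
#'   (`NA` for skipped candidates).
#' @slot bestK the candidate maximising mean Dunn (ties broken towards the
#'   smallest k).
#' @export
setClass("KSelection",
  representation(
    candidateK = "integer",
    dunnValues = "numeric",
    bestK = "integer"
  )
)

#' DivikTree: result of a divisive segmentation
#'
#' The recursive segmentation produced by [divikFit()].  Nodes are plain
#' nested lists (fields `nodeId`, `obsIndex`, `featureMask`, `k`, `dunn`,
#' `stopReason`, `children`); [flatLabels()], [nodeFeatures()],
#' [treeLeaves()] and [nodeIds()] are the intended access paths.
#'
#' @slot root the root node.
#' @slot config the [DivikConfig-class] the tree was fitted with.
#' @slot globalAbundanceMask logical mask over the original features kept
#'   by the one-off global abundance filter.
#' @slot featureIds original feature identifiers.
#' @slot obsIds observation identifiers.
#' @export
setClass("DivikTree",
  representation(
    root = "list",
    config = "DivikConfig",
    globalAbundanceMask = "logical",
    featureIds = "character",
    obsIds = "character"
  )
)

setValidity("DivikTree", function(object) {
  msg <- character(0)
  if (length(object@globalAbundanceMask) != length(object@featureIds)) {
    msg <- c(msg, "globalAbundanceMask must cover the original features")
  }
  leaves <- .collectLeaves(object@root)
  covered <- sort(unlist(lapply(leaves, function(nd) nd$obsIndex),
                         use.names = FALSE))
  if (length(covered) != length(object@obsIds) ||
      anyDuplicated(covered) ||
      !identical(covered, seq_along(object@obsIds))) {
    msg <- c(msg, "leaf observation sets must partition all observations")
  }
  if (length(msg)) msg else TRUE
})

#' QualityReport: segmentation quality against annotated regions
#'
#' @slot adjustedRand adjusted Rand index between the normalised cluster
#'   labels and the region annotation.
#' @slot dicePerRoi Dice coefficient per region of interest, after label
#'   normalisation.
#' @slot relativeExims externally supplied spatial-structure score, clipped
#'   to `[0, 1]`.
#' @slot d000 Euclidean norm of `(ARI, primary Dice, relative EXIMS)` from
#'   the origin (higher is better).
#' @slot d111 Euclidean distance of the same triplet from `(1, 1, 1)`
#'   (lower is better).
#' @slot clusterRoiMap named character vector: cluster label to region name
#'   (or `"other"`).
#' @export
setClass("QualityReport",
  representation(
    adjustedRand = "numeric",
    dicePerRoi = "numeric",
    relativeExims = "numeric",
    d000 = "numeric",
    d111 = "numeric",
    clusterRoiMap = "character"
  )
)
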