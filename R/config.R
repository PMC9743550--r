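#' Create a segmentation configuration
#'
#' Defaults correspond to the 2-D tissue parameterisation (see
#' [divikPreset()] for both published presets).
#'
#' @param distance `"correlation"` or `"euclidean"`.
#' @param maxK maximum clusters swept per segmentation level.
#' @param minClusterSize smallest cluster that may still be split.
#' @param minFeatureFraction minimum fraction of the feature pool that the
#'   local variance filter retains.
#' @param kdtreeLeafFraction KD-tree leaf capacity as a fraction of node size.
#' @param seedPercentile percentile used by the deterministic seeding.
#' @param nSubsamples subsamples drawn for GAP / Dunn estimation.
#' @param subsampleSize observations per subsample.
#' @param gapNReference uniform reference datasets per GAP evaluation.
#' @param rngSeed master seed for all stochastic steps.
#' @param applyGlobalAbundanceFilter apply the one-off global noise filter
#'   on log mean abundance at the root.
#' @param maxLeafSizeStop clusters at or below this size are not split
#'   (`NA` disables; used by the 3-D preset).
#' @param maxDepth recursion depth guard.
#'
#' @return a validated [DivikConfig-class].
#' @export
DivikConfig <- function(distance = "correlation",
                        maxK = 10L,
                        minClusterSize = 200L,
                        minFeatureFraction = 0.01,
                        kdtreeLeafFraction = 0.01,
                        seedPercentile = 99,
                        nSubsamples = 10L,
                        subsampleSize = 1000L,
                        gapNReference = 10L,
                        rngSeed = 42L,
                        applyGlobalAbundanceFilter = TRUE,
                        maxLeafSizeStop = NA_integer_,
                        maxDepth = 20L) {
  new("DivikConfig",
      distance = distance,
      maxK = as.integer(maxK),
      minClusterSize = as.integer(minClusterSize),
      minFeatureFraction = as.numeric(minFeatureFraction),
      kdtreeLeafFraction = as.numeric(kdtreeLeafFraction),
      seedPercentile = as.numeric(seedPercentile),
      nSubsamples = as.integer(nSubsamples),
      subsampleSize = as.integer(subsampleSize),
      gapNReference = as.integer(gapNReference),
      rngSeed = as.integer(rngSeed),
      applyGlobalAbundanceFilter = applyGlobalAbundanceFilter,
      maxLeafSizeStop = as.integer(maxLeafSizeStop),
      maxDepth = as.integer(maxDepth))
}

#' Published parameterisation presets
#'
#' `"oscc"`: the 2-D oral squamous cell carcinoma setting — correlation
#' distance, up to 10 clusters per level, minimum cluster of 200 spectra,
#' at least 1\% of local features retained, KD-tree leaves of 1\%, 99th
#' seeding percentile, ten subsamples of 1000 spectra for GAP and Dunn.
#'
#' `"kidney3d"`: the 3-D mouse kidney setting — at least 0.5\% of local
#' features, clusters of 50,000 spectra or fewer are not split further,
#' KD-tree leaves of 0.1\%, 95th seeding percentile, ten subsamples of
#' 5000 spectra.
#'
#' @param name `"oscc"` or `"kidney3d"`.
#' @param ... overrides passed to [DivikConfig()].
#' @return a [DivikConfig-class].
#' @examples
#' divikPreset("oscc", rngSeed = 1L)
#' @export
divikPreset <- function(name = c("oscc", "kidney3d"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    oscc = list(
      distance = "correlation", maxK = 10L, minClusterSize = 200L,
      minFeatureFraction = 0.01, kdtreeLeafFraction = 0.01,
      seedPercentile = 99, nSubsamples = 10L, subsampleSize = 1000L,
      gapNReference = 10L, applyGlobalAbundanceFilter = TRUE
    ),
    kidney3d = list(
      distance = "correlation", maxK = 10L, minClusterSize = 200L,
      minFeatureFraction = 0.005, kdtreeLeafFraction = 0.001,
      seedPercentile = 95, nSubsamples = 10L, subsampleSize = 5000L,
      gapNReference = 10L, applyGlobalAbundanceFilter = TRUE,
      maxLeafSizeStop = 50000L
    )
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(DivikConfig, base)
}

#' Read / write a configuration as JSON
#'
#' @param cfg a [DivikConfig-class].
#' @param path JSON file path.
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(is(cfg, "DivikConfig"))
  fields <- slotNames("DivikConfig")
  lst <- lapply(fields, function(f) slot(cfg, f))
  names(lst) <- fields
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  lst <- jsonlite::fromJSON(path)
  if (is.null(lst$maxLeafSizeStop)) lst$maxLeafSizeStop <- NA_integer_
  do.call(DivikConfig, lst)
}

setMethod("show", "DivikConfig", function(object) {
  cat("DivikConfig\n")
  cat("  distance:            ", object@distance, "\n")
  cat("  maxK / minClusterSize:", object@maxK, "/", object@minClusterSize, "\n")
  cat("  minFeatureFraction:  ", object@minFeatureFraction, "\n")
  cat("  kdtreeLeafFraction:  ", object@kdtreeLeafFraction,
      " seedPercentile:", object@seedPercentile, "\n")
  cat("  subsampling:         ", object@nSubsamples, "x",
      object@subsampleSize, " (", object@gapNReference,
      "GAP references )\n")
  if (!is.na(object@maxLeafSizeStop)) {
    cat("  maxLeafSizeStop:     ", object@maxLeafSizeStop, "\n")
  }
  cat("  rngSeed:             ", object@rngSeed, "\n")
})
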