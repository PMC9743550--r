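# Deterministic generator of MSI-like abundance matrices with planted
# hierarchical cluster structure, so every stage of the pipeline can be
# exercised at desk scale with a known ground truth.

#' Describe a planted hierarchy
#'
#' `hierarchyLeaf(size)` is a terminal group of observations;
#' `hierarchySplit(children, nInformative, effect)` is an internal split
#' driven by its own disjoint block of `nInformative` features, shifted by
#' `± effect` log10 units per child.
#'
#' @param size number of observations in the leaf (at least 1).
#' @return a plain list understood by [generateHierarchy()].
#' @export
hierarchyLeaf <- function(size) {
  stopifnot(size >= 1L)
  list(size = as.integer(size))
}

#' @rdname hierarchyLeaf
#' @param children list of `hierarchyLeaf`/`hierarchySplit` specs
#'   (at least 2).
#' @param nInformative number of features carrying this split.
#' @param effect per-feature shift magnitude in log10 units.
#' @export
hierarchySplit <- function(children, nInformative, effect = 1.0) {
  stopifnot(length(children) >= 2L, nInformative >= 1L, effect > 0)
  list(children = children, nInformative = as.integer(nInformative),
       effect = effect)
}

#' Generate a hierarchically structured abundance matrix
#'
#' Log10 abundances are a per-feature base level (drawn once per feature
#' around `baseLogMean` with spread `featureMeanSd`, emulating the large
#' intensity differences between peaks) plus the accumulated split shifts
#' of the observation's path plus `N(0, logSd)` noise; abundances are
#' `10^(...)`, hence strictly positive and log-normal-like, as peak
#' intensities behave.  Each internal split owns a disjoint block of
#' informative features scattered over the columns; every child of a split
#' receives a distinct `±effect` sign pattern on that block.  All remaining
#' features are pure noise: they vary between observations but carry no
#' cluster structure.  Output is fully reproducible for a fixed seed.
#'
#' Deeper splits are attenuated: the shift applied by a split at depth `d`
#' (root split = depth 0) is `effect * depthAttenuation^d`.  This makes the
#' planted structure genuinely hierarchical — subtypes differ less than
#' types, as intra-tissue heterogeneity is subordinate to tissue-type
#' heterogeneity — rather than a flat set of equidistant blocks that no
#' divisive method could order into levels.
#'
#' @param spec a [hierarchySplit()] / [hierarchyLeaf()] tree.
#' @param nNoiseFeatures number of uninformative features added.
#' @param baseLogMean centre of the per-feature base log10 abundances.
#' @param featureMeanSd spread of the per-feature base levels (log10).
#' @param depthAttenuation multiplicative shrinkage of split amplitudes per
#'   level of depth, in (0, 1].
#' @param logSd observation noise on the log10 scale.
#' @param seed RNG seed.
#' @param withCoords attach raster-order 2-D pixel coordinates.
#' @return a list with elements `matrix` ([AbundanceMatrix-class]),
#'   `leafLabels` (0-based integer vector), `labelsAtDepth` (list of
#'   0-based label vectors, one per depth), `informative` (named list:
#'   split node id to feature identifiers) and `spec`.
#' @export
generateHierarchy <- function(spec, nNoiseFeatures = 400L,
                              baseLogMean = 2, featureMeanSd = 0.1,
                              depthAttenuation = 0.6,
                              logSd = 0.2, seed = 0L,
                              withCoords = TRUE) {
  stopifnot(depthAttenuation > 0, depthAttenuation <= 1)
  splits <- list()   # nodeId -> list(node, rows, childRows)
  leaves <- list()   # in preorder: list(path = integer vector, size)
  walk <- function(node, path) {
    if (!is.null(node$size)) {
      leaves[[length(leaves) + 1L]] <<- list(path = path, size = node$size)
      return(node$size)
    }
    sizes <- integer(0)
    for (j in seq_along(node$children)) {
      sizes <- c(sizes, walk(node$children[[j]], c(path, j - 1L)))
    }
    splits[[paste(c("0", path), collapse = ".")]] <<-
      list(nInformative = node$nInformative, effect = node$effect,
           path = path, childSizes = sizes)
    sum(sizes)
  }
  n <- walk(spec, integer(0))
  totalInformative <- sum(vapply(splits, `[[`, integer(1), "nInformative"))
  p <- totalInformative + as.integer(nNoiseFeatures)
  if (totalInformative > p) stop("informative features exceed n_feat")

  leafPath <- lapply(leaves, `[[`, "path")
  leafSize <- vapply(leaves, `[[`, integer(1), "size")
  obsLeaf <- rep(seq_along(leaves), leafSize)

  out <- .withSeed(seed, {
    featOrder <- sample.int(p)        # scatter informative columns
    featBase <- baseLogMean + stats::rnorm(p, sd = featureMeanSd)
    meanMat <- matrix(featBase, nrow = n, ncol = p, byrow = TRUE)
    informative <- list()
    cursor <- 0L
    for (id in names(splits)) {
      sp <- splits[[id]]
      cols <- featOrder[cursor + seq_len(sp$nInformative)]
      cursor <- cursor + sp$nInformative
      informative[[id]] <- sort(cols)
      nChild <- length(sp$childSizes)
      # balanced sign codes: sibling patterns differ pairwise on close to
      # half of the split's features, so planted siblings are roughly
      # equidistant (neither near-duplicates nor a dominant pair)
      mInf <- sp$nInformative
      hammingLo <- max(1L, floor(0.4 * mInf))
      hammingHi <- max(hammingLo, ceiling(0.6 * mInf))
      patterns <- matrix(0, nrow = nChild, ncol = mInf)
      for (j in seq_len(nChild)) {
        tries <- 0L
        clash <- FALSE
        repeat {
          tries <- tries + 1L
          cand <- sample(c(-1, 1), mInf, replace = TRUE)
          clash <- j > 1L &&
            any(apply(patterns[seq_len(j - 1L), , drop = FALSE], 1L,
                      function(r) {
                        hd <- sum(r != cand)
                        hd < hammingLo || hd > hammingHi
                      }))
          if (!clash || tries > 10000L) break
        }
        if (clash) stop("could not draw ", nChild,
                        " balanced sign patterns over ", mInf,
                        " features; increase nInformative")
        patterns[j, ] <- cand
      }
      depth <- length(sp$path)
      amplitude <- sp$effect * depthAttenuation^depth
      for (j in seq_len(nChild)) {
        inChild <- vapply(leafPath[obsLeaf], function(pp) {
          length(pp) > depth && all(pp[seq_len(depth)] == sp$path) &&
            pp[depth + 1L] == j - 1L
        }, logical(1))
        meanMat[inChild, cols] <- meanMat[inChild, cols] +
          matrix(amplitude * patterns[j, ], nrow = sum(inChild),
                 ncol = sp$nInformative, byrow = TRUE)
      }
    }
    values <- 10^(meanMat + matrix(stats::rnorm(n * p, sd = logSd),
                                   nrow = n))
    list(values = values, informative = informative)
  })

  featIds <- paste0("f", seq_len(p))
  coordsM <- NULL
  if (withCoords) {
    w <- ceiling(sqrt(n))
    coordsM <- cbind(x = (seq_len(n) - 1L) %% w,
                     y = (seq_len(n) - 1L) %/% w)
  }
  m <- AbundanceMatrix(out$values, featureIds = featIds, coords = coordsM)

  maxDepth <- max(lengths(leafPath))
  labelsAtDepth <- lapply(seq_len(maxDepth), function(d) {
    keys <- vapply(leafPath[obsLeaf], function(pp) {
      paste(pp[seq_len(min(d, length(pp)))], collapse = ".")
    }, character(1))
    match(keys, sort(unique(keys))) - 1L
  })
  informative <- lapply(out$informative, function(cols) featIds[cols])
  if (length(informative) > 1L) {
    informative <- informative[order(names(informative))]
  }
  list(matrix = m,
       leafLabels = obsLeaf - 1L,
       labelsAtDepth = labelsAtDepth,
       informative = informative,
       spec = spec)
}

#' Generate a bimodal noise-floor fixture
#'
#' Per-feature log10 means are drawn from a two-mode distribution — a low
#' "noise" mode and a high "signal" mode `separation` log units above — so
#' the global abundance filter has a recoverable planted ground truth.
#'
#' @param nObs,nFeat matrix dimensions.
#' @param lowModeFraction expected fraction of noise-mode features, in
#'   `[0, 1)` (0 yields a unimodal, all-signal matrix).
#' @param separation distance between the modes in log10 units.
#' @param baseLogMean mean of the low mode.
#' @param modeSd spread of the per-feature means within a mode.
#' @param logSd observation noise on the log10 scale.
#' @param seed RNG seed.
#' @return `list(matrix = AbundanceMatrix, lowMode = logical)` where
#'   `lowMode` flags the planted noise features.
#' @export
generateNoiseFloor <- function(nObs, nFeat, lowModeFraction,
                               separation = 3, baseLogMean = 0.5,
                               modeSd = 0.15, logSd = 0.3, seed = 0L) {
  stopifnot(lowModeFraction >= 0, lowModeFraction < 1)
  out <- .withSeed(seed, {
    low <- stats::runif(nFeat) < lowModeFraction
    featMean <- baseLogMean + ifelse(low, 0, separation) +
      stats::rnorm(nFeat, sd = modeSd)
    values <- 10^(matrix(featMean, nrow = nObs, ncol = nFeat, byrow = TRUE) +
                    matrix(stats::rnorm(nObs * nFeat, sd = logSd),
                           nrow = nObs))
    list(values = values, low = low)
  })
  list(matrix = AbundanceMatrix(out$values), lowMode = out$low)
}
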