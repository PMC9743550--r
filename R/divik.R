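# The deglomerative driver: per-node feature-space optimisation,
# homogeneity check, k selection, split, recursion.

.makeNode <- function(nodeId, obsIndex, featureMask, k = NA_integer_,
                      dunn = NA_real_, stopReason = NA_character_,
                      children = list()) {
  list(nodeId = nodeId, obsIndex = obsIndex, featureMask = featureMask,
       k = k, dunn = dunn, stopReason = stopReason, children = children)
}

#' Divisive segmentation with local feature-space adaptation
#'
#' The full recursion: a one-off global abundance (noise) filter at the
#' root, then per node (1) a stop on nodes smaller than
#' `cfg@minClusterSize` (or at/below `cfg@maxLeafSizeStop` when set, or at
#' `cfg@maxDepth`), (2) a variance filter recomputed over the
#' root-surviving feature pool restricted to the node's observations,
#' (3) the two-trial GAP homogeneity test in the node's filtered space and
#' (4) on a heterogeneous verdict, K-means at the Dunn-selected number of
#' clusters, followed by recursion into every child.  Children are visited
#' depth-first in ascending split-label order; node identifiers are
#' path-like (`"0"`, `"0.2"`, `"0.2.1"`).
#'
#' The run is deterministic: the same matrix, configuration and seed yield
#' an identical tree.
#'
#' @param m an [AbundanceMatrix-class] (or numeric matrix) with at least
#'   two observations.
#' @param cfg a [DivikConfig-class].
#' @param verbose emit one log line per node.
#' @return a [DivikTree-class].
#' @seealso [flatLabels()], [nodeFeatures()], [writeTree()]
#' @export
divikFit <- function(m, cfg = DivikConfig(), verbose = FALSE) {
  if (!is(m, "AbundanceMatrix")) m <- AbundanceMatrix(m)
  stopifnot(is(cfg, "DivikConfig"))
  if (nrow(m@values) < 2L) stop("at least two observations are required",
                                call. = FALSE)
  logLine <- function(...) if (verbose) message(...)

  if (cfg@applyGlobalAbundanceFilter) {
    globalMask <- abundanceFilter(m)@mask
    logLine("global abundance filter keeps ", sum(globalMask), " of ",
            length(globalMask), " features")
  } else {
    globalMask <- rep(TRUE, ncol(m@values))
  }
  X <- m@values[, globalMask, drop = FALSE]
  nPool <- ncol(X)

  recurse <- function(rows, depth, nodeId) {
    size <- length(rows)
    nodeSeed <- .deriveSeed(cfg@rngSeed, .hashString(nodeId))

    mask <- if (size >= 2L) {
      varianceFilter(X[rows, , drop = FALSE], cfg@minFeatureFraction)@mask
    } else rep(TRUE, nPool)

    leaf <- function(reason) {
      logLine("node ", nodeId, ": depth ", depth, ", size ", size,
              ", features ", sum(mask), ", leaf (", reason, ")")
      .makeNode(nodeId, rows, mask, stopReason = reason)
    }

    if (size < cfg@minClusterSize) return(leaf("too_small"))
    if (!is.na(cfg@maxLeafSizeStop) && size <= cfg@maxLeafSizeStop) {
      return(leaf("too_small"))
    }
    if (depth >= cfg@maxDepth) return(leaf("max_depth"))

    sub <- X[rows, mask, drop = FALSE]
    decision <- isHomogeneous(sub, cfg, rngSeed = nodeSeed)
    if (decision@homogeneous) return(leaf("homogeneous"))

    sel <- selectK(sub, cfg, rngSeed = nodeSeed)
    if (is.null(sel)) return(leaf("no_valid_split"))

    split <- sel$split
    logLine("node ", nodeId, ": depth ", depth, ", size ", size,
            ", features ", sum(mask), ", split into k = ", split@k,
            " (Dunn ", format(split@dunn, digits = 4), ")")
    children <- lapply(seq_len(split@k) - 1L, function(j) {
      recurse(rows[split@labels == j], depth + 1L,
              paste0(nodeId, ".", j))
    })
    .makeNode(nodeId, rows, mask, k = split@k, dunn = split@dunn,
              children = children)
  }

  root <- recurse(seq_len(nrow(X)), 0L, "0")
  new("DivikTree", root = root, config = cfg,
      globalAbundanceMask = globalMask,
      featureIds = m@featureIds, obsIds = m@obsIds)
}

#' Flat cluster labels from a segmentation tree
#'
#' One label per observation: by default one cluster per leaf; with `depth`
#' given, one cluster per node at that depth (nodes that became leaves
#' earlier keep their leaf membership).  Labels are canonicalised to
#' consecutive integers starting at 0, ordered by decreasing cluster size
#' with ties broken by node identifier.
#'
#' @param tree a [DivikTree-class].
#' @param depth optional cut depth (`NULL` = leaves; `1` = the root split).
#' @return integer vector of labels in `0:(g-1)`.
#' @export
flatLabels <- function(tree, depth = NULL) {
  stopifnot(is(tree, "DivikTree"))
  groups <- list()
  collect <- function(node, d) {
    atCut <- !is.null(depth) && d >= depth
    if (length(node$children) == 0L || atCut) {
      groups[[length(groups) + 1L]] <<- list(id = node$nodeId,
                                             rows = node$obsIndex)
      return(invisible(NULL))
    }
    for (ch in node$children) collect(ch, d + 1L)
  }
  collect(tree@root, 0L)
  sizes <- vapply(groups, function(g) length(g$rows), integer(1))
  ids <- vapply(groups, function(g) g$id, character(1))
  ord <- order(-sizes, ids)
  out <- integer(length(tree@obsIds))
  for (pos in seq_along(ord)) {
    out[groups[[ord[pos]]]$rows] <- pos - 1L
  }
  out
}

.findNode <- function(node, nodeId) {
  if (identical(node$nodeId, nodeId)) return(node)
  for (ch in node$children) {
    found <- .findNode(ch, nodeId)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' Feature identifiers retained at a tree node
#'
#' The node's local variance mask composed with the global abundance mask,
#' translated back to the original feature identifiers.  Leaves record a
#' mask too, even when never split.
#'
#' @param tree a [DivikTree-class].
#' @param nodeId path-like node identifier, e.g. `"0.2.1"`.
#' @return character vector of feature identifiers.
#' @export
nodeFeatures <- function(tree, nodeId) {
  stopifnot(is(tree, "DivikTree"))
  node <- .findNode(tree@root, nodeId)
  if (is.null(node)) stop("unknown node: ", nodeId, call. = FALSE)
  pool <- tree@featureIds[tree@globalAbundanceMask]
  pool[node$featureMask]
}

#' @rdname DivikTree-class
#' @export
setMethod("treeConfig", "DivikTree", function(x) x@config)

#' @rdname DivikTree-class
#' @export
setMethod("rootNode", "DivikTree", function(x) x@root)

#' @rdname DivikTree-class
#' @export
setMethod("treeLeaves", "DivikTree", function(x) .collectLeaves(x@root))

#' @rdname DivikTree-class
#' @export
setMethod("nodeIds", "DivikTree", function(x) {
  collect <- function(node) {
    c(node$nodeId, unlist(lapply(node$children, collect), use.names = FALSE))
  }
  collect(x@root)
})

setMethod("show", "DivikTree", function(object) {
  leaves <- .collectLeaves(object@root)
  reasons <- table(vapply(leaves, function(nd) nd$stopReason, character(1)))
  cat("DivikTree:", length(object@obsIds), "observations,",
      length(leaves), "leaf cluster(s)\n")
  cat("  global abundance filter kept", sum(object@globalAbundanceMask),
      "of", length(object@globalAbundanceMask), "features\n")
  cat("  leaf stop reasons:",
      paste(names(reasons), reasons, sep = "=", collapse = ", "), "\n")
})
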