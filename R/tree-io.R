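# Versioned JSON serialisation of segmentation trees.

.TREE_SCHEMA_VERSION <- "1"

.nodeToList <- function(node, pool) {
  list(
    node_id = node$nodeId,
    obs_index = as.integer(node$obsIndex),
    features = pool[node$featureMask],
    k = if (is.na(node$k)) NULL else as.integer(node$k),
    dunn = if (is.na(node$dunn)) NULL else node$dunn,
    stop_reason = if (is.na(node$stopReason)) NULL else node$stopReason,
    children = lapply(node$children, .nodeToList, pool = pool)
  )
}

.nodeFromList <- function(lst, pool) {
  required <- c("node_id", "obs_index", "features", "children")
  missing <- setdiff(required, names(lst))
  if (length(missing)) {
    stop("tree schema error: node missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  feats <- unlist(lst$features, use.names = FALSE)
  if (is.null(feats)) feats <- character(0)
  .makeNode(
    nodeId = lst$node_id,
    obsIndex = as.integer(unlist(lst$obs_index, use.names = FALSE)),
    featureMask = pool %in% feats,
    k = if (is.null(lst$k)) NA_integer_ else as.integer(lst$k),
    dunn = if (is.null(lst$dunn)) NA_real_ else as.numeric(lst$dunn),
    stopReason = if (is.null(lst$stop_reason)) NA_character_
                 else lst$stop_reason,
    children = lapply(lst$children, .nodeFromList, pool = pool)
  )
}

#' Write / read a segmentation tree as JSON
#'
#' The document carries a schema version, the observation and feature
#' identifiers, the configuration, the global abundance mask (as the list
#' of surviving feature identifiers) and the recursive node structure with
#' per-node feature lists, chosen `k`, Dunn value and stop reason.
#' `readTree(writeTree(tree))` is the identity on the logical tree, and
#' serialisation is byte-stable for identical trees.
#'
#' @param tree a [DivikTree-class].
#' @param path JSON file path.
#' @export
writeTree <- function(tree, path) {
  stopifnot(is(tree, "DivikTree"))
  validObject(tree)
  pool <- tree@featureIds[tree@globalAbundanceMask]
  cfgFields <- slotNames("DivikConfig")
  cfg <- lapply(cfgFields, function(f) slot(tree@config, f))
  names(cfg) <- cfgFields
  doc <- list(
    schema_version = .TREE_SCHEMA_VERSION,
    n_obs = length(tree@obsIds),
    obs_ids = tree@obsIds,
    feature_ids = tree@featureIds,
    global_abundance_kept = pool,
    config = cfg,
    root = .nodeToList(tree@root, pool)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname writeTree
#' @return `readTree`: a [DivikTree-class].
#' @export
readTree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), .TREE_SCHEMA_VERSION)) {
    stop("unknown tree schema version: ",
         if (is.null(doc$schema_version)) "<missing>" else doc$schema_version,
         call. = FALSE)
  }
  featureIds <- unlist(doc$feature_ids, use.names = FALSE)
  kept <- unlist(doc$global_abundance_kept, use.names = FALSE)
  if (is.null(kept)) kept <- character(0)
  cfgList <- doc$config
  if (is.null(cfgList$maxLeafSizeStop)) cfgList$maxLeafSizeStop <- NA_integer_
  cfg <- do.call(DivikConfig, cfgList)
  root <- .nodeFromList(doc$root, pool = kept)
  new("DivikTree", root = root, config = cfg,
      globalAbundanceMask = featureIds %in% kept,
      featureIds = featureIds,
      obsIds = unlist(doc$obs_ids, use.names = FALSE))
}
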