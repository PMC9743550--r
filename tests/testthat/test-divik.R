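# The recursive driver: stop rules, partitions, labels, per-node features.

test_that("a structureless region yields a single homogeneous leaf", {
  h <- hierarchySplit(list(hierarchyLeaf(150), hierarchyLeaf(150)),
                      nInformative = 2, effect = 0.01)
  g <- generateHierarchy(h, nNoiseFeatures = 78, seed = 7)
  cfg <- fastConfig(minClusterSize = 50L, subsampleSize = 120L,
                    applyGlobalAbundanceFilter = FALSE)
  tree <- divikFit(g$matrix, cfg)
  leaves <- treeLeaves(tree)
  expect_length(leaves, 1L)
  expect_identical(leaves[[1]]$stopReason, "homogeneous")
  expect_identical(flatLabels(tree), rep(0L, 300))
})

test_that("undersized inputs stop immediately with too_small", {
  g <- generateHierarchy(hierarchySplit(list(hierarchyLeaf(20),
                                             hierarchyLeaf(20)),
                                        nInformative = 5),
                         nNoiseFeatures = 35, seed = 1)
  cfg <- fastConfig(minClusterSize = 100L, subsampleSize = 30L, maxK = 3L,
                    applyGlobalAbundanceFilter = FALSE)
  tree <- divikFit(g$matrix, cfg)
  expect_identical(treeLeaves(tree)[[1]]$stopReason, "too_small")
})

test_that("clusters at or below maxLeafSizeStop are never split", {
  h <- hierarchySplit(list(hierarchyLeaf(200), hierarchyLeaf(200)),
                      nInformative = 20, effect = 1)
  g <- generateHierarchy(h, nNoiseFeatures = 80, seed = 3)
  cfg <- fastConfig(minClusterSize = 30L, subsampleSize = 150L,
                    maxLeafSizeStop = 250L,
                    applyGlobalAbundanceFilter = FALSE)
  tree <- divikFit(g$matrix, cfg)
  for (leaf in treeLeaves(tree)) {
    expect_lte(length(leaf$obsIndex), 250L)
  }
  # the root (400 obs) is above the stop size, so it did split
  expect_gt(length(treeLeaves(tree)), 1L)
})

test_that("the planted two-level hierarchy is recovered", {
  g <- generateHierarchy(twoLevelHierarchy(400, 200, 200, nInformative = 25),
                         nNoiseFeatures = 450, seed = 11)
  cfg <- divikPreset("oscc", minClusterSize = 80L, subsampleSize = 300L,
                     rngSeed = 5L, applyGlobalAbundanceFilter = FALSE)
  tree <- divikFit(g$matrix, cfg)

  # partition property at every depth
  for (node in Filter(function(nd) length(nd$children) > 0,
                      lapply(nodeIds(tree), function(id) {
                        divikr:::.findNode(rootNode(tree), id)
                      }))) {
    childRows <- sort(unlist(lapply(node$children, `[[`, "obsIndex")))
    expect_identical(childRows, sort(node$obsIndex))
  }

  # no undersized node was ever split
  for (id in nodeIds(tree)) {
    node <- divikr:::.findNode(rootNode(tree), id)
    if (length(node$children) > 0) {
      expect_gte(length(node$obsIndex), 80L)
    }
    expect_gte(sum(node$featureMask), 1L)
  }

  expect_gte(adjustedRand(flatLabels(tree, depth = 1),
                          g$labelsAtDepth[[1]]), 0.95)
  expect_gte(adjustedRand(flatLabels(tree), g$leafLabels), 0.9)

  # the root split's informative features were recovered (Jaccard >= 0.5)
  rootFeats <- nodeFeatures(tree, "0")
  planted <- g$informative[["0"]]
  jac <- length(intersect(rootFeats, planted)) /
    length(union(rootFeats, planted))
  expect_gte(jac, 0.5)
})

test_that("flat labels are canonical and depth cuts match the root split", {
  g <- generateHierarchy(twoLevelHierarchy(400, 200, 200),
                         nNoiseFeatures = 450, seed = 11)
  cfg <- divikPreset("oscc", minClusterSize = 80L, subsampleSize = 300L,
                     rngSeed = 5L, applyGlobalAbundanceFilter = FALSE)
  tree <- divikFit(g$matrix, cfg)
  lab <- flatLabels(tree)
  expect_identical(sort(unique(lab)), seq_along(treeLeaves(tree)) - 1L)
  sizes <- as.vector(table(lab))
  expect_true(all(diff(sizes) <= 0))  # decreasing cluster size order

  top <- flatLabels(tree, depth = 1)
  expect_identical(length(unique(top)), length(rootNode(tree)$children))
  # depth-1 groups refine into the leaf groups
  expect_true(all(tapply(lab, top, function(x) length(unique(x))) >= 1))
})

test_that("node lookup errors on unknown identifiers, leaves carry masks", {
  g <- generateHierarchy(hierarchySplit(list(hierarchyLeaf(100),
                                             hierarchyLeaf(100)),
                                        nInformative = 20, effect = 1),
                         nNoiseFeatures = 80, seed = 9)
  cfg <- fastConfig(minClusterSize = 40L, subsampleSize = 100L,
                    applyGlobalAbundanceFilter = FALSE)
  tree <- divikFit(g$matrix, cfg)
  expect_error(nodeFeatures(tree, "9.9"), "unknown node")
  for (leaf in treeLeaves(tree)) {
    feats <- nodeFeatures(tree, leaf$nodeId)
    expect_gte(length(feats), 1L)
    expect_true(all(feats %in% featureIds(g$matrix)))
  }
})

test_that("identical configuration and seed reproduce the identical tree", {
  g <- generateHierarchy(hierarchySplit(list(hierarchyLeaf(150),
                                             hierarchyLeaf(150)),
                                        nInformative = 20, effect = 1),
                         nNoiseFeatures = 80, seed = 13)
  cfg <- fastConfig(minClusterSize = 40L, subsampleSize = 120L, rngSeed = 2L,
                    applyGlobalAbundanceFilter = FALSE)
  t1 <- divikFit(g$matrix, cfg)
  t2 <- divikFit(g$matrix, cfg)
  p1 <- file.path(tempdir(), "det1.json")
  p2 <- file.path(tempdir(), "det2.json")
  writeTree(t1, p1)
  writeTree(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
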