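test_that("TBR neighborhoods cover the known small-tree cases", {
  quartet <- readNewick("((A,B),(C,D));")
  nb <- tbrNeighbors(quartet)
  # the other two quartet topologies, and nothing else
  expect_equal(length(nb), 2)
  sigs <- vapply(nb, topologySignature, character(1))
  expect_setequal(sigs, vapply(list(readNewick("((A,C),(B,D));"),
                                    readNewick("((A,D),(B,C));")),
                               topologySignature, character(1)))

  # 5 leaves: a single bisection-reconnection reaches every topology except
  # the two in which BOTH cherries are exchanged at once (those share no
  # split with the source; the naive double-loop rearranger agrees)
  five <- readNewick("(((A,B),C),(D,E));")
  nb5 <- tbrNeighbors(five)
  all5 <- lapply(allTopologyEdges(5), cachalot:::phyloFromEdges, nTip = 5,
                 labels = LETTERS[1:5])
  allSigs <- vapply(all5, topologySignature, character(1))
  expect_equal(length(unique(allSigs)), 15)
  nbSigs <- vapply(nb5, topologySignature, character(1))
  expect_setequal(nbSigs, naiveTbrSignatures(five))
  expect_equal(length(nbSigs), 12)
  unreachable <- setdiff(allSigs, c(nbSigs, topologySignature(five)))
  sharedSplits <- vapply(all5[match(unreachable, allSigs)], function(t)
    length(intersect(treeSplits(t), treeSplits(five))), integer(1))
  expect_true(all(sharedSplits == 0))
})

test_that("TBR neighbor sets match a naive double-loop rearranger", {
  set.seed(201)
  for (i in 1:3) {
    tr <- ape::rtree(7, rooted = FALSE)
    mine <- vapply(tbrNeighbors(tr), topologySignature, character(1))
    expect_setequal(mine, naiveTbrSignatures(tr))
  }
})

test_that("random addition is deterministic and finds perfect-fit trees", {
  set.seed(202)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:8)
  pm <- perfectMatrix(tr)
  # a compatible matrix is fit perfectly straight from the addition sequence
  ra <- randomAdditionTree(pm, seed = 5)
  smin <- sum(vapply(seq_len(nChars(pm)), function(j) minSteps(pm, j), integer(1)))
  expect_equal(fitchLength(ra, pm)$totalLength, smin)
  # determinism under a fixed seed
  expect_identical(topologySignature(randomAdditionTree(pm, seed = 9)),
                   topologySignature(randomAdditionTree(pm, seed = 9)))
  # 3 taxa: the one unrooted topology
  m3 <- randomMatrix(3, 2)
  expect_equal(length(randomAdditionTree(m3, seed = 1)$tip.label), 3)
})

test_that("heuristic search equals exhaustive search on small instances", {
  set.seed(203)
  for (i in 1:8) {
    n <- sample(5:7, 1)
    m <- randomMatrix(n, nChars = sample(5:10, 1), nStates = sample(2:4, 1),
                      pMissing = 0.1, pPoly = 0.1)
    res <- heuristicSearch(m, searchConfig(nReplicates = 3, seed = i))
    topos <- allTopologyEdges(n)
    sd <- cachalot:::searchData(m)
    lens <- vapply(topos, function(e)
      cachalot:::fitch_total_cpp(e, n, sd$masks, sd$nStates,
                                 .Machine$integer.max - 1L), integer(1))
    expect_equal(res$bestLength, min(lens))
    # every retained tree rescored independently gives the best length
    for (tr in res$trees) {
      expect_equal(fitchLength(tr, m)$totalLength, res$bestLength)
    }
    # the full shortest-tree set is recovered by the plateau search
    bestSigs <- unique(vapply(topos[lens == min(lens)], function(e)
      topologySignature(cachalot:::phyloFromEdges(e, n, m$taxa)), character(1)))
    expect_setequal(vapply(res$trees, topologySignature, character(1)), bestSigs)
  }
})

test_that("search recovers the generating tree from compatible characters", {
  set.seed(204)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:8)
  pm <- perfectMatrix(tr, copies = 2)
  res <- heuristicSearch(pm, searchConfig(nReplicates = 5, seed = 17))
  expect_true(topologySignature(tr) %in%
              vapply(res$trees, topologySignature, character(1)))
  smin <- sum(vapply(seq_len(nChars(pm)), function(j) minSteps(pm, j), integer(1)))
  expect_equal(res$bestLength, smin)
})

test_that("more addition replicates never lengthen the best tree", {
  set.seed(205)
  m <- randomMatrix(9, 12, nStates = 3, pMissing = 0.15, pPoly = 0.05)
  # same seed: the first replicate of the longer run is the shorter run
  short <- heuristicSearch(m, searchConfig(nReplicates = 1, seed = 31))
  long <- heuristicSearch(m, searchConfig(nReplicates = 6, seed = 31))
  expect_lte(long$bestLength, short$bestLength)
})

test_that("search is reproducible and mandatory-seeded", {
  m <- randomMatrix(6, 8)
  expect_error(heuristicSearch(m, searchConfig(nReplicates = 2)), "seed")
  a <- heuristicSearch(m, searchConfig(nReplicates = 3, seed = 7))
  b <- heuristicSearch(m, searchConfig(nReplicates = 3, seed = 7))
  expect_identical(vapply(a$trees, topologySignature, character(1)),
                   vapply(b$trees, topologySignature, character(1)))
  expect_identical(a$log, b$log)
  expect_equal(nrow(a$log), 3)
  expect_true(all(a$log$end_length <= a$log$start_length))
})

test_that("the tied-tree cap flags truncation", {
  # a matrix with massive plateaus: few informative characters, many taxa
  set.seed(206)
  m <- randomMatrix(10, 2, nStates = 2, pMissing = 0, pPoly = 0)
  res <- heuristicSearch(m, searchConfig(nReplicates = 2, seed = 3, maxTrees = 5))
  expect_true(res$truncated)
  expect_lte(length(res$trees), 5)
})

test_that("zero-length-branch collapse merges unsupported branches only", {
  tr <- readNewick("(((A,B),C),(D,E));")
  # one character supporting {A,B}; nothing supports the {A,B,C} branch
  m <- characterMatrix(list(A = list(1), B = list(1), C = list(0),
                            D = list(0), E = list(0)), taxa = LETTERS[1:5])
  col <- collapseZeroLengthBranches(tr, m)
  expect_setequal(treeSplits(col), "C,D,E")  # the {A,B} clade, canonical side
  # a fully supported tree is untouched
  pm <- perfectMatrix(tr)
  expect_identical(topologySignature(collapseZeroLengthBranches(tr, pm)),
                   topologySignature(tr))
  expect_equal(countUniqueTopologies(list(tr, tr, readNewick("((A,C),(B,(D,E)));"))), 2)
})
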