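test_that("minimum-change scoring handles the textbook cases", {
  quartet <- readNewick("((A,B),(C,D));")
  m01 <- characterMatrix(list(A = list(0), B = list(1), C = list(0), D = list(1)),
                         taxa = c("A", "B", "C", "D"))
  # brute-force over both internal labelings gives 2
  et <- cachalot:::edgesFromPhylo(quartet)
  expect_equal(oracleFitchLength(et$edge, m01), 2L)
  expect_equal(fitchLength(quartet, m01)$totalLength, 2L)

  allSame <- characterMatrix(lapply(1:4, function(i) list(0, 0)),
                             taxa = c("A", "B", "C", "D"))
  expect_equal(fitchLength(quartet, allSame)$totalLength, 0L)

  expect_error(fitchLength(readNewick("((A,B),(C,E));"), m01), "E")
})

test_that("scoring equals the exhaustive labeling oracle (property)", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    m <- randomMatrix(n, nChars = sample(2:6, 1), nStates = sample(2:4, 1),
                      pMissing = runif(1, 0, 0.3), pPoly = runif(1, 0, 0.2))
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- sample(paste0("t", 1:n))
    et <- cachalot:::edgesFromPhylo(tr)
    perm <- match(et$labels, m$taxa)
    edge <- et$edge
    edge[edge <= n] <- perm[edge[edge <= n]]
    expect_equal(fitchLength(tr, m)$totalLength, oracleFitchLength(edge, m))
  }
})

test_that("polytomies are scored as hard multifurcations, still minimal", {
  set.seed(102)
  for (i in 1:20) {
    n <- sample(5:7, 1)
    m <- randomMatrix(n, nChars = 3, nStates = 3, pMissing = 0.1, pPoly = 0.1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- paste0("t", 1:n)
    tr <- ape::di2multi(tr, tol = Inf)  # collapse to a star sometimes
    star <- ape::stree(n, "star", tip.label = paste0("t", 1:n))
    for (t in list(tr, star)) {
      et <- cachalot:::edgesFromPhylo(t)
      perm <- match(et$labels, m$taxa)
      edge <- et$edge
      edge[edge <= n] <- perm[edge[edge <= n]]
      expect_equal(fitchLength(t, m)$totalLength, oracleFitchLength(edge, m))
    }
  }
})

test_that("score is invariant under re-rooting", {
  set.seed(103)
  m <- randomMatrix(8, 6, nStates = 4)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:8)
  ref <- fitchLength(tr, m)$totalLength
  for (tip in sample(tr$tip.label, 4)) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitchLength(rerooted, m)$totalLength, ref)
  }
})

test_that("lengths, CI and RI match phangorn on clean data", {
  skip_if_not_installed("phangorn")
  set.seed(104)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    states <- matrix(sample(0:3, n * 12, replace = TRUE), n, 12,
                     dimnames = list(tr$tip.label, NULL))
    m <- characterMatrix(lapply(seq_len(n), function(i) as.list(states[i, ])),
                         taxa = tr$tip.label, symbols = 0:3)
    pd <- phangorn::phyDat(states, type = "USER", levels = 0:3)
    s <- fitchLength(tr, m)
    expect_equal(s$totalLength,
                 as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
    expect_equal(s$ci, phangorn::CI(tr, pd), tolerance = 1e-12)
    expect_equal(s$ri, phangorn::RI(tr, pd), tolerance = 1e-12)
  }
})

test_that("best- and worst-case step counts follow their definitions", {
  m3 <- characterMatrix(list(A = list(0), B = list(1), C = list(2)),
                        taxa = c("A", "B", "C"), symbols = 0:2)
  expect_equal(minSteps(m3, 1), 2L)   # three states observed
  const <- characterMatrix(list(A = list(1), B = list(1)), taxa = c("A", "B"))
  expect_equal(minSteps(const, 1), 0L)
  expect_equal(maxSteps(const, 1), 0L)

  # polymorphic cell resolvable: {0},{1},{0,1} needs only 2 states -> 1 step;
  # brute force over the resolutions of the polymorphic cell agrees
  mp <- characterMatrix(list(A = list(0), B = list(1), C = list(c(0, 1))),
                        taxa = c("A", "B", "C"))
  bruteMin <- min(vapply(0:1, function(res) {
    length(unique(c(0, 1, res))) - 1L
  }, integer(1)))
  expect_equal(minSteps(mp, 1), bruteMin)

  # worst case 0,0,0,1,1 over all 15 five-leaf topologies is 2
  m5 <- characterMatrix(list(A = list(0), B = list(0), C = list(0),
                             D = list(1), E = list(1)), taxa = LETTERS[1:5])
  worst <- max(vapply(allTopologyEdges(5), oracleFitchLength, integer(1), m = m5))
  expect_equal(maxSteps(m5, 1), worst)

  # 4 distinct singleton states: worst case 3 over the 3 quartet topologies
  m4 <- characterMatrix(list(A = list(0), B = list(1), C = list(2), D = list(3)),
                        taxa = LETTERS[1:4])
  worst4 <- max(vapply(allTopologyEdges(4), oracleFitchLength, integer(1), m = m4))
  expect_equal(maxSteps(m4, 1), worst4)
  expect_equal(worst4, 3L)
})

test_that("homoplasy indices follow the summation formulas", {
  set.seed(105)
  tr <- ape::rtree(5, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:5)
  m <- randomMatrix(5, 8, nStates = 3, pMissing = 0.1, pPoly = 0.1)
  s <- fitchLength(tr, m)
  # spreadsheet-style independent summation
  smin <- sum(vapply(1:8, function(j) minSteps(m, j), integer(1)))
  smax <- sum(vapply(1:8, function(j) maxSteps(m, j), integer(1)))
  L <- sum(s$perCharLengths)
  expect_equal(s$totalLength, L)
  expect_equal(s$ci, smin / L)
  expect_equal(s$ri, (smax - L) / (smax - smin))
  expect_true(s$ci > 0 && s$ci <= 1)
  expect_true(s$ri >= 0 && s$ri <= 1)

  # excluding uninformative characters drops constants and autapomorphies
  s2 <- fitchLength(tr, m, includeUninformative = FALSE)
  keep <- vapply(1:8, function(j) isInformative(m, j), logical(1))
  if (any(keep) && sum(s$perCharLengths[keep]) > 0) {
    expect_equal(s2$ci,
                 sum(s$minSteps[keep]) / sum(s$perCharLengths[keep]))
  }
})

test_that("zero homoplasy gives CI 1 and a constant matrix CI/RI of 1", {
  tr <- ape::rtree(6, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:6)
  pm <- perfectMatrix(tr)
  expect_equal(fitchLength(tr, pm)$ci, 1)
  const <- characterMatrix(lapply(1:6, function(i) list(0L)),
                           taxa = paste0("t", 1:6))
  s <- fitchLength(tr, const)
  expect_equal(s$totalLength, 0L)
  expect_equal(s$ci, 1)
  expect_equal(s$ri, 1)
})

test_that("appending characters moves the indices the right way", {
  set.seed(106)
  tr <- ape::rtree(6, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:6)
  m <- randomMatrix(6, 5, nStates = 3, pMissing = 0, pPoly = 0)
  base <- fitchLength(tr, m)
  # constant character: length unchanged
  mConst <- m
  mConst$masks <- cbind(m$masks, 1L)  # all taxa state 0
  mConst$missing <- cbind(m$missing, FALSE)
  mConst$ordered <- c(m$ordered, FALSE)
  expect_equal(fitchLength(tr, mConst)$totalLength, base$totalLength)
  # homoplasy-free split character: CI cannot decrease
  pm <- perfectMatrix(tr)
  mPlus <- m
  mPlus$masks <- cbind(m$masks, pm$masks[match(m$taxa, pm$taxa), 1])
  mPlus$missing <- cbind(m$missing, FALSE)
  mPlus$ordered <- c(m$ordered, FALSE)
  expect_gte(fitchLength(tr, mPlus)$ci, base$ci)
})

test_that("per-character step tables export cleanly", {
  tr <- ape::rtree(5, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:5)
  m <- randomMatrix(5, 4)
  df <- writeStepsTable(fitchLength(tr, m))
  expect_equal(nrow(df), 4)
  expect_true(all(df$min_steps <= df$observed_steps))
  expect_true(all(df$observed_steps <= pmax(df$max_steps, df$min_steps)))
})
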