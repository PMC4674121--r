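test_that("squared-change parsimony solves the worked three-tip case", {
  rec <- squaredChangeParsimony(readNewick("((A,B),C);"), c(A = 0, B = 0, C = 3))
  v <- rec$nodeValues
  expect_equal(unname(v[["node5"]]), 0.6)   # ancestor of A,B
  expect_equal(unname(v[["node4"]]), 1.8)   # root
  expect_equal(rec$objective, 3.6)
  # constant tips: everything constant, objective zero
  rec0 <- squaredChangeParsimony(readNewick("((A,B),C);"), c(A = 5, B = 5, C = 5))
  expect_true(all(rec0$nodeValues == 5))
  expect_equal(rec0$objective, 0)
  expect_error(squaredChangeParsimony(readNewick("((A,B),C);"), c(A = 1, B = 2)),
               "C")
})

test_that("the reconstruction minimizes the quadratic (numeric oracle)", {
  set.seed(401)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    if (i %% 2 == 0) tr <- ape::di2multi(ape::rtree(n), tol = Inf)  # polytomy
    x <- stats::setNames(runif(n, 0, 600), tr$tip.label)
    rec <- squaredChangeParsimony(tr, x)
    # generic quadratic minimization with analytic gradient
    nn <- tr$Nnode
    obj <- function(v) {
      all <- c(unname(x[tr$tip.label]), v)
      sum((all[tr$edge[, 1]] - all[tr$edge[, 2]])^2)
    }
    grad <- function(v) {
      all <- c(unname(x[tr$tip.label]), v)
      g <- numeric(length(all))
      for (r in seq_len(nrow(tr$edge))) {
        d <- all[tr$edge[r, 1]] - all[tr$edge[r, 2]]
        g[tr$edge[r, 1]] <- g[tr$edge[r, 1]] + 2 * d
        g[tr$edge[r, 2]] <- g[tr$edge[r, 2]] - 2 * d
      }
      g[(n + 1):(n + nn)]
    }
    opt <- stats::optim(rep(mean(x), nn), obj, grad, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 1000))
    expect_equal(rec$objective, opt$value, tolerance = 1e-9)
    # mean-of-neighbors first-order condition
    expect_lt(cachalot:::meanOfNeighborsResidual(rec), 1e-9)
    # internal values lie within the tip range
    expect_true(all(rec$nodeValues >= min(x) - 1e-9 &
                    rec$nodeValues <= max(x) + 1e-9))
  }
})

test_that("direct solve agrees with iterative local averaging", {
  set.seed(402)
  tr <- ape::rtree(10)
  x <- stats::setNames(runif(10, 0, 100), tr$tip.label)
  rec <- squaredChangeParsimony(tr, x)
  # Gauss-Seidel: repeatedly replace internal values by neighbor means
  n <- 10; nn <- tr$Nnode
  adj <- vector("list", n + nn)
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1]; c <- tr$edge[r, 2]
    adj[[p]] <- c(adj[[p]], c); adj[[c]] <- c(adj[[c]], p)
  }
  v <- c(unname(x[tr$tip.label]), rep(mean(x), nn))
  for (it in 1:3000) {
    for (i in (n + 1):(n + nn)) v[i] <- mean(v[adj[[i]]])
  }
  expect_equal(unname(rec$nodeValues), v, tolerance = 1e-8)
})

test_that("reconstruction matches Brownian-motion ML on unit branches", {
  skip_if_not_installed("phytools")
  set.seed(403)
  tr <- ape::rtree(12)
  tr$edge.length <- rep(1, nrow(tr$edge))
  x <- stats::setNames(runif(12, 40, 500), tr$tip.label)
  rec <- squaredChangeParsimony(tr, x)
  fa <- phytools::fastAnc(tr, x)
  expect_equal(unname(rec$nodeValues[13:(12 + tr$Nnode)]), as.numeric(fa),
               tolerance = 1e-6)
})

test_that("reconstruction is affine-equivariant", {
  set.seed(404)
  tr <- ape::rtree(8)
  x <- stats::setNames(runif(8, 0, 10), tr$tip.label)
  a <- 3.7; b <- -12
  r1 <- squaredChangeParsimony(tr, x)
  r2 <- squaredChangeParsimony(tr, a * x + b)
  expect_equal(unname(r2$nodeValues), a * unname(r1$nodeValues) + b,
               tolerance = 1e-9)
  expect_equal(r2$objective, a^2 * r1$objective, tolerance = 1e-9)
})

test_that("equal-width binning assigns the documented bins", {
  # values spanning [0, 600]: width 100, so 250 falls in bin 3
  tr <- ape::stree(4, "star", tip.label = c("A", "B", "C", "D"))
  rec <- squaredChangeParsimony(tr, c(A = 0, B = 600, C = 250, D = 300))
  rec <- binTraits(rec, nBins = 6)
  expect_equal(unname(rec$bins[["C"]]), 3L)
  expect_equal(unname(rec$bins[["A"]]), 1L)
  expect_equal(unname(rec$bins[["B"]]), 6L)  # right-closed last bin
  expect_true(all(rec$bins >= 1 & rec$bins <= 6))
  expect_equal(length(rec$bins), length(rec$nodeValues))  # a partition
  # degenerate range: everything in bin 1
  recc <- binTraits(squaredChangeParsimony(tr, c(A = 2, B = 2, C = 2, D = 2)))
  expect_true(all(recc$bins == 1L))
  expect_error(binTraits(rec, nBins = 1), "nBins")
})

test_that("stratigraphic range annotation validates and attaches", {
  tr <- readNewick("((Albicetus_oxymycterus,Livyatan_melvillei),Zygorhiza_kochii);")
  ok <- data.frame(taxon = "Albicetus_oxymycterus", first_ma = 16, last_ma = 14)
  out <- annotateStratRanges(tr, ok)
  expect_equal(attr(out, "stratRanges")$first_ma, 16)
  bad <- data.frame(taxon = "Albicetus_oxymycterus", first_ma = 14, last_ma = 16)
  expect_error(annotateStratRanges(tr, bad), "inverted")
  expect_identical(annotateStratRanges(tr, ok[0, ]), tr)  # empty: unchanged
  expect_error(annotateStratRanges(tr, data.frame(taxon = "Nobody",
                                                  first_ma = 2, last_ma = 1)),
               "Nobody")
  full <- readTraitTable(fixturePath("physeteroid_strat_ranges_synthetic.csv"),
                         sep = ",")
  expect_true(all(full$cbl_cm > 0))  # parses as a generic two-column table
})

test_that("reconstruction exports annotated newick and node tables", {
  tr <- readNewick("((A,B),C);")
  rec <- binTraits(squaredChangeParsimony(tr, c(A = 0, B = 0, C = 3)))
  nf <- tempfile(fileext = ".nwk"); tf <- tempfile(fileext = ".tsv")
  df <- writeReconstruction(rec, newickFile = nf, tableFile = tf)
  expect_true(file.exists(nf) && file.exists(tf))
  expect_true(any(grepl("value=", readLines(nf))))
  expect_equal(nrow(df), 5)
})
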