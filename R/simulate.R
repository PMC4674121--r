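## Synthetic-data generators: discrete character matrices evolved on known
## trees under a symmetric Mk process, and bivariate allometric reference
## tables with known slope/intercept/noise. Every generator is a pure
## function of (config, seed).

#' Simulate a random (Yule) tree
#'
#' A pure-birth topology with unit edge lengths, as a neutral source of
#' test phylogenies.
#'
#' @param nTaxa Number of leaves (>= 3).
#' @param seed Optional integer seed.
#' @return A `phylo` tree with tip labels `t1..tN` and all edge lengths 1.
#' @export
simulateTree <- function(nTaxa, seed = NULL) {
  if (nTaxa < 3) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(nTaxa, birth = 1, death = 0)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Configuration for Mk-style matrix simulation
#'
#' @param nChars Number of characters.
#' @param nStates Number of states (2..4; morphological matrices here use
#'   codes 0-3).
#' @param rate Per-edge change probability of the symmetric Mk process.
#' @param propMissing Proportion of cells replaced by `?`.
#' @param propPolymorphic Proportion of cells unioned with one random
#'   additional state.
#' @param seed Optional integer seed used by [simulateMatrix()].
#' @return An `mkSimConfig` list.
#' @export
mkSimConfig <- function(nChars, nStates = 4, rate = 0.1, propMissing = 0,
                        propPolymorphic = 0, seed = NULL) {
  if (nStates < 2 || nStates > 4) stop("nStates must be in 2..4")
  if (rate < 0 || rate > 1) stop("rate must be a probability")
  if (propMissing < 0 || propMissing > 1 || propPolymorphic < 0 ||
      propPolymorphic > 1) stop("proportions must be in [0,1]")
  structure(list(nChars = as.integer(nChars), nStates = as.integer(nStates),
                 rate = rate, propMissing = propMissing,
                 propPolymorphic = propPolymorphic, seed = seed),
            class = "mkSimConfig")
}

#' Simulate a discrete character matrix on a tree
#'
#' Each character evolves independently down the tree under a symmetric
#' Mk process: the root state is uniform over the `nStates` states, and
#' along each edge the state changes with probability `rate`, moving to one
#' of the other states uniformly. Missing (`?`) and polymorphic cells are
#' then injected at the configured rates; a polymorphic cell is the union
#' of the true state with one random other state.
#'
#' @param tree A `phylo` tree.
#' @param config An [mkSimConfig()].
#' @return A `charMatrix` whose taxa are the tree's tip labels.
#' @export
simulateMatrix <- function(tree, config) {
  stopifnot(inherits(config, "mkSimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  k <- config$nStates
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  nChars <- config$nChars

  states <- matrix(0L, n + nn, nChars)
  root <- edge[1, 1]
  states[root, ] <- sample.int(k, nChars, replace = TRUE) - 1L
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]; ch <- edge[r, 2]
    flip <- stats::runif(nChars) < config$rate
    s <- states[p, ]
    if (any(flip)) {
      shift <- sample.int(k - 1L, sum(flip), replace = TRUE)
      s[flip] <- (s[flip] + shift) %% k
    }
    states[ch, ] <- s
  }

  tipStates <- states[seq_len(n), , drop = FALSE]
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    row <- vector("list", nChars)
    for (j in seq_len(nChars)) row[[j]] <- tipStates[i, j]
    cells[[i]] <- row
  }
  if (config$propPolymorphic > 0) {
    poly <- stats::runif(n * nChars) < config$propPolymorphic
    for (idx in which(poly)) {
      i <- ((idx - 1L) %% n) + 1L
      j <- ((idx - 1L) %/% n) + 1L
      other <- sample(setdiff(0:(k - 1L), cells[[i]][[j]]), 1L)
      cells[[i]][[j]] <- sort(c(cells[[i]][[j]], other))
    }
  }
  if (config$propMissing > 0) {
    missFlag <- stats::runif(n * nChars) < config$propMissing
    for (idx in which(missFlag)) {
      i <- ((idx - 1L) %% n) + 1L
      j <- ((idx - 1L) %/% n) + 1L
      cells[[i]][[j]] <- "?"
    }
  }
  characterMatrix(cells, taxa = tree$tip.label, symbols = 0:(k - 1L))
}

#' Configuration for allometric reference-data simulation
#'
#' Defaults emulate a physeteroid reference set: 36 specimens spanning the
#' pygmy-sperm-whale-to-sperm-whale size range, with the published
#' coefficient pairs as the generating relationships.
#'
#' @param nSpecimens Number of reference specimens (>= 3; default 36).
#' @param coefficients Coefficient list as in [physeteroidCoefficients()].
#' @param residualSd Gaussian residual standard deviation (cm) applied to
#'   each generated relationship (default 15).
#' @param aonRange Range (cm) of the uniform antorbital notch widths
#'   (default 10-200 cm, roughly Kogia to Physeter).
#' @param seed Optional integer seed used by [simulateAllometry()].
#' @return An `allometrySimConfig` list.
#' @export
allometrySimConfig <- function(nSpecimens = 36,
                               coefficients = physeteroidCoefficients(),
                               residualSd = 15, aonRange = c(10, 200),
                               seed = NULL) {
  if (nSpecimens < 3) stop("nSpecimens must be >= 3")
  if (residualSd < 0) stop("residualSd must be >= 0")
  structure(list(nSpecimens = as.integer(nSpecimens),
                 coefficients = coefficients, residualSd = residualSd,
                 aonRange = aonRange, seed = seed),
            class = "allometrySimConfig")
}

#' Simulate an allometric reference table
#'
#' Draws antorbital notch widths uniformly over the configured range and
#' generates condylobasal length from `CBL = a*AON + b`, rostrum length via
#' the rostrum-corrected relationship `CBL - RL = a*AON + b`, and total
#' length from `TL = a*CBL + b`, each plus independent Gaussian noise of
#' the configured standard deviation. (The fourth published relationship,
#' `(TL - CBL) ~ AON`, is then determined by composition rather than
#' generated independently; the four cannot all hold exactly at once.)
#'
#' @param config An [allometrySimConfig()].
#' @return A data frame with columns `AON`, `CBL`, `RL`, `TL` (cm), ready
#'   for [pipelineFromData()].
#' @export
simulateAllometry <- function(config) {
  stopifnot(inherits(config, "allometrySimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$nSpecimens
  co <- config$coefficients
  sd <- config$residualSd
  lin <- function(pair, x) unname(pair["slope"]) * x + unname(pair["intercept"])
  aon <- stats::runif(n, config$aonRange[1], config$aonRange[2])
  cbl <- lin(co$cblFromAON, aon) + stats::rnorm(n, 0, sd)
  rl <- cbl - (lin(co$cblMinusRLFromAON, aon) + stats::rnorm(n, 0, sd))
  tl <- lin(co$tlFromCBL, cbl) + stats::rnorm(n, 0, sd)
  data.frame(AON = aon, CBL = cbl, RL = rl, TL = tl)
}
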