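#' Squared-change parsimony reconstruction of a continuous trait
#'
#' Maps a continuous trait (here typically condylobasal length in cm, a
#' cetacean body-size proxy) onto a tree by minimizing the sum of squared
#' changes along edges, all edges weighted equally (the unweighted variant
#' appropriate for a consensus tree without branch lengths). Tip values are
#' fixed at the observations; internal values are free. The minimizer of
#' this positive-definite quadratic is unique and satisfies the
#' mean-of-neighbors condition: every internal value equals the average of
#' the values at its adjacent nodes. It is found by a direct sparse linear
#' solve of the normal equations.
#'
#' The reconstruction is performed on the (rooted) display tree as given;
#' the root value is reported but depends on root placement. Polytomies are
#' handled naturally.
#'
#' @param tree A `phylo` tree (polytomies allowed; branch lengths ignored).
#' @param traits A named numeric vector of tip values, or a `traitTable`
#'   from [readTraitTable()]. Every tip must have a value.
#' @return A `traitReconstruction`: list with `tree`, `nodeValues` (numeric
#'   vector over all nodes, tips first, named by tip label or node id),
#'   `objective` (the minimized sum of squared changes), `rootValue`.
#' @examples
#' tr <- readNewick("((A,B),C);")
#' rec <- squaredChangeParsimony(tr, c(A = 0, B = 0, C = 3))
#' rec$objective  # 3.6
#' @export
squaredChangeParsimony <- function(tree, traits) {
  if (inherits(traits, "traitTable")) traits <- traitVector(traits)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  tipN <- normalizeLabel(tree$tip.label)
  names(traits) <- normalizeLabel(names(traits))
  missingTips <- setdiff(tipN, names(traits))
  if (length(missingTips)) {
    stop("no trait value for tip(s): ", paste(missingTips, collapse = ", "))
  }
  tipVals <- unname(traits[tipN])

  vals <- numeric(n + nn)
  vals[seq_len(n)] <- tipVals
  if (nn > 0L) {
    A <- matrix(0, nn, nn)
    b <- numeric(nn)
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
      pi <- p - n
      A[pi, pi] <- A[pi, pi] + 1
      if (c > n) {
        ci <- c - n
        A[ci, ci] <- A[ci, ci] + 1
        A[pi, ci] <- A[pi, ci] - 1
        A[ci, pi] <- A[ci, pi] - 1
      } else {
        b[pi] <- b[pi] + tipVals[c]
      }
    }
    vals[(n + 1L):(n + nn)] <- solve(A, b)
  }
  objective <- sum((vals[tree$edge[, 1]] - vals[tree$edge[, 2]])^2)
  names(vals) <- c(tree$tip.label, paste0("node", (n + 1L):(n + nn)))
  structure(list(tree = tree, nodeValues = vals, objective = objective,
                 rootValue = vals[n + 1L], bins = NULL, nBins = NULL),
            class = "traitReconstruction")
}

#' @export
print.traitReconstruction <- function(x, ...) {
  cat(sprintf("Squared-change parsimony reconstruction: %d tips, %d internal nodes, objective %.4g\n",
              length(x$tree$tip.label), x$tree$Nnode, x$objective))
  if (!is.null(x$bins)) cat(sprintf("  binned into %d equal-width classes\n", x$nBins))
  invisible(x)
}

# largest |node value - mean of adjacent values| over internal nodes;
# a solver sanity check (should be ~0)
meanOfNeighborsResidual <- function(rec) {
  tree <- rec$tree
  n <- length(tree$tip.label)
  v <- rec$nodeValues
  adj <- vector("list", n + tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
  }
  resid <- vapply((n + 1L):(n + tree$Nnode), function(i) {
    abs(v[i] - mean(v[adj[[i]]]))
  }, numeric(1))
  max(resid)
}

#' Discretize reconstructed trait values into equal-width bins
#'
#' Bins all node values (tips and internals) into `nBins` equal-width
#' classes over their observed range, as used to color body size classes on
#' a phylogeny. Bins are left-closed with a right-closed last bin; a
#' degenerate range puts every node in bin 1.
#'
#' @param rec A `traitReconstruction`.
#' @param nBins Number of bins (default 6).
#' @return The reconstruction with a `bins` integer vector added.
#' @export
binTraits <- function(rec, nBins = 6) {
  if (nBins < 2) stop("nBins must be >= 2")
  v <- rec$nodeValues
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    bins <- rep(1L, length(v))
  } else {
    width <- (hi - lo) / nBins
    bins <- pmin(as.integer(floor((v - lo) / width)) + 1L, as.integer(nBins))
  }
  rec$bins <- stats::setNames(bins, names(v))
  rec$nBins <- as.integer(nBins)
  rec
}

#' Attach stratigraphic ranges to a tree for plotting/export
#'
#' Ranges are first/last occurrence ages in Ma (ages decrease toward the
#' present, so `first >= last > 0` is required). No computation is
#' performed beyond validation; the ranges are attached as an attribute.
#'
#' @param tree A `phylo` tree.
#' @param ranges Data frame with columns `taxon`, `first_ma`, `last_ma`.
#'   An empty set of ranges returns the tree unchanged.
#' @return The tree with attribute `stratRanges`.
#' @export
annotateStratRanges <- function(tree, ranges) {
  if (is.null(ranges) || nrow(ranges) == 0L) return(tree)
  need <- c("taxon", "first_ma", "last_ma")
  if (!all(need %in% names(ranges))) {
    stop("ranges must have columns taxon, first_ma, last_ma")
  }
  bad <- ranges$first_ma < ranges$last_ma
  if (any(bad)) {
    stop("inverted stratigraphic range (first < last) for: ",
         paste(ranges$taxon[bad], collapse = ", "))
  }
  if (any(ranges$last_ma < 0 | ranges$first_ma <= 0)) {
    stop("stratigraphic ages must be positive")
  }
  unknown <- setdiff(normalizeLabel(ranges$taxon), normalizeLabel(tree$tip.label))
  if (length(unknown)) {
    stop("range taxa not in the tree: ", paste(unknown, collapse = ", "))
  }
  attr(tree, "stratRanges") <- ranges
  tree
}

#' Export a reconstruction as annotated Newick and a node table
#'
#' Writes the tree with `value=...,bin=...` comments on node labels and,
#' optionally, a TSV of node id, reconstructed value and bin.
#'
#' @param rec A `traitReconstruction` (binned or not).
#' @param newickFile,tableFile Output paths (`NULL` to skip).
#' @return The node table data frame, invisibly.
#' @export
writeReconstruction <- function(rec, newickFile = NULL, tableFile = NULL) {
  v <- rec$nodeValues
  df <- data.frame(node = names(v), value = unname(v),
                   bin = if (is.null(rec$bins)) NA_integer_ else unname(rec$bins))
  if (!is.null(tableFile)) {
    utils::write.table(df, tableFile, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(newickFile)) {
    tr <- rec$tree
    n <- length(tr$tip.label)
    fmt <- function(i) {
      s <- sprintf("[&value=%.6g", v[i])
      if (!is.null(rec$bins)) s <- paste0(s, sprintf(",bin=%d", rec$bins[i]))
      paste0(s, "]")
    }
    tr$node.label <- vapply((n + 1L):(n + tr$Nnode), fmt, character(1))
    writeLines(ape::write.tree(tr), newickFile)
  }
  invisible(df)
}
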