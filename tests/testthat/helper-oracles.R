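# Independent oracles used across the suite. These deliberately avoid the
# package's compiled search/scoring path: scoring is exhaustive minimization
# over internal-node labelings, topology enumeration is recursive leaf
# addition, and TBR is a naive double-loop rearrangement in plain R.

# all unrooted binary topologies on n labelled leaves, as edge matrices
# (tips 1..n, internals n+1...). 3 leaves -> 1, 5 -> 15, 6 -> 105, 7 -> 945.
allTopologyEdges <- function(n) {
  grow <- function(edges, nextTaxon) {
    if (nextTaxon > n) return(list(edges))
    out <- list()
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      w <- max(edges) + 1L
      ne <- rbind(edges[-r, , drop = FALSE], c(a, w), c(b, w), c(w, nextTaxon))
      out <- c(out, grow(ne, nextTaxon + 1L))
    }
    out
  }
  start <- matrix(as.integer(c(n + 1, 1, n + 1, 2, n + 1, 3)), ncol = 2, byrow = TRUE)
  grow(start, 4L)
}

# exhaustive minimum-change score of one matrix on one tree: minimize over
# every assignment of states to internal nodes (tips may take any state in
# their set at no cost).
oracleFitchLength <- function(edge, m) {
  nTip <- length(m$taxa)
  internals <- sort(setdiff(unique(as.vector(edge)), seq_len(nTip)))
  nInt <- length(internals)
  symbols <- m$symbols
  grids <- do.call(expand.grid, rep(list(symbols), nInt))
  total <- 0L
  for (ch in seq_len(ncol(m$masks))) {
    cost <- numeric(nrow(grids))
    for (r in seq_len(nrow(edge))) {
      a <- edge[r, 1]; b <- edge[r, 2]
      if (a > nTip && b > nTip) {
        sa <- grids[[match(a, internals)]]
        sb <- grids[[match(b, internals)]]
        cost <- cost + (sa != sb)
      } else {
        tip <- min(a, b); int <- max(a, b)
        si <- grids[[match(int, internals)]]
        tipSet <- cachalot::stateSet(m, tip, ch)
        cost <- cost + !(si %in% tipSet)
      }
    }
    total <- total + min(cost)
  }
  as.integer(total)
}

# random character matrix with arbitrary cells (not Mk-generated)
randomMatrix <- function(nTaxa, nChars, nStates = 3, pMissing = 0.1,
                         pPoly = 0.1) {
  cells <- lapply(seq_len(nTaxa), function(i) {
    lapply(seq_len(nChars), function(j) {
      u <- runif(1)
      if (u < pMissing) return("?")
      if (u < pMissing + pPoly && nStates > 1) {
        sort(sample(0:(nStates - 1), 2))
      } else {
        sample(0:(nStates - 1), 1)
      }
    })
  })
  characterMatrix(cells, taxa = paste0("t", seq_len(nTaxa)),
                  symbols = 0:(nStates - 1))
}

# naive double-loop TBR: cut every edge, suppress the freed node on each
# fragment, reattach every edge/leaf pairing; return distinct neighbor
# topology signatures (input excluded).
naiveTbrSignatures <- function(tree) {
  et <- cachalot:::edgesFromPhylo(tree)
  edge <- et$edge; nTip <- et$nTip
  m <- nrow(edge)
  comp <- function(rows, start) {
    seen <- start
    repeat {
      hit <- rows[rows[, 1] %in% seen | rows[, 2] %in% seen, , drop = FALSE]
      nxt <- setdiff(unique(as.vector(hit)), seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    seen
  }
  suppress <- function(rows, endNode) {
    if (nrow(rows) == 0L) return(NULL)
    inc <- which(rows[, 1] == endNode | rows[, 2] == endNode)
    nbr <- vapply(inc, function(i) setdiff(rows[i, ], endNode), integer(1))
    list(edge = rbind(rows[-inc, , drop = FALSE], nbr), free = endNode)
  }
  sigOf <- function(e) cachalot::topologySignature(
    cachalot:::phyloFromEdges(e, nTip, et$labels))
  self <- sigOf(edge)
  sigs <- character()
  for (r in seq_len(m)) {
    u <- edge[r, 1]; v <- edge[r, 2]
    others <- edge[-r, , drop = FALSE]
    sideU <- comp(others, u)
    rowsU <- others[others[, 1] %in% sideU & others[, 2] %in% sideU, , drop = FALSE]
    rowsV <- others[!(others[, 1] %in% sideU & others[, 2] %in% sideU), , drop = FALSE]
    fu <- suppress(rowsU, u)
    fv <- suppress(rowsV, v)
    if (is.null(fu) && is.null(fv)) next
    if (is.null(fu) || is.null(fv)) {
      leaf <- if (is.null(fu)) u else v
      tree <- if (is.null(fu)) fv else fu
      for (ib in seq_len(nrow(tree$edge))) {
        ne <- rbind(tree$edge[-ib, , drop = FALSE],
                    c(tree$edge[ib, 1], tree$free),
                    c(tree$edge[ib, 2], tree$free),
                    c(tree$free, leaf))
        sigs <- c(sigs, sigOf(ne))
      }
    } else {
      for (ia in seq_len(nrow(fu$edge))) for (ib in seq_len(nrow(fv$edge))) {
        ne <- rbind(fu$edge[-ia, , drop = FALSE], fv$edge[-ib, , drop = FALSE],
                    c(fu$edge[ia, 1], fu$free), c(fu$edge[ia, 2], fu$free),
                    c(fv$edge[ib, 1], fv$free), c(fv$edge[ib, 2], fv$free),
                    c(fu$free, fv$free))
        sigs <- c(sigs, sigOf(ne))
      }
    }
  }
  setdiff(unique(sigs), self)
}

# a homoplasy-free ("perfect") matrix on a given binary tree: one binary
# character per internal edge, marking the smaller side of the split
perfectMatrix <- function(tree, copies = 1) {
  labs <- tree$tip.label
  splits <- cachalot::treeSplits(tree)
  cells <- lapply(labs, function(l) {
    unlist(lapply(rep(splits, each = copies), function(s) {
      as.integer(l %in% strsplit(s, ",", fixed = TRUE)[[1]])
    }), recursive = FALSE)
  })
  cells <- lapply(cells, as.list)
  characterMatrix(cells, taxa = labs, symbols = 0:1)
}

fixturePath <- function(f) system.file("extdata", f, package = "cachalot")
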