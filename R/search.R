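## Heuristic maximum-parsimony tree search: random-addition starting trees
## refined by tree-bisection-reconnection (TBR), retaining all tied shortest
## trees (plateau search), as in the standard morphological-parsimony
## workflow.
##
## Internally trees are bare integer edge matrices with undirected
## semantics: tips 1..nTip (matching the matrix taxon order), internal
## nodes above nTip. TBR enumeration, Fitch scoring and topology
## signatures run in compiled code.

#' Search configuration
#'
#' @param nReplicates Number of random-addition-sequence replicates
#'   (default 100).
#' @param seed Integer seed; mandatory, recorded in the search log.
#' @param maxTrees Cap on the number of tied shortest trees retained during
#'   plateau search (default 10000). Exceeding it flags the result as
#'   truncated.
#' @param steepestDescent If `TRUE`, each TBR sweep scans the full
#'   neighborhood and takes the best neighbor; the default accepts the
#'   first shorter neighbor found, which reaches the same local optima
#'   faster.
#' @return A `searchConfig` list.
#' @export
searchConfig <- function(nReplicates = 100, seed = NULL, maxTrees = 10000,
                         steepestDescent = FALSE) {
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  structure(list(nReplicates = as.integer(nReplicates), seed = seed,
                 maxTrees = as.integer(maxTrees),
                 steepestDescent = isTRUE(steepestDescent)),
            class = "searchConfig")
}

# ---- edge-matrix utilities ------------------------------------------------

edgesFromPhylo <- function(tree) {
  tr <- ape::unroot(tree)
  storage.mode(tr$edge) <- "integer"
  list(edge = tr$edge, nTip = length(tr$tip.label), labels = tr$tip.label)
}

phyloFromEdges <- function(edge, nTip, labels) {
  # orient away from an internal node and renumber internals n+1, n+2, ...
  maxNode <- max(edge)
  adj <- vector("list", maxNode)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- edge[1, 1]
  if (root <= nTip) root <- edge[1, 2]
  newId <- integer(maxNode)
  newId[seq_len(nTip)] <- seq_len(nTip)
  nextId <- nTip + 1L
  out <- matrix(0L, nrow(edge), 2)
  k <- 0L
  stack <- list(c(root, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1]; p <- top[2]
    if (v > nTip) { newId[v] <- nextId; nextId <- nextId + 1L }
    if (p > 0L) { k <- k + 1L; out[k, ] <- c(newId[p], newId[v]) }
    for (w in adj[[v]]) if (w != p && w > nTip) stack[[length(stack) + 1L]] <- c(w, v)
    for (w in adj[[v]]) if (w != p && w <= nTip) { k <- k + 1L; out[k, ] <- c(newId[v], w) }
  }
  tr <- structure(list(edge = out, tip.label = labels, Nnode = maxNode - nTip),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

edgeSignature <- function(edge, nTip) edge_signature_cpp(edge, nTip)

# split signatures (label-based, canonical, matching treeSplits()) straight
# from a search edge matrix
edgeSplitSigs <- function(edge, sd) {
  labs <- normalizeLabel(sd$labels)
  ref <- sort(labs)[1]
  splits <- edge_splits_cpp(edge, sd$nTip)
  out <- vapply(splits, function(tips) {
    sideLabs <- labs[tips]
    if (ref %in% sideLabs) sideLabs <- setdiff(labs, sideLabs)
    paste(sort(sideLabs), collapse = ",")
  }, character(1))
  sort(unique(out))
}

#' All tree-bisection-reconnection neighbors of a tree
#'
#' Enumerates every distinct unrooted topology obtained by bisecting an
#' edge of `tree` and reconnecting an edge (or the lone leaf) of one
#' fragment to any edge of the other. The input topology itself is not
#' returned.
#'
#' @param tree An unrooted binary `phylo` tree with at least 4 leaves.
#' @return A `multiPhylo` of distinct neighbor topologies.
#' @export
tbrNeighbors <- function(tree) {
  et <- edgesFromPhylo(tree)
  if (et$nTip < 4L) stop("TBR needs at least 4 leaves")
  if (nrow(et$edge) != 2L * et$nTip - 3L) stop("tree must be binary (unrooted)")
  out <- lapply(tbr_neighbors_cpp(et$edge, et$nTip), phyloFromEdges,
                nTip = et$nTip, labels = et$labels)
  class(out) <- "multiPhylo"
  out
}

# ---- random addition ------------------------------------------------------

# masks/nStates prepared once per matrix
searchData <- function(m) {
  list(masks = m$masks, nStates = max(m$symbols) + 1L,
       nTip = length(m$taxa), labels = m$taxa)
}

BIGBOUND <- .Machine$integer.max - 1L

randomAdditionEdges <- function(sd) {
  nTip <- sd$nTip
  ord <- sample.int(nTip)
  nextInternal <- nTip + 1L
  edge <- rbind(c(nextInternal, ord[1]), c(nextInternal, ord[2]),
                c(nextInternal, ord[3]))
  storage.mode(edge) <- "integer"
  nextInternal <- nextInternal + 1L
  if (nTip > 3L) {
    for (t in ord[4:nTip]) {
      best <- Inf
      bestRows <- integer()
      for (r in seq_len(nrow(edge))) {
        cand <- attachAt(edge, r, t, nextInternal)
        len <- fitch_total_cpp(cand, nTip, sd$masks, sd$nStates, BIGBOUND)
        if (len < best) { best <- len; bestRows <- r }
        else if (len == best) bestRows <- c(bestRows, r)
      }
      pick <- if (length(bestRows) == 1L) bestRows else sample(bestRows, 1L)
      edge <- attachAt(edge, pick, t, nextInternal)
      nextInternal <- nextInternal + 1L
    }
  }
  edge
}

attachAt <- function(edge, r, tip, newNode) {
  a <- edge[r, 1]; b <- edge[r, 2]
  rbind(edge[-r, , drop = FALSE], c(a, newNode), c(b, newNode), c(newNode, tip))
}

#' Random-addition-sequence starting tree
#'
#' Inserts the taxa in random order, each at the attachment point that
#' minimizes the incremental parsimony length; ties are broken at random.
#' With a fixed seed the result is reproducible.
#'
#' @param m A `charMatrix` with at least 3 taxa.
#' @param seed Optional integer seed.
#' @return A `phylo` tree.
#' @export
randomAdditionTree <- function(m, seed = NULL) {
  if (length(m$taxa) < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  sd <- searchData(m)
  phyloFromEdges(randomAdditionEdges(sd), sd$nTip, sd$labels)
}

# ---- hill climbing --------------------------------------------------------

# TBR hill climb to a local optimum; returns edges, length, neighbor count.
tbrClimb <- function(edge, sd, steepest = FALSE) {
  cur <- fitch_total_cpp(edge, sd$nTip, sd$masks, sd$nStates, BIGBOUND)
  tried <- 0L
  if (sd$nTip < 4L) return(list(edge = edge, length = cur, tried = tried))
  repeat {
    step <- tbr_improve_cpp(edge, sd$nTip, sd$masks, sd$nStates, cur, steepest)
    tried <- tried + step$tried
    if (nrow(step$edge) == 0L) break
    edge <- step$edge
    cur <- step$length
  }
  list(edge = edge, length = cur, tried = tried)
}

#' Heuristic maximum-parsimony search
#'
#' Runs `nReplicates` random-addition-sequence replicates, refines each by
#' TBR branch swapping until no rearrangement is shorter, and collects all
#' distinct unrooted topologies tying the best length. The tied set is then
#' closed under TBR at constant length (plateau search): every equal-length
#' neighbor of a retained tree is itself retained and swapped, up to
#' `maxTrees`.
#'
#' @param m A `charMatrix`.
#' @param config A [searchConfig()]; `config$seed` is mandatory.
#' @return A `searchResult`: list with `bestLength`, `trees` (a
#'   `multiPhylo` of distinct shortest trees), `log` (per-replicate data
#'   frame), `truncated`, `seed`.
#' @examples
#' m <- simulateMatrix(simulateTree(6, seed = 1),
#'                     mkSimConfig(nChars = 20, seed = 2))
#' res <- heuristicSearch(m, searchConfig(nReplicates = 5, seed = 3))
#' res$bestLength
#' @export
heuristicSearch <- function(m, config = searchConfig()) {
  if (is.null(config$seed)) stop("a seed is required for heuristic search")
  set.seed(config$seed)
  sd <- searchData(m)
  best <- .Machine$integer.max
  pool <- list()        # edge matrices at best length
  sigs <- new.env(parent = emptyenv())
  log <- data.frame(replicate = integer(), start_length = integer(),
                    end_length = integer(), rearrangements = integer())
  addTree <- function(edge) {
    sig <- edgeSignature(edge, sd$nTip)
    if (is.null(sigs[[sig]])) {
      sigs[[sig]] <- TRUE
      pool[[length(pool) + 1L]] <<- edge
      TRUE
    } else FALSE
  }
  resetPool <- function() {
    pool <<- list()
    sigs <<- new.env(parent = emptyenv())
  }

  for (rep in seq_len(config$nReplicates)) {
    start <- randomAdditionEdges(sd)
    startLen <- fitch_total_cpp(start, sd$nTip, sd$masks, sd$nStates, BIGBOUND)
    cl <- tbrClimb(start, sd, steepest = config$steepestDescent)
    log <- rbind(log, data.frame(replicate = rep, start_length = startLen,
                                 end_length = cl$length,
                                 rearrangements = cl$tried))
    if (cl$length < best) { best <- cl$length; resetPool() }
    if (cl$length == best) addTree(cl$edge)
  }

  truncated <- FALSE
  if (sd$nTip >= 4L) {
    i <- 1L
    while (i <= length(pool)) {
      if (length(pool) >= config$maxTrees) { truncated <- TRUE; break }
      nb <- tbr_within_cpp(pool[[i]], sd$nTip, sd$masks, sd$nStates, best,
                           10L * config$maxTrees)
      shorter <- which(nb$lengths < best)
      if (length(shorter)) {
        cl <- tbrClimb(nb$edges[[shorter[1]]], sd,
                       steepest = config$steepestDescent)
        best <- cl$length
        resetPool()
        addTree(cl$edge)
        i <- 1L
        next
      }
      for (e in nb$edges) {
        if (length(pool) >= config$maxTrees) { truncated <- TRUE; break }
        addTree(e)
      }
      i <- i + 1L
    }
  }

  trees <- lapply(pool, phyloFromEdges, nTip = sd$nTip, labels = sd$labels)
  class(trees) <- "multiPhylo"
  structure(list(bestLength = best, trees = trees, log = log,
                 truncated = truncated, seed = config$seed, config = config,
                 poolEdges = pool, taxa = sd$labels),
            class = "searchResult")
}

#' @export
print.searchResult <- function(x, ...) {
  cat(sprintf("Parsimony search: best length %d, %d tree(s)%s, %d replicate(s), seed %s\n",
              x$bestLength, length(x$trees),
              if (x$truncated) " [truncated]" else "",
              nrow(x$log), format(x$seed)))
  invisible(x)
}

#' Collapse branches that require no character change
#'
#' Contracts every internal branch whose contraction leaves the parsimony
#' length unchanged, i.e. branches on which no character unambiguously
#' demands a change. Used to compare shortest-tree counts under the two
#' common branch-collapse conventions.
#'
#' @param tree A `phylo` tree.
#' @param m The `charMatrix` the tree was scored against.
#' @return A `phylo` tree, possibly with polytomies.
#' @export
collapseZeroLengthBranches <- function(tree, m) {
  et <- edgesFromPhylo(tree)
  idx <- match(normalizeLabel(et$labels), normalizeLabel(m$taxa))
  masks <- m$masks[idx, , drop = FALSE]
  nStates <- max(m$symbols) + 1L
  base <- fitch_total_cpp(et$edge, et$nTip, masks, nStates, BIGBOUND)
  edge <- et$edge
  internal <- which(edge[, 1] > et$nTip & edge[, 2] > et$nTip)
  drop <- logical(nrow(edge))
  for (r in internal) {
    contracted <- contractEdge(edge, r)
    len <- fitch_total_cpp(contracted, et$nTip, masks, nStates, BIGBOUND)
    if (len == base) drop[r] <- TRUE
  }
  for (r in rev(which(drop))) edge <- contractEdge(edge, r)
  phyloFromEdges(edge, et$nTip, et$labels)
}

contractEdge <- function(edge, r) {
  a <- edge[r, 1]; b <- edge[r, 2]
  out <- edge[-r, , drop = FALSE]
  out[out == b] <- a
  out
}

#' Number of distinct unrooted topologies in a tree set
#'
#' @param trees `multiPhylo` or list of `phylo`.
#' @return Integer count after deduplication by unrooted topology.
#' @export
countUniqueTopologies <- function(trees) {
  length(unique(vapply(as.list(trees), topologySignature, character(1))))
}
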