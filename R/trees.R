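#' Read and write Newick trees
#'
#' Thin, validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. `readNewick` rejects unbalanced parentheses and
#' duplicate leaf labels; round trips preserve the leaf set, polytomies and
#' the unrooted topology.
#'
#' @param text A Newick string, a character vector of lines, or a file path.
#' @return A `phylo` tree.
#' @export
readNewick <- function(text) {
  s <- paste(asLines(text), collapse = "")
  nOpen <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  nClose <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (nOpen != nClose) stop("unbalanced parentheses in Newick string")
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @rdname readNewick
#' @param tree A `phylo` tree.
#' @param file Optional output path; if `NULL` the Newick string is returned.
#' @export
writeNewick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Unrooted bipartitions (splits) of a tree
#'
#' Returns the nontrivial splits of a tree as a character vector of
#' canonical signatures, one per internal edge. Each split is represented by
#' the side *not* containing the alphabetically first leaf, as a sorted,
#' comma-separated label string, so signatures are invariant to rooting and
#' to leaf order in the Newick string.
#'
#' @param tree A `phylo` tree (rooted or unrooted; polytomies allowed).
#' @return Character vector of split signatures (may be empty for a star).
#' @export
treeSplits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  ref <- labs[order(labs)][1]
  clades <- cladeLeafSets(tree)
  sigs <- vapply(clades, function(cl) {
    side <- if (ref %in% cl) setdiff(labs, cl) else cl
    paste(sort(side), collapse = ",")
  }, character(1))
  sigs <- sigs[vapply(clades, function(cl) {
    k <- length(cl); k >= 2L && k <= n - 2L
  }, logical(1))]
  sort(unique(sigs))
}

# Leaf label sets below each internal node (root included; trivial clades too).
cladeLeafSets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- vector("list", n + nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  sets <- vector("list", n + nn)
  po <- postorderNodes(tree)
  for (v in po) {
    sets[[v]] <- if (v <= n) tree$tip.label[v]
                 else unlist(lapply(kids[[v]], function(k) sets[[k]]))
  }
  sets[(n + 1L):(n + nn)]
}

postorderNodes <- function(tree) {
  # children-before-parents node ordering derived from the edge matrix
  ord <- ape::reorder.phylo(tree, "postorder")
  root <- ord$edge[nrow(ord$edge), 1]
  c(ord$edge[, 2], root)
}

#' Canonical topology signature of an unrooted tree
#'
#' Two trees have equal signatures iff they have the same leaf set and the
#' same unrooted topology. Used to deduplicate trees found in heuristic
#' search.
#'
#' @param tree A `phylo` tree.
#' @return A single string.
#' @export
topologySignature <- function(tree) {
  paste(c(paste(sort(tree$tip.label), collapse = ","), treeSplits(tree)),
        collapse = "|")
}

#' Strict consensus of a set of trees
#'
#' The tree whose split set is the intersection of the input trees' unrooted
#' bipartitions; groups on which the inputs disagree collapse into
#' polytomies.
#'
#' @param trees A `multiPhylo` or list of `phylo` trees on one leaf set.
#' @return An unrooted `phylo` tree.
#' @examples
#' t1 <- readNewick("((A,B),C,(D,E));")
#' t2 <- readNewick("((A,C),B,(D,E));")
#' writeNewick(strictConsensus(list(t1, t2)))
#' @export
strictConsensus <- function(trees) {
  trees <- as.list(trees)
  if (length(trees) == 0L) stop("no trees supplied")
  leafSets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leafSets, identical, logical(1), y = leafSets[[1]]))) {
    stop("trees have differing leaf sets")
  }
  shared <- Reduce(intersect, lapply(trees, treeSplits))
  buildTreeFromSplits(shared, leafSets[[1]])
}

# Build an unrooted tree realizing a pairwise-compatible set of splits.
# Splits use the treeSplits() convention (side excluding the first label).
buildTreeFromSplits <- function(splits, labels) {
  labels <- sort(labels)
  n <- length(labels)
  clades <- lapply(splits, function(s) sort(strsplit(s, ",", fixed = TRUE)[[1]]))
  clades <- clades[order(-lengths(clades))]
  # rooted view: root = all labels; each split-side (excluding ref leaf) is a clade
  nodes <- c(list(labels), clades)
  nTip <- n
  nNode <- length(nodes)
  nodeId <- seq.int(nTip + 1L, nTip + nNode)
  parentOf <- function(k) {
    # smallest strictly-containing clade (nodes are sorted by decreasing size)
    for (q in rev(seq_len(k - 1L))) {
      if (all(nodes[[k]] %in% nodes[[q]])) return(nodeId[q])
    }
    nodeId[1]
  }
  edges <- matrix(0L, 0, 2)
  for (k in seq_along(nodes)[-1]) edges <- rbind(edges, c(parentOf(k), nodeId[k]))
  for (i in seq_len(nTip)) {
    lab <- labels[i]
    best <- nodeId[1]; bestSize <- n + 1L
    for (k in seq_along(nodes)) {
      if (lab %in% nodes[[k]] && length(nodes[[k]]) < bestSize) {
        best <- nodeId[k]; bestSize <- length(nodes[[k]])
      }
    }
    edges <- rbind(edges, c(best, i))
  }
  tr <- structure(list(edge = edges, tip.label = labels, Nnode = nNode),
                  class = "phylo", order = "cladewise")
  tr <- ape::collapse.singles(tr)
  ape::unroot(tr)
}
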