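#' Nonparametric bootstrap clade support
#'
#' Each replicate resamples the characters with replacement, reruns the
#' heuristic search at (typically reduced) effort, and records the clades of
#' that replicate's strict consensus of shortest trees. A clade's support is
#' the percentage of replicates whose consensus contains it.
#'
#' @param m A `charMatrix`.
#' @param nReplicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed (mandatory); per-replicate search seeds are
#'   derived from it.
#' @param searchReplicates Addition-sequence replicates per bootstrap
#'   replicate (default 10; reduced effort relative to a full search).
#' @param maxTrees Tied-tree cap passed to the per-replicate search.
#' @return A `supportSummary`: list with `table` (data frame: `clade`
#'   signature, `count`, `bootstrap_pct`), `majorityTree` (majority-rule
#'   consensus `phylo` with support percentages as node labels),
#'   `replicateSplits` (per-replicate consensus clade sets), `nReplicates`,
#'   `seed`.
#' @export
bootstrapSupport <- function(m, nReplicates = 100, seed = NULL,
                             searchReplicates = 10, maxTrees = 100) {
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  if (is.null(seed)) stop("a seed is required for the bootstrap")
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
  colSamples <- replicate(nReplicates, sample.int(nChars(m), replace = TRUE),
                          simplify = FALSE)
  tally <- new.env(parent = emptyenv())
  repSplits <- vector("list", nReplicates)
  for (b in seq_len(nReplicates)) {
    mb <- subsetChars(m, colSamples[[b]])
    res <- heuristicSearch(mb, searchConfig(nReplicates = searchReplicates,
                                            seed = repSeeds[b],
                                            maxTrees = maxTrees))
    sdLoc <- list(labels = res$taxa, nTip = length(res$taxa))
    splits <- Reduce(intersect, lapply(res$poolEdges, edgeSplitSigs, sd = sdLoc))
    repSplits[[b]] <- splits
    for (s in splits) {
      tally[[s]] <- if (is.null(tally[[s]])) 1L else tally[[s]] + 1L
    }
  }
  clades <- ls(tally)
  counts <- vapply(clades, function(s) tally[[s]], integer(1))
  tab <- data.frame(clade = clades, count = counts,
                    bootstrap_pct = 100 * counts / nReplicates,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$bootstrap_pct, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  majSplits <- tab$clade[tab$count > nReplicates / 2]
  maj <- buildTreeFromSplits(majSplits, sort(normalizeLabel(m$taxa)))
  maj <- annotateSupport(maj, tab)
  structure(list(table = tab, majorityTree = maj, replicateSplits = repSplits,
                 nReplicates = nReplicates, seed = seed),
            class = "supportSummary")
}

#' @export
print.supportSummary <- function(x, ...) {
  what <- if (!is.null(x$table$bootstrap_pct)) "bootstrap" else "decay"
  cat(sprintf("Clade support (%s): %d clade(s)\n", what, nrow(x$table)))
  print(utils::head(x$table, 10))
  invisible(x)
}

# attach support values (from a clade table) as node labels of a tree
annotateSupport <- function(tree, tab) {
  sigs <- treeSplits(tree)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  n <- length(labs)
  nodeLab <- rep("", tree$Nnode)
  clades <- cladeLeafSets(tree)
  for (i in seq_along(clades)) {
    cl <- clades[[i]]
    if (length(cl) < 2L || length(cl) > n - 2L) next
    side <- if (ref %in% cl) setdiff(labs, cl) else cl
    sig <- paste(sort(side), collapse = ",")
    hit <- match(sig, tab$clade)
    if (!is.na(hit)) {
      val <- if (!is.null(tab$bootstrap_pct)) tab$bootstrap_pct[hit] else tab$decay[hit]
      nodeLab[i] <- format(val, trim = TRUE)
    }
  }
  tree$node.label <- nodeLab
  tree
}

#' Bootstrap percentage of a particular clade
#'
#' @param summary A `supportSummary` from [bootstrapSupport()].
#' @param tips Character vector of the taxa forming the clade.
#' @param allTaxa All taxon labels of the analysis (used to canonicalize the
#'   split); defaults to the union seen in the summary's majority tree.
#' @return Percentage in \[0, 100\] (0 if never seen).
#' @export
cladeSupport <- function(summary, tips, allTaxa = summary$majorityTree$tip.label) {
  sig <- canonicalSplit(tips, allTaxa)
  hit <- match(sig, summary$table$clade)
  if (is.na(hit)) 0 else summary$table$bootstrap_pct[hit]
}

canonicalSplit <- function(tips, allTaxa) {
  tips <- normalizeLabel(tips)
  allTaxa <- normalizeLabel(allTaxa)
  ref <- sort(allTaxa)[1]
  side <- if (ref %in% tips) setdiff(allTaxa, tips) else tips
  paste(sort(side), collapse = ",")
}

#' Bremer decay indices
#'
#' For `k = 1 .. kMax`, collects (heuristically) the trees of length at most
#' `bestLength + k` by closing the shortest-tree set under TBR within the
#' length threshold, and takes the strict consensus at each `k`. A clade's
#' decay index is the smallest `k` at which it drops out of that consensus;
#' clades still present at `kMax` are reported as `Inf` (i.e. "> kMax").
#'
#' @param m A `charMatrix`.
#' @param search A `searchResult` from [heuristicSearch()] (supplies the
#'   shortest trees and best length).
#' @param kMax Largest extra length examined (>= 1).
#' @param maxTrees Cap on retained suboptimal trees.
#' @return A `supportSummary` with `table` columns `clade` and `decay`, and
#'   `consensusTree` (the shortest-tree strict consensus annotated with
#'   decay values).
#' @export
bremerDecay <- function(m, search, kMax = 3, maxTrees = 20000) {
  if (kMax < 1) stop("kMax must be >= 1")
  sd <- searchData(m)
  best <- search$bestLength
  cap <- best + kMax
  pool <- list()
  lens <- integer()
  sigs <- new.env(parent = emptyenv())
  addTree <- function(edge, len) {
    sig <- edgeSignature(edge, sd$nTip)
    if (is.null(sigs[[sig]])) {
      sigs[[sig]] <- TRUE
      pool[[length(pool) + 1L]] <<- edge
      lens[length(lens) + 1L] <<- len
      TRUE
    } else FALSE
  }
  startEdges <- if (!is.null(search$poolEdges)) search$poolEdges
                else lapply(search$trees, function(tr) {
                  et <- edgesFromPhylo(tr)
                  perm <- match(normalizeLabel(et$labels), normalizeLabel(sd$labels))
                  edge <- et$edge
                  edge[edge <= et$nTip] <- perm[edge[edge <= et$nTip]]
                  edge
                })
  for (edge in startEdges) addTree(edge, best)
  i <- 1L
  truncated <- FALSE
  while (i <= length(pool) && sd$nTip >= 4L) {
    if (length(pool) >= maxTrees) { truncated <- TRUE; break }
    nb <- tbr_within_cpp(pool[[i]], sd$nTip, sd$masks, sd$nStates, cap,
                         10L * maxTrees)
    for (k in seq_along(nb$edges)) {
      if (length(pool) >= maxTrees) { truncated <- TRUE; break }
      addTree(nb$edges[[k]], nb$lengths[k])
    }
    i <- i + 1L
  }

  splitsOf <- function(maxLen) {
    keep <- which(lens <= maxLen)
    Reduce(intersect, lapply(pool[keep], function(e) edgeSplitSigs(e, sd)))
  }
  base <- splitsOf(best)
  decay <- rep(Inf, length(base))
  for (k in seq_len(kMax)) {
    sk <- splitsOf(best + k)
    lost <- is.infinite(decay) & !(base %in% sk)
    decay[lost] <- k
  }
  tab <- data.frame(clade = base, decay = decay, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$decay, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  cons <- strictConsensus(search$trees)
  cons <- annotateSupport(cons, tab)
  structure(list(table = tab, consensusTree = cons, kMax = kMax,
                 truncated = truncated, bestLength = best),
            class = "supportSummary")
}

#' Write a clade support table as TSV
#'
#' @param bootstrap Optional `supportSummary` from [bootstrapSupport()].
#' @param decay Optional `supportSummary` from [bremerDecay()].
#' @param file Output path, or `NULL` to return the merged data frame.
#' @return Data frame with `clade`, `bootstrap_pct`, `decay` columns (as
#'   available), invisibly when written.
#' @export
writeSupportTable <- function(bootstrap = NULL, decay = NULL, file = NULL) {
  if (is.null(bootstrap) && is.null(decay)) stop("nothing to write")
  tabs <- list()
  if (!is.null(bootstrap)) tabs$b <- bootstrap$table[, c("clade", "bootstrap_pct")]
  if (!is.null(decay)) tabs$d <- decay$table
  df <- if (length(tabs) == 2L) merge(tabs$b, tabs$d, by = "clade", all = TRUE)
        else tabs[[1]]
  if (!is.null(file)) utils::write.table(df, file, sep = "\t", row.names = FALSE,
                                         quote = FALSE)
  invisible(df)
}
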