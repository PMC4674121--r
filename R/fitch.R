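#' Parsimony length and homoplasy indices of a tree
#'
#' Scores a tree against a [characterMatrix()] under minimum-change
#' (Fitch) parsimony with all characters unordered. Tip cells initialize
#' from their state sets, so polymorphic cells (`{01}`) may adopt any listed
#' state at no cost and missing cells (`?`) any state at all. Scoring uses
#' the max-count (Hartigan) recursion, which returns the exact minimum
#' number of changes on multifurcating as well as binary trees and is
#' independent of root placement.
#'
#' The ensemble consistency index is `CI = sum(minSteps)/L` and the
#' retention index `RI = (sum(maxSteps) - L)/(sum(maxSteps) - sum(minSteps))`,
#' where `L` is the observed tree length. By default all characters enter
#' the sums (the convention of the common parsimony programs);
#' `includeUninformative = FALSE` drops characters that cannot show
#' homoplasy on any tree (constant columns and autapomorphies). A tree
#' length of zero gives `CI = RI = 1` by convention.
#'
#' @param tree A `phylo` tree whose tip labels match the matrix taxa
#'   (underscores and spaces are interchangeable).
#' @param m A `charMatrix`.
#' @param includeUninformative Include parsimony-uninformative characters in
#'   the CI/RI sums? Default `TRUE`.
#' @return An object of class `parsimonyScore`: list with `totalLength`,
#'   `perCharLengths`, `ci`, `ri`, `minSteps`, `maxSteps`.
#' @examples
#' m <- characterMatrix(list(A = list(0), B = list(1), C = list(0), D = list(1)),
#'                      taxa = c("A", "B", "C", "D"))
#' fitchLength(readNewick("((A,B),(C,D));"), m)$totalLength
#' @export
fitchLength <- function(tree, m, includeUninformative = TRUE) {
  stopifnot(inherits(m, "charMatrix"))
  tipN <- normalizeLabel(tree$tip.label)
  taxN <- normalizeLabel(m$taxa)
  if (!setequal(tipN, taxN) || length(tipN) != length(taxN)) {
    stop("tree leaves and matrix taxa differ; in tree only: ",
         paste(setdiff(tipN, taxN), collapse = ", "),
         "; in matrix only: ", paste(setdiff(taxN, tipN), collapse = ", "))
  }
  idx <- match(tipN, taxN)
  masks <- m$masks[idx, , drop = FALSE]
  nStates <- max(m$symbols) + 1L
  counts <- fitch_counts_cpp(treeEdgeForScoring(tree), length(tipN), masks, nStates)
  mins <- vapply(seq_len(nChars(m)), function(j) minSteps(m, j), integer(1))
  maxs <- vapply(seq_len(nChars(m)), function(j) maxSteps(m, j), integer(1))
  score <- scoreFromCounts(counts, mins, maxs, includeUninformative)
  score$tree <- tree
  score
}

scoreFromCounts <- function(counts, mins, maxs, includeUninformative = TRUE) {
  keep <- if (includeUninformative) rep(TRUE, length(counts)) else mins < maxs
  L <- sum(counts[keep])
  smin <- sum(mins[keep])
  smax <- sum(maxs[keep])
  ci <- if (L == 0L) 1 else smin / L
  ri <- if (smax == smin) 1 else (smax - L) / (smax - smin)
  structure(
    list(totalLength = sum(counts), perCharLengths = as.integer(counts),
         ci = ci, ri = ri, minSteps = mins, maxSteps = maxs,
         includeUninformative = includeUninformative),
    class = "parsimonyScore"
  )
}

#' @export
print.parsimonyScore <- function(x, ...) {
  cat(sprintf("Parsimony score: length %d, CI %.3f, RI %.3f (%d characters)\n",
              x$totalLength, x$ci, x$ri, length(x$perCharLengths)))
  invisible(x)
}

# edge matrix with a usable root for the C++ scorer; ape trees qualify as-is
treeEdgeForScoring <- function(tree) {
  storage.mode(tree$edge) <- "integer"
  tree$edge
}

#' Best-case (minimum) steps of one character over all trees
#'
#' The length of character `char` on its most favourable tree: the smallest
#' number of states that can jointly cover every scoreable cell, minus one.
#' Polymorphic cells may resolve to any of their states; missing cells are
#' ignored.
#'
#' @param m A `charMatrix`.
#' @param char Character (column) index.
#' @return Integer step count (0 for a constant or empty column).
#' @export
minSteps <- function(m, char) {
  cells <- m$masks[!m$missing[, char], char]
  if (length(cells) == 0L) return(0L)
  full <- statesToMask(m$symbols)
  nb <- max(m$symbols) + 1L
  # smallest hitting set over <= 10 states, by increasing subset size
  for (size in 1:length(m$symbols)) {
    for (sub in subsetsOfSize(m$symbols, size)) {
      sm <- statesToMask(sub)
      if (all(bitwAnd(cells, sm) != 0L)) return(size - 1L)
    }
  }
  length(m$symbols) - 1L
}

subsetsOfSize <- function(set, k) {
  if (k > length(set)) return(list())
  asplit(utils::combn(set, k), 2)
}

#' Worst-case (maximum) steps of one character over all trees
#'
#' The length of character `char` on its least favourable tree: the number
#' of scoreable (non-missing) cells minus the largest frequency any single
#' state can attain, resolving polymorphic cells in favour of the dominant
#' state.
#'
#' @inheritParams minSteps
#' @return Integer step count.
#' @export
maxSteps <- function(m, char) {
  cells <- m$masks[!m$missing[, char], char]
  n <- length(cells)
  if (n == 0L) return(0L)
  freq <- vapply(m$symbols, function(s) sum(bitwAnd(cells, bitwShiftL(1L, s)) != 0L),
                 integer(1))
  n - max(freq)
}

#' Is a character parsimony-informative?
#'
#' A character is uninformative when its best- and worst-case lengths agree
#' (constant columns and autapomorphies): it can never display homoplasy.
#'
#' @inheritParams minSteps
#' @export
isInformative <- function(m, char) minSteps(m, char) < maxSteps(m, char)

#' Ensemble consistency and retention indices
#'
#' @inheritParams fitchLength
#' @return List with elements `ci` and `ri`.
#' @export
homoplasyIndices <- function(tree, m, includeUninformative = TRUE) {
  s <- fitchLength(tree, m, includeUninformative = includeUninformative)
  list(ci = s$ci, ri = s$ri)
}

#' Export per-character step counts as a TSV table
#'
#' @param score A `parsimonyScore`.
#' @param file Output path, or `NULL` to return the data frame.
#' @return Data frame with character index, min, max and observed steps.
#' @export
writeStepsTable <- function(score, file = NULL) {
  df <- data.frame(character = seq_along(score$perCharLengths),
                   min_steps = score$minSteps, max_steps = score$maxSteps,
                   observed_steps = score$perCharLengths)
  if (!is.null(file)) utils::write.table(df, file, sep = "\t", row.names = FALSE,
                                         quote = FALSE)
  invisible(df)
}
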