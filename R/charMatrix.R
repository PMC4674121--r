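#' Discrete morphological character matrix
#'
#' A `charMatrix` stores a taxa-by-characters grid of *state sets*. Each cell
#' holds the set of integer states (codes 0--9) consistent with the
#' observation: a single state for an ordinary coding, several states for a
#' polymorphic/uncertain coding such as `0/1`, and the full symbol set for a
#' missing (`?`) cell. State sets are held internally as integer bitmasks
#' (bit *s* set means state *s* is in the set), which is the natural
#' representation for Fitch-style set operations.
#'
#' @param stateSets A list of length `n_taxa`; each element a list of
#'   length `n_chars` of integer vectors (the state set of that cell). A
#'   cell may also be the string `"?"` for missing.
#' @param taxa Character vector of unique taxon labels.
#' @param symbols Integer vector of legal state codes for the matrix
#'   (default the states actually observed; missing cells expand to this
#'   full set).
#' @param charLabels Optional character vector of per-character labels.
#' @param ordered Logical vector of per-character ordering flags. All
#'   `FALSE` here: every analysis in this package treats characters as
#'   unordered.
#'
#' @return An object of class `charMatrix` with fields `taxa`, `masks`
#'   (integer bitmask matrix), `missing` (logical matrix), `symbols`,
#'   `charLabels`, `ordered`.
#' @seealso [readNexus()], [writeNexus()], [fitchLength()]
#' @examples
#' m <- characterMatrix(
#'   list(A = list(0, 1), B = list(0, c(0, 1)), C = list(1, "?")),
#'   taxa = c("A", "B", "C")
#' )
#' stateSet(m, "B", 2)
#' @export
characterMatrix <- function(stateSets, taxa = names(stateSets),
                            symbols = NULL, charLabels = NULL,
                            ordered = NULL) {
  if (is.null(taxa)) stop("taxon labels are required")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  nTaxa <- length(taxa)
  if (length(stateSets) != nTaxa) stop("one row of cells per taxon required")
  nChars <- length(stateSets[[1L]])
  if (nTaxa == 0L || nChars == 0L) stop("matrix must have >= 1 taxon and >= 1 character")
  lens <- vapply(stateSets, length, integer(1))
  if (any(lens != nChars)) {
    stop("rows with wrong character count: ",
         paste(taxa[lens != nChars], collapse = ", "))
  }

  observed <- sort(unique(unlist(lapply(stateSets, function(row) {
    unlist(lapply(row, function(cell) if (identical(cell, "?")) integer() else cell))
  }))))
  if (is.null(symbols)) symbols <- observed
  symbols <- sort(unique(as.integer(symbols)))
  if (length(symbols) == 0L) symbols <- 0L
  if (any(symbols < 0L | symbols > 9L)) stop("state codes must lie in 0..9")
  if (length(setdiff(observed, symbols)) > 0L) {
    stop("undeclared state symbol(s) outside the symbol set: ",
         paste(setdiff(observed, symbols), collapse = ", "))
  }
  fullMask <- statesToMask(symbols)

  masks <- matrix(0L, nTaxa, nChars, dimnames = list(taxa, NULL))
  miss <- matrix(FALSE, nTaxa, nChars, dimnames = list(taxa, NULL))
  for (i in seq_len(nTaxa)) {
    row <- stateSets[[i]]
    for (j in seq_len(nChars)) {
      cell <- row[[j]]
      if (identical(cell, "?")) {
        masks[i, j] <- fullMask
        miss[i, j] <- TRUE
      } else {
        st <- as.integer(cell)
        if (length(st) < 1L) stop("empty state set at taxon ", taxa[i], ", character ", j)
        masks[i, j] <- statesToMask(st)
      }
    }
  }

  if (!is.null(charLabels) && length(charLabels) != nChars) {
    stop("charLabels must have one entry per character")
  }
  if (is.null(ordered)) ordered <- rep(FALSE, nChars)

  structure(
    list(taxa = taxa, masks = masks, missing = miss, symbols = symbols,
         charLabels = charLabels, ordered = as.logical(ordered)),
    class = "charMatrix"
  )
}

statesToMask <- function(states) {
  states <- unique(as.integer(states))
  if (any(states < 0L | states > 9L)) stop("state codes must lie in 0..9")
  sum(bitwShiftL(1L, states))
}

maskToStates <- function(mask) {
  which(bitwAnd(bitwShiftR(as.integer(mask), 0:9), 1L) == 1L) - 1L
}

#' @rdname characterMatrix
#' @param x A `charMatrix`.
#' @export
taxonLabels <- function(x) x$taxa

#' @rdname characterMatrix
#' @export
nChars <- function(x) ncol(x$masks)

#' @rdname characterMatrix
#' @param taxon Taxon label or row index.
#' @param char Character (column) index.
#' @export
stateSet <- function(x, taxon, char) {
  maskToStates(x$masks[taxon, char])
}

#' @rdname characterMatrix
#' @export
isMissing <- function(x, taxon, char) x$missing[taxon, char]

#' @export
print.charMatrix <- function(x, ...) {
  cat("charMatrix:", length(x$taxa), "taxa x", nChars(x), "characters;",
      "symbols {", paste(x$symbols, collapse = " "), "};",
      sum(x$missing), "missing cells\n")
  invisible(x)
}

#' @export
dim.charMatrix <- function(x) dim(x$masks)

#' Extract characters (columns) from a character matrix
#'
#' Column subsetting with replacement is what the bootstrap uses to resample
#' characters.
#'
#' @param x A `charMatrix`.
#' @param j Column indices (may repeat).
#' @return A new `charMatrix` with the selected characters.
#' @export
subsetChars <- function(x, j) {
  out <- x
  out$masks <- x$masks[, j, drop = FALSE]
  out$missing <- x$missing[, j, drop = FALSE]
  out$charLabels <- if (!is.null(x$charLabels)) x$charLabels[j]
  out$ordered <- x$ordered[j]
  out
}

#' @export
all.equal.charMatrix <- function(target, current, ...) {
  if (!inherits(current, "charMatrix")) return("not a charMatrix")
  msgs <- character()
  if (!identical(normalizeLabel(target$taxa), normalizeLabel(current$taxa)))
    msgs <- c(msgs, "taxon labels differ")
  if (!identical(unname(target$masks), unname(current$masks)))
    msgs <- c(msgs, "state sets differ")
  if (!identical(unname(target$missing), unname(current$missing)))
    msgs <- c(msgs, "missingness differs")
  if (length(msgs)) msgs else TRUE
}

# Underscores and spaces are interchangeable in taxon labels (NEXUS habit).
normalizeLabel <- function(x) gsub(" ", "_", trimws(x))
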