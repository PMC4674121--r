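#' Read a NEXUS morphological character matrix
#'
#' Parses the `DATA` or `CHARACTERS` block of a NEXUS document into a
#' [characterMatrix()]. Handles the notations in routine use for
#' paleontological matrices: single-digit states, polymorphism written
#' `{01}`, `(01)` or `0/1` (all read as the state set \{0,1\}), and `?` for
#' a missing cell (the full symbol set). Keywords are case-insensitive and
#' whitespace-insensitive; `[...]` comments are stripped.
#'
#' Polymorphic cells are treated as *uncertainty*: any one of the listed
#' states is acceptable at a tip at no internal cost, which is the standard
#' Fitch handling (see the package vignette).
#'
#' @param file Path to a NEXUS file, or a character vector of lines, or a
#'   single string containing the document.
#' @return A `charMatrix`.
#' @examples
#' nex <- c("#NEXUS", "BEGIN DATA;",
#'          "DIMENSIONS NTAX=2 NCHAR=3;",
#'          "FORMAT SYMBOLS=\"0 1 2\" MISSING=?;",
#'          "MATRIX", "A 0{01}?", "B 1 2 0", ";", "END;")
#' m <- readNexus(nex)
#' stateSet(m, "A", 2)
#' @export
readNexus <- function(file) {
  lines <- asLines(file)
  text <- paste(lines, collapse = "\n")
  text <- stripNexusComments(text)
  if (!grepl("#NEXUS", text, ignore.case = TRUE)) {
    stop("not a NEXUS document (missing #NEXUS header)")
  }

  block <- regmatches(
    text,
    regexpr("(?s)BEGIN\\s+(DATA|CHARACTERS)\\s*;.*?\\bEND\\s*;",
            text, ignore.case = TRUE, perl = TRUE)
  )
  if (length(block) == 0L) stop("no DATA or CHARACTERS block found")
  block <- block[[1]]

  ntax <- nexusNumber(block, "NTAX")
  nchar <- nexusNumber(block, "NCHAR")
  if (is.na(ntax) || is.na(nchar)) stop("DIMENSIONS must declare NTAX and NCHAR")

  missingSym <- "?"
  mm <- regmatches(block, regexpr("MISSING\\s*=\\s*\\S", block, ignore.case = TRUE))
  if (length(mm)) missingSym <- substr(mm, nchar(mm), nchar(mm))

  symbols <- NULL
  sm <- regmatches(block,
                   regexpr("SYMBOLS\\s*=\\s*\"[^\"]*\"", block, ignore.case = TRUE))
  if (length(sm)) {
    symTxt <- sub("(?i)SYMBOLS\\s*=\\s*\"([^\"]*)\"", "\\1", sm, perl = TRUE)
    symChars <- strsplit(gsub("\\s", "", symTxt), "")[[1]]
    if (!all(grepl("^[0-9]$", symChars))) {
      stop("only digit state symbols 0..9 are supported; got: ", symTxt)
    }
    symbols <- as.integer(symChars)
  }

  mtxt <- regmatches(
    block,
    regexpr("(?s)\\bMATRIX\\b(.*?);", block, ignore.case = TRUE, perl = TRUE)
  )
  if (length(mtxt) == 0L) stop("no MATRIX statement found")
  mtxt <- sub("(?i)^MATRIX", "", mtxt[[1]], perl = TRUE)
  mtxt <- sub(";$", "", mtxt)

  mlines <- strsplit(mtxt, "\n", fixed = TRUE)[[1]]
  rows <- list()
  taxa <- character()
  lineOffset <- matrixLineOffset(lines)
  for (k in seq_along(mlines)) {
    ln <- trimws(mlines[[k]])
    if (ln == "") next
    parsed <- parseMatrixRow(ln, missingSym, lineNo = lineOffset + k)
    taxa <- c(taxa, parsed$taxon)
    rows[[length(rows) + 1L]] <- parsed$cells
  }

  if (length(taxa) != ntax) {
    stop("dimension mismatch: NTAX=", ntax, " declared but ",
         length(taxa), " taxon rows found")
  }
  badLen <- vapply(rows, length, integer(1)) != nchar
  if (any(badLen)) {
    stop("dimension mismatch: NCHAR=", nchar, " declared but taxon ",
         paste(taxa[badLen], collapse = ", "), " has a different cell count")
  }

  # characterMatrix() itself rejects states outside the declared symbol set
  characterMatrix(rows, taxa = taxa, symbols = symbols)
}

# Parse "Taxon_name  0 1{01}(23)0/1?" into a taxon label and cell list.
parseMatrixRow <- function(ln, missingSym, lineNo = NA) {
  where <- if (is.na(lineNo)) "" else paste0(" (line ", lineNo, ")")
  lab <- regmatches(ln, regexpr("^('[^']*'|\"[^\"]*\"|\\S+)", ln))
  if (length(lab) == 0L) stop("cannot parse matrix row", where)
  rest <- trimws(substr(ln, nchar(lab) + 1L, nchar(ln)))
  taxon <- gsub("^['\"]|['\"]$", "", lab)
  taxon <- normalizeLabel(taxon)
  if (rest == "") stop("no character data for taxon ", taxon, where)

  chars <- strsplit(gsub("\\s", "", rest), "")[[1]]
  cells <- list()
  i <- 1L
  n <- length(chars)
  err <- function(msg) stop(msg, " for taxon ", taxon, where, call. = FALSE)
  while (i <= n) {
    ch <- chars[i]
    if (ch == missingSym || ch == "?") {
      cells[[length(cells) + 1L]] <- "?"
      i <- i + 1L
    } else if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      states <- integer()
      while (j <= n && chars[j] != close) {
        if (!grepl("^[0-9]$", chars[j])) err(paste0("bad symbol '", chars[j], "' in polymorphism"))
        states <- c(states, as.integer(chars[j]))
        j <- j + 1L
      }
      if (j > n) err("unclosed polymorphism bracket")
      if (length(states) == 0L) err("empty polymorphism bracket")
      cells[[length(cells) + 1L]] <- states
      i <- j + 1L
    } else if (grepl("^[0-9]$", ch)) {
      states <- as.integer(ch)
      i <- i + 1L
      # slash-form polymorphism: 0/1 or 1/2/3
      while (i + 1L <= n && chars[i] == "/" && grepl("^[0-9]$", chars[i + 1L])) {
        states <- c(states, as.integer(chars[i + 1L]))
        i <- i + 2L
      }
      cells[[length(cells) + 1L]] <- states
    } else {
      err(paste0("unexpected symbol '", ch, "'"))
    }
  }
  list(taxon = taxon, cells = cells)
}

#' Write a character matrix as a NEXUS document
#'
#' Emits the canonical dialect used throughout this package: a `DATA` block,
#' digit symbols, curly-brace polymorphism (`{01}`), `?` for missing cells,
#' no interleaving, underscores in taxon labels. `readNexus(writeNexus(m))`
#' recovers `m` exactly (state sets, missingness, labels).
#'
#' @param m A `charMatrix`.
#' @param file Optional path; if `NULL` the document is returned as a
#'   character vector of lines.
#' @return The lines, invisibly when written to a file.
#' @export
writeNexus <- function(m, file = NULL) {
  stopifnot(inherits(m, "charMatrix"))
  if (length(m$taxa) == 0L) stop("cannot write a matrix with no taxa")
  fmtCell <- function(i, j) {
    if (m$missing[i, j]) return("?")
    st <- maskToStates(m$masks[i, j])
    if (length(st) == 1L) as.character(st) else paste0("{", paste(st, collapse = ""), "}")
  }
  labs <- normalizeLabel(m$taxa)
  width <- max(nchar(labs))
  rows <- vapply(seq_along(m$taxa), function(i) {
    cells <- paste(vapply(seq_len(nChars(m)), function(j) fmtCell(i, j), character(1)),
                   collapse = "")
    sprintf("%-*s  %s", width, labs[i], cells)
  }, character(1))
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), nChars(m)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=?;",
            paste(m$symbols, collapse = " ")),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  )
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

asLines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) == 1L) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    file
  }
}

stripNexusComments <- function(text) gsub("\\[[^]]*\\]", "", text)

nexusNumber <- function(block, key) {
  m <- regmatches(block, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), block,
                                 ignore.case = TRUE))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

matrixLineOffset <- function(lines) {
  hit <- grep("^\\s*MATRIX\\b", lines, ignore.case = TRUE)
  if (length(hit)) hit[1] else 0L
}
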