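#' Read a taxon-to-condylobasal-length trait table
#'
#' Reads a delimited table (CSV or TSV) with a taxon column and a
#' condylobasal length column in centimetres, plus an optional provenance
#' column. A `~` prefix on a length marks an approximate value taken from a
#' proxy taxon of similar size; it parses numerically and the entry is
#' flagged `proxy`.
#'
#' @param file Path, lines, or a single string.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A data frame of class `traitTable` with columns `taxon`,
#'   `cbl_cm`, `provenance` (`"measured"` or `"proxy"`).
#' @export
readTraitTable <- function(file, sep = NULL) {
  lines <- asLines(file)
  lines <- lines[trimws(lines) != ""]
  first <- lines[!startsWith(trimws(lines), "#")][1]
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = looksLikeHeader(first, sep),
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "#", quote = "\"")
  if (ncol(df) < 2L) stop("trait table needs at least taxon and CBL columns")
  taxon <- normalizeLabel(as.character(df[[1]]))
  raw <- trimws(as.character(df[[2]]))
  approx <- startsWith(raw, "~")
  cbl <- suppressWarnings(as.numeric(sub("^~", "", raw)))
  bad <- is.na(cbl) | cbl <= 0
  if (any(bad)) {
    stop("non-numeric or non-positive CBL in row(s): ",
         paste(taxon[bad], collapse = ", "))
  }
  if (anyDuplicated(taxon)) {
    stop("duplicate taxa in trait table: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  }
  prov <- if (ncol(df) >= 3L) tolower(trimws(as.character(df[[3]]))) else
    rep("measured", length(taxon))
  prov[approx] <- "proxy"
  prov[!prov %in% c("measured", "proxy")] <- "measured"
  out <- data.frame(taxon = taxon, cbl_cm = cbl, provenance = prov,
                    stringsAsFactors = FALSE)
  class(out) <- c("traitTable", "data.frame")
  out
}

looksLikeHeader <- function(line, sep) {
  fields <- trimws(strsplit(line, sep, fixed = TRUE)[[1]])
  length(fields) >= 2L && is.na(suppressWarnings(as.numeric(sub("^~", "", fields[2]))))
}

#' Named vector of trait values from a trait table
#' @param tab A `traitTable`.
#' @return Named numeric vector (names are normalized taxon labels).
#' @export
traitVector <- function(tab) {
  stats::setNames(tab$cbl_cm, normalizeLabel(tab$taxon))
}
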