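## Alignment input/output and coordinate maps.
##
## Reading normalizes every row to the internal alphabet: uppercase, '.'
## (Stockholm insert-state gap) -> '-', and the ambiguity/rare letters
## B, Z, J, U, O -> 'X'. Lowercase insert-state residues are uppercased and
## treated like any other column; the census does not distinguish match
## states.

.normalizeRows <- function(rows, ids) {
  rows <- toupper(rows)
  rows <- chartr(".BZJUO", "-XXXXX", rows)
  bad <- regexpr(sprintf("[^%s-]", paste(AA_ALPHABET_HPT, collapse = "")),
                 rows)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[1L]
    stop(sprintf(
      "illegal character '%s' at column %d of sequence '%s'",
      substr(rows[k], bad[k], bad[k]), bad[k], ids[k]))
  }
  rows
}

#' Construct an alignment from ids and rows
#'
#' Rows are normalized (uppercased; `.` to `-`; non-standard letters
#' B, Z, J, U, O to `X`) and validated for equal length and unique ids.
#'
#' @param ids character vector of sequence identifiers.
#' @param rows character vector of aligned rows.
#' @param descriptions optional per-sequence descriptions.
#' @return an [HptAlignment-class].
#' @examples
#' hptAlignment(c("a", "b"), c("AH-GK", "AHGGK"))
#' @export
hptAlignment <- function(ids, rows, descriptions = NULL) {
  ids <- as.character(ids)
  if (is.null(descriptions)) descriptions <- rep(NA_character_, length(ids))
  if (length(rows) >= 1L) {
    w <- nchar(rows)
    if (length(unique(w)) != 1L) {
      off <- ids[which(w != w[1L])[1L]]
      stop(sprintf("ragged alignment: sequence '%s' has a different length",
                   off))
    }
  }
  new("HptAlignment", ids = ids,
      rows = unname(.normalizeRows(as.character(rows), ids)),
      descriptions = as.character(descriptions))
}

.sniffFormat <- function(lines) {
  first <- lines[nzchar(trimws(lines))][1L]
  if (is.na(first)) stop("empty alignment file")
  if (startsWith(first, "# STOCKHOLM")) "stockholm"
  else if (startsWith(first, ">")) "fasta"
  else stop("cannot sniff alignment format: expected '# STOCKHOLM 1.0' or '>'")
}

.readStockholm <- function(lines) {
  body <- lines[!grepl("^\\s*(#|//)", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("Stockholm file contains no sequence lines")
  m <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)\\s*$", body))
  ok <- lengths(m) == 3L
  if (any(!ok))
    stop(sprintf("malformed Stockholm sequence line: '%s'", body[!ok][1L]))
  ids <- vapply(m, `[`, "", 2L)
  seqs <- vapply(m, `[`, "", 3L)
  # interleaved blocks: concatenate per id, preserving first-seen order
  rows <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                 paste0, "", collapse = "")
  list(ids = names(rows), rows = unname(rows))
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm (e.g. a Pfam family alignment such as
#' PF01627). Stockholm `#=GF/#=GS/#=GC/#=GR` markup lines are tolerated and
#' ignored; interleaved blocks are concatenated per sequence. Characters are
#' normalized as in [hptAlignment()]. Input row order is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the header), `"fasta"` or `"stockholm"`.
#' @return an [HptAlignment-class].
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AH-GK", ">b", "AHGGK"), tf)
#' readAlignment(tf)
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "auto")
    format <- .sniffFormat(readLines(path, warn = FALSE))
  if (format == "stockholm") {
    st <- .readStockholm(readLines(path, warn = FALSE))
    return(hptAlignment(st$ids, st$rows))
  }
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (!length(ss)) stop("empty FASTA alignment file")
  nm <- names(ss)
  ids <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  hptAlignment(ids, as.character(ss), desc)
}

#' Write a multiple sequence alignment
#'
#' `readAlignment(writeAlignment(aln, ...))` reproduces ids and rows exactly
#' for both formats.
#'
#' @param aln an [HptAlignment-class].
#' @param path output file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "stockholm")) {
  stopifnot(is(aln, "HptAlignment"))
  format <- match.arg(format)
  validObject(aln)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(stats::setNames(aln@rows, aln@ids))
    Biostrings::writeXStringSet(ss, filepath = path, format = "fasta")
  } else {
    w <- max(nchar(aln@ids))
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf("%-*s %s", w, aln@ids, aln@rows),
                 "//"), path)
  }
  invisible(path)
}

#' Map alignment columns to ungapped residue positions
#'
#' For one aligned row, returns an integer vector of length `nchar(row)`
#' whose j-th entry is the 1-based ungapped residue position at alignment
#' column j, or `NA` for gap columns. The inverse map (residue position ->
#' column) is attached as attribute `"inverse"`.
#'
#' @param row a single aligned row (character scalar), already normalized.
#' @return integer vector with attribute `"inverse"`.
#' @examples
#' columnPositionMap("A-CD")   # 1 NA 2 3
#' @export
columnPositionMap <- function(row) {
  stopifnot(is.character(row), length(row) == 1L)
  ch <- strsplit(row, "", fixed = TRUE)[[1L]]
  nongap <- ch != GAP_CHAR
  map <- rep(NA_integer_, length(ch))
  map[nongap] <- seq_len(sum(nongap))
  attr(map, "inverse") <- which(nongap)
  map
}
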