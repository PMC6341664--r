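## Anchor-relative residue conservation census.
##
## Pipeline: remove near-duplicate rows (greedy identity clustering), locate
## the conserved phospho-accepting histidine column, then count the residue
## found k positions downstream of the anchor in ungapped sequence
## coordinates (the "H+k" census), as done for the HPt family around Ypd1
## H64/G68.

.alnMatrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln@rows, "", fixed = TRUE), use.names = FALSE),
              nrow = nSequences(aln), byrow = TRUE)
  rownames(m) <- aln@ids
  m
}

#' Percent identity between two aligned rows
#'
#' Identity over mutually aligned positions: columns where both rows carry a
#' residue (no gap) and neither is the unknown letter `X`. Matches divided by
#' the number of such columns; 0 when there are none.
#'
#' @param a,b aligned rows of equal length (character scalars), or a
#'   two-sequence [HptAlignment-class] subset via `[`.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("AHGK-L", "AHGKGL")  # 1.0 over 5 shared columns
#' @export
pairwiseIdentity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("rows differ in length; identity requires a shared alignment")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  comp <- ca != GAP_CHAR & cb != GAP_CHAR & ca != "X" & cb != "X"
  if (!any(comp)) return(0)
  sum(ca[comp] == cb[comp]) / sum(comp)
}

#' All-pairs percent identity matrix
#'
#' Computes [pairwiseIdentity()] for every pair of rows at once via one-hot
#' residue indicators and matrix cross-products, so the cost is a handful of
#' BLAS calls rather than `n^2` string scans.
#'
#' @param aln an [HptAlignment-class].
#' @return symmetric `n x n` matrix of identity fractions with unit diagonal,
#'   dimnames = sequence ids.
#' @export
pairwiseIdentityMatrix <- function(aln) {
  stopifnot(is(aln, "HptAlignment"))
  mat <- .alnMatrix(aln)
  usable <- mat != GAP_CHAR & mat != "X"
  denom <- tcrossprod(usable * 1)              # mutually aligned, non-X
  matches <- matrix(0, nrow(mat), nrow(mat))
  for (a in AA_STANDARD) {
    ind <- (mat == a) * 1
    if (any(ind > 0)) matches <- matches + tcrossprod(ind)
  }
  ident <- ifelse(denom > 0, matches / denom, 0)
  dimnames(ident) <- list(aln@ids, aln@ids)
  ident
}

#' Greedy redundancy removal at an identity threshold
#'
#' Single deterministic pass in input row order: each row joins the first
#' existing cluster whose *representative* has identity at least `threshold`
#' to it (identity as in [pairwiseIdentity()]); otherwise it founds a new
#' cluster. Representatives are the founding rows. With the default 0.98 this
#' mirrors the common alignment-viewer "remove redundancy at 98% identity"
#' operation.
#'
#' @param aln an [HptAlignment-class].
#' @param threshold identity threshold in (0, 1].
#' @return a [RedundancyResult-class].
#' @export
removeRedundancy <- function(aln, threshold = 0.98) {
  stopifnot(is(aln, "HptAlignment"))
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold <= 1))
    stop("threshold must be a single fraction in (0, 1]")
  n <- nSequences(aln)
  # identity of row i to any candidate representative j < i
  if (n <= 4000L) {
    im <- pairwiseIdentityMatrix(aln)
    identTo <- function(i, reps) im[i, reps]
  } else {                                     # low-memory fallback
    rows <- aln@rows
    identTo <- function(i, reps)
      vapply(reps, function(j) pairwiseIdentity(rows[i], rows[j]), 0)
  }
  repIdx <- integer(0)                         # representative row indices
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- if (length(repIdx))
      which(identTo(i, repIdx) >= threshold)[1L] else NA_integer_
    if (!is.na(hit)) assign[i] <- hit
    else {
      repIdx <- c(repIdx, i)
      assign[i] <- length(repIdx)
    }
  }
  keptIds <- aln@ids[repIdx]
  clusters <- lapply(seq_along(repIdx), function(k) aln@ids[assign == k])
  names(clusters) <- keptIds
  new("RedundancyResult", keptIds = keptIds, clusters = clusters,
      threshold = threshold)
}

#' Locate the conserved anchor (phospho-histidine) column
#'
#' The anchor column is the alignment column maximizing the fraction of rows
#' carrying `anchorResidue` (ties broken by the lowest column index). Rows
#' without the anchor residue in that column are listed for removal,
#' mirroring "any sequence lacking a conserved phosphorylatable histidine was
#' removed".
#'
#' @param aln an [HptAlignment-class].
#' @param anchorResidue the anchor letter, default `"H"`.
#' @param minFreq minimum anchor frequency; below it no conserved anchor
#'   exists and an error is raised.
#' @return an [AnchorResult-class].
#' @export
findAnchorColumn <- function(aln, anchorResidue = "H", minFreq = 0.5) {
  stopifnot(is(aln, "HptAlignment"))
  mat <- .alnMatrix(aln)
  freq <- colMeans(mat == anchorResidue)
  col <- which.max(freq)                      # ties -> lowest index
  if (freq[col] < minFreq)
    stop(sprintf(
      "no conserved anchor: best '%s' column frequency %.3f is below %.3f",
      anchorResidue, freq[col], minFreq))
  removed <- aln@ids[mat[, col] != anchorResidue]
  new("AnchorResult", anchorCol = as.integer(col),
      anchorFreq = freq[[col]], anchorResidue = anchorResidue,
      removedIds = removed)
}

#' Residue at an anchor-relative offset, in sequence coordinates
#'
#' Returns the residue `k` positions downstream of the anchor column in the
#' *ungapped* sequence (gap columns are skipped), or `NA` when the sequence
#' ends before reaching the offset ("too short").
#'
#' @param row one aligned row (character scalar).
#' @param anchorCol 1-based alignment column of the anchor; must hold a
#'   residue in this row.
#' @param k non-negative integer offset.
#' @return single residue letter, or `NA_character_` if too short.
#' @examples
#' residueAtOffset("AH--GKLG", 2, 4)  # "L": gaps are skipped
#' @export
residueAtOffset <- function(row, anchorCol, k) {
  map <- columnPositionMap(row)
  if (anchorCol < 1L || anchorCol > length(map))
    stop("anchorCol outside the alignment")
  pos <- map[anchorCol]
  if (is.na(pos))
    stop("row has a gap at the anchor column; filter such rows first")
  inv <- attr(map, "inverse")
  target <- pos + k
  if (target > length(inv)) return(NA_character_)
  substr(row, inv[target], inv[target])
}

#' Census of residues at anchor + k over an alignment
#'
#' Counts, over the retained rows (those not in `anchor@removedIds`), the
#' residue found `k` positions downstream of the anchor in ungapped sequence
#' coordinates. Rows too short to reach the offset are tallied in `nShort`
#' and excluded from `total`.
#'
#' @param aln the [HptAlignment-class] on which `anchor` was computed.
#' @param anchor an [AnchorResult-class].
#' @param k offset (default 4, the "H+4" position).
#' @return a [PositionCount-class].
#' @export
countOffsetResidues <- function(aln, anchor, k = 4) {
  stopifnot(is(aln, "HptAlignment"), is(anchor, "AnchorResult"))
  keep <- !(aln@ids %in% anchor@removedIds)
  letters <- vapply(aln@rows[keep], residueAtOffset, "",
                    anchorCol = anchor@anchorCol, k = k, USE.NAMES = FALSE)
  counts <- stats::setNames(integer(length(AA_ALPHABET_HPT)),
                            AA_ALPHABET_HPT)
  tab <- table(letters[!is.na(letters)])
  counts[names(tab)] <- as.integer(tab)
  new("PositionCount", offsetK = as.integer(k), counts = counts,
      nShort = sum(is.na(letters)), total = sum(counts))
}

.roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percent-of-total table for a residue census
#'
#' Formats a census as (residue, count, percent of total) rows sorted by
#' count descending (ties keep input order). Percents use half-up rounding to
#' `digits` decimals, matching how such census tables are conventionally
#' printed.
#'
#' @param counts a [PositionCount-class], or a named numeric vector of
#'   residue counts.
#' @param excludeX drop the `X` (non-standard residue) tally from both the
#'   rows and the denominator. Default keeps it in the total.
#' @param digits decimal places for the percent column.
#' @return `data.frame` with columns `residue`, `count`, `percent`; the
#'   denominator is attached as attribute `"total"`.
#' @examples
#' percentTable(c(G = 87, S = 10, A = 3))
#' @export
percentTable <- function(counts, excludeX = FALSE, digits = 2L) {
  if (is(counts, "PositionCount")) counts <- counts@counts
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of residue counts")
  if (excludeX) counts <- counts[names(counts) != "X"]
  total <- sum(counts)
  if (total <= 0) stop("census total is zero; nothing to tabulate")
  ord <- order(-counts)                        # stable for ties
  out <- data.frame(residue = names(counts)[ord],
                    count = as.integer(counts[ord]),
                    percent = .roundHalfUp(100 * counts[ord] / total, digits),
                    row.names = NULL)
  attr(out, "total") <- as.integer(total)
  out
}

#' Sequence-logo matrix: per-column frequencies and information content
#'
#' For each column, gap- and `X`-excluded residue frequencies `p_a`, Shannon
#' entropy `H = -sum p_a log2 p_a`, information content
#' `info_bits = log2(20) - H - e_n` (clamped at 0), and letter heights
#' `p_a * info_bits` — the numbers behind a WebLogo-style sequence logo. The
#' small-sample correction `e_n = (20 - 1) / (2 n ln 2)` is applied when
#' `smallSampleCorrection = TRUE`, else `e_n = 0`.
#'
#' @param aln an [HptAlignment-class].
#' @param smallSampleCorrection logical, default off.
#' @return long `data.frame` with columns `col`, `residue`, `freq`, `n_obs`,
#'   `info_bits`, `height`; one row per observed residue per column. Columns
#'   with no residue observations yield one row with `NA` residue and
#'   missing statistics.
#' @export
logoMatrix <- function(aln, smallSampleCorrection = FALSE) {
  stopifnot(is(aln, "HptAlignment"))
  mat <- .alnMatrix(aln)
  maxInfo <- log2(20)
  res <- lapply(seq_len(ncol(mat)), function(j) {
    obs <- mat[, j]
    obs <- obs[obs %in% AA_STANDARD]
    n <- length(obs)
    if (n == 0L)
      return(data.frame(col = j, residue = NA_character_, freq = NA_real_,
                        n_obs = 0L, info_bits = NA_real_, height = NA_real_))
    p <- as.vector(table(obs)) / n
    resid <- names(table(obs))
    H <- -sum(p * log2(p))
    en <- if (smallSampleCorrection) (20 - 1) / (2 * n * log(2)) else 0
    info <- max(0, maxInfo - H - en)
    data.frame(col = j, residue = resid, freq = p, n_obs = n,
               info_bits = info, height = p * info)
  })
  do.call(rbind, res)
}
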