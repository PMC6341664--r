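#' Accessors for hptkit classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x an hptkit object.
#' @name accessors
NULL

#' @rdname accessors
#' @return `sequenceIds()`: character vector of sequence ids.
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))

#' @rdname accessors
#' @return `alignedRows()`: named character vector of aligned rows.
#' @export
setGeneric("alignedRows", function(x) standardGeneric("alignedRows"))

#' @rdname accessors
#' @return `nSequences()`: number of rows in the alignment.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname accessors
#' @return `nColumns()`: number of alignment columns.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname accessors
#' @return `atomTable()`: the atom `data.frame` of a [StructureModel-class].
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setMethod("sequenceIds", "HptAlignment", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("alignedRows", "HptAlignment",
          function(x) stats::setNames(x@rows, x@ids))

#' @rdname accessors
#' @export
setMethod("nSequences", "HptAlignment", function(x) length(x@ids))

#' @rdname accessors
#' @export
setMethod("nColumns", "HptAlignment",
          function(x) nchar(x@rows[1L]))

#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' Subset an alignment by sequence
#'
#' `x[i]` keeps the selected sequences (by index, id or logical mask) and all
#' columns.
#'
#' @param x an [HptAlignment-class].
#' @param i numeric, character or logical index over sequences.
#' @param j,drop,... ignored (alignments are subset by sequence only).
#' @return an [HptAlignment-class] with the selected rows.
#' @export
setMethod("[", "HptAlignment", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  if (anyNA(i)) stop("unknown sequence id in subset")
  new("HptAlignment", ids = x@ids[i], rows = x@rows[i],
      descriptions = x@descriptions[i])
})

setMethod("show", "HptAlignment", function(object) {
  cat(sprintf("HptAlignment: %d sequences x %d columns\n",
              nSequences(object), nColumns(object)))
  n <- min(3L, nSequences(object))
  w <- min(60L, nColumns(object))
  for (k in seq_len(n))
    cat(sprintf("  %-20s %s%s\n", object@ids[k],
                substr(object@rows[k], 1L, w),
                if (nColumns(object) > w) "..." else ""))
  if (nSequences(object) > n)
    cat(sprintf("  ... and %d more\n", nSequences(object) - n))
})

setMethod("show", "RedundancyResult", function(object) {
  sizes <- lengths(object@clusters)
  cat(sprintf(
    "RedundancyResult: %d representatives from %d sequences (threshold %.2f)\n",
    length(object@keptIds), sum(sizes), object@threshold))
  cat(sprintf("  cluster sizes: min %d / median %g / max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
})

setMethod("show", "AnchorResult", function(object) {
  cat(sprintf(
    "AnchorResult: '%s' anchor at column %d (%.1f%% of rows); %d rows lack it\n",
    object@anchorResidue, object@anchorCol, 100 * object@anchorFreq,
    length(object@removedIds)))
})

setMethod("show", "PositionCount", function(object) {
  cat(sprintf("PositionCount at anchor+%d: %d sequences (%d too short)\n",
              object@offsetK, object@total, object@nShort))
  top <- sort(object@counts[object@counts > 0L], decreasing = TRUE)
  top <- utils::head(top, 5L)
  if (length(top))
    cat("  top:", paste(sprintf("%s=%d", names(top), top), collapse = ", "),
        "\n")
})

setMethod("show", "Titration", function(object) {
  cat(sprintf(
    "Titration: %d points, L_T %.3g-%.3g M, R_T %.3g M, F0 %.4g\n",
    length(object@ltotal), min(object@ltotal), max(object@ltotal),
    object@receptorTotal, object@f0))
})

setMethod("show", "NormalizedTitration", function(object) {
  cat(sprintf(
    "NormalizedTitration: %d points, L_T %.3g-%.3g M, R_T %.3g M\n",
    length(object@ltotal), min(object@ltotal), max(object@ltotal),
    object@receptorTotal))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit (%s): Kd = %.4g M (SE %.2g), A = %.4g (SE %.2g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@kd, object@se[["kd"]], object@amplitude,
              object@se[["amplitude"]]))
  cat(sprintf("  rss = %.4g over %d points\n", object@rss, object@nPoints))
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms (%d hetero), chains: %s\n",
              nrow(a), sum(a$hetero),
              paste(sort(unique(a$chain)), collapse = ", ")))
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition over %d atoms: rmsd = %.4f A\n",
              object@nAtoms, object@rmsd))
})

setMethod("show", "RegionSpec", function(object) {
  cat(sprintf("RegionSpec: chain %s, residues %s, atoms = %s\n",
              object@chain,
              paste(apply(object@ranges, 1L, function(r)
                sprintf("%d-%d", r[1L], r[2L])), collapse = ","),
              object@selection))
})
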