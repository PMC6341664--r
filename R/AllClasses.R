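#' @import methods
NULL

## Residue alphabet used throughout: the 20 standard amino acids, 'X' for
## anything non-standard, '-' for gaps.
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
AA_ALPHABET_HPT <- c(AA_STANDARD, "X")
GAP_CHAR <- "-"

#' HptAlignment: a gapped multiple sequence alignment
#'
#' Holds an in-memory multiple sequence alignment with one row per sequence.
#' Rows are uppercase strings over the 20 standard amino-acid letters, `X`
#' (any non-standard residue) and `-` (gap); all rows have equal length and
#' ids are unique. Columns and residue positions are 1-based.
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot rows character vector of aligned rows, same length as `ids`.
#' @slot descriptions optional per-sequence description strings (may be `NA`).
#'
#' @seealso [readAlignment()], [hptAlignment()], [generateAlignment()]
#' @export
setClass("HptAlignment",
  representation(ids = "character", rows = "character",
                 descriptions = "character"))

setValidity("HptAlignment", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (n < 1L) msg <- c(msg, "alignment must contain at least one sequence")
  if (length(object@rows) != n)
    msg <- c(msg, "ids and rows differ in length")
  if (length(object@descriptions) != n)
    msg <- c(msg, "descriptions must have one entry per sequence")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate sequence id: %s",
                          object@ids[duplicated(object@ids)][1L]))
  if (any(!nzchar(object@ids)) || anyNA(object@ids))
    msg <- c(msg, "empty or missing sequence id")
  if (n >= 1L) {
    w <- unique(nchar(object@rows))
    if (length(w) != 1L)
      msg <- c(msg, "rows have unequal lengths (ragged alignment)")
    bad <- grepl(sprintf("[^%s-]", paste(AA_ALPHABET_HPT, collapse = "")),
                 object@rows)
    if (any(bad))
      msg <- c(msg, sprintf("illegal character in row '%s'",
                            object@ids[bad][1L]))
  }
  if (length(msg)) msg else TRUE
})

#' RedundancyResult: greedy identity clustering of alignment rows
#'
#' @slot keptIds representatives, in the order they were founded.
#' @slot clusters named list: representative id -> character vector of member
#'   ids (the representative included, first).
#' @slot threshold identity threshold in (0, 1] used for clustering.
#' @seealso [removeRedundancy()]
#' @export
setClass("RedundancyResult",
  representation(keptIds = "character", clusters = "list",
                 threshold = "numeric"))

setValidity("RedundancyResult", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    msg <- c(msg, "threshold must be a single value in (0, 1]")
  if (!identical(object@keptIds, names(object@clusters)))
    msg <- c(msg, "keptIds must equal the cluster representative names")
  members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(members))
    msg <- c(msg, "a sequence id appears in more than one cluster")
  if (length(msg)) msg else TRUE
})

#' AnchorResult: location of the conserved phospho-accepting histidine column
#'
#' @slot anchorCol 1-based alignment column of the anchor.
#' @slot anchorFreq fraction of rows carrying the anchor residue there.
#' @slot anchorResidue the anchor residue letter (default `"H"`).
#' @slot removedIds ids of rows lacking the anchor residue at `anchorCol`.
#' @seealso [findAnchorColumn()]
#' @export
setClass("AnchorResult",
  representation(anchorCol = "integer", anchorFreq = "numeric",
                 anchorResidue = "character", removedIds = "character"))

setValidity("AnchorResult", function(object) {
  msg <- character()
  if (object@anchorCol < 1L) msg <- c(msg, "anchorCol must be >= 1")
  if (object@anchorFreq <= 0 || object@anchorFreq > 1)
    msg <- c(msg, "anchorFreq must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' PositionCount: residue census at an anchor-relative offset
#'
#' Counts of the residue found `offsetK` positions downstream (in ungapped
#' sequence coordinates) of the anchor, over the retained rows of an
#' alignment. Rows whose sequence ends before the offset are tallied in
#' `nShort` and excluded from `total`.
#'
#' @slot offsetK the offset k in "H+k".
#' @slot counts named integer vector, residue letter -> count (letters from
#'   the 20 standard amino acids plus `X`).
#' @slot nShort number of retained rows too short to reach the offset.
#' @slot total sum of `counts`.
#' @seealso [countOffsetResidues()], [percentTable()]
#' @export
setClass("PositionCount",
  representation(offsetK = "integer", counts = "integer",
                 nShort = "integer", total = "integer"))

setValidity("PositionCount", function(object) {
  msg <- character()
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (!all(names(object@counts) %in% AA_ALPHABET_HPT))
    msg <- c(msg, "count keys must be standard residues or 'X'")
  if (object@total != sum(object@counts))
    msg <- c(msg, "total must equal the sum of counts")
  if (object@nShort < 0L) msg <- c(msg, "nShort must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Titration: a raw fluorescence titration series
#'
#' One series of total-titrant concentrations and raw fluorescence
#' intensities, plus the pre-titration baseline intensity F0 (read at zero
#' added titrant) and the total receptor (labelled species) concentration.
#'
#' @slot receptorTotal total receptor concentration R_T, molar.
#' @slot ltotal total titrant concentrations L_T, molar, strictly increasing.
#' @slot intensity raw fluorescence intensities, same length as `ltotal`.
#' @slot f0 baseline intensity at L_T = 0 (must be > 0).
#' @seealso [titration()], [normalizeTitration()], [generateTitration()]
#' @export
setClass("Titration",
  representation(receptorTotal = "numeric", ltotal = "numeric",
                 intensity = "numeric", f0 = "numeric"))

setValidity("Titration", function(object) {
  msg <- character()
  if (length(object@receptorTotal) != 1L || object@receptorTotal < 0)
    msg <- c(msg, "receptorTotal must be a single non-negative concentration")
  if (length(object@f0) != 1L || !is.finite(object@f0) || object@f0 <= 0)
    msg <- c(msg, "baseline intensity f0 must be a single positive value")
  if (length(object@ltotal) != length(object@intensity))
    msg <- c(msg, "ltotal and intensity differ in length")
  if (length(object@ltotal) < 1L)
    msg <- c(msg, "at least one titration point is required")
  if (any(object@ltotal < 0)) msg <- c(msg, "ltotal must be non-negative")
  if (any(diff(object@ltotal) <= 0))
    msg <- c(msg, "ltotal must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' NormalizedTitration: buffer-subtracted binding signal
#'
#' The dimensionless binding signal delta_i = (F/F0)_titrant − (F/F0)_buffer
#' at each shared addition index, against total titrant concentration.
#'
#' @slot receptorTotal total receptor concentration R_T, molar.
#' @slot ltotal total titrant concentrations, molar.
#' @slot delta normalized, buffer-subtracted response.
#' @seealso [normalizeTitration()], [fitBinding()]
#' @export
setClass("NormalizedTitration",
  representation(receptorTotal = "numeric", ltotal = "numeric",
                 delta = "numeric"))

setValidity("NormalizedTitration", function(object) {
  msg <- character()
  if (length(object@ltotal) != length(object@delta))
    msg <- c(msg, "ltotal and delta differ in length")
  if (length(object@receptorTotal) != 1L || object@receptorTotal <= 0)
    msg <- c(msg, "receptorTotal must be a single positive concentration")
  if (length(msg)) msg else TRUE
})

#' BindingFit: fitted ligand-depletion binding model
#'
#' @slot kd dissociation constant, molar.
#' @slot amplitude signed saturating amplitude of the normalized response.
#' @slot se named numeric: standard errors for `kd` and `amplitude` from the
#'   local curvature at the optimum (delta method for `kd`, which is fitted
#'   on the log scale).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot nPoints number of points fitted.
#' @slot message optimizer diagnostic message.
#' @seealso [fitBinding()]
#' @export
setClass("BindingFit",
  representation(kd = "numeric", amplitude = "numeric", se = "numeric",
                 rss = "numeric", converged = "logical",
                 nPoints = "integer", message = "character"))

setValidity("BindingFit", function(object) {
  if (object@converged &&
      !(is.finite(object@kd) && object@kd > 0 && is.finite(object@amplitude)))
    return("a converged fit must carry finite kd > 0 and amplitude")
  TRUE
})

#' StructureModel: atoms of a macromolecular structure
#'
#' A flat atom table (one row per atom after alternate-location resolution,
#' first MODEL only). Waters and other hetero records are retained but
#' flagged so that analyses can exclude them.
#'
#' @slot atoms `data.frame` with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `element`, `hetero` (logical).
#' @seealso [readPDB()], [structureModel()], [generateStructurePair()]
#' @export
setClass("StructureModel", representation(atoms = "data.frame"))

.ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resseq",
                "icode", "x", "y", "z", "occupancy", "element", "hetero")

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(.ATOM_COLS %in% names(a)))
    msg <- c(msg, sprintf("atom table must contain columns: %s",
                          paste(.ATOM_COLS, collapse = ", ")))
  else {
    if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
      msg <- c(msg, "atom coordinates must be finite")
    key <- paste(a$chain, a$resseq, a$icode, a$name, a$hetero)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chain, resseq, icode, name) atom key")
  }
  if (length(msg)) msg else TRUE
})

#' Superposition: an optimal rigid-body superposition
#'
#' Result of least-squares (Kabsch) superposition of a mobile coordinate set
#' onto a reference: a proper rotation, a translation, and the residual RMSD.
#' Mobile points (rows) are transformed as `x %*% t(rotation) + translation`.
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation length-3 translation, Angstrom.
#' @slot rmsd root-mean-square residual after superposition, Angstrom.
#' @slot nAtoms number of paired atoms used.
#' @seealso [kabschSuperpose()], [applySuperposition()]
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"))

setValidity("Superposition", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det = +1)")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthogonal")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RegionSpec: a residue-range selection within one chain
#'
#' @slot chain one-character chain identifier.
#' @slot ranges integer matrix with columns `start`, `end` (inclusive,
#'   residue numbers).
#' @slot selection atom subset: `"CA"`, `"backbone"`, `"heavy"` or `"all"`.
#' @seealso [regionSpec()], [regionRmsd()], [clashScan()]
#' @export
setClass("RegionSpec",
  representation(chain = "character", ranges = "matrix",
                 selection = "character"))

setValidity("RegionSpec", function(object) {
  msg <- character()
  if (length(object@chain) != 1L)
    msg <- c(msg, "chain must be a single identifier")
  r <- object@ranges
  if (ncol(r) != 2L) msg <- c(msg, "ranges must have two columns (start, end)")
  else if (nrow(r) && any(r[, 1L] > r[, 2L]))
    msg <- c(msg, "each range must satisfy start <= end")
  if (!object@selection %in% c("CA", "backbone", "heavy", "all"))
    msg <- c(msg, "selection must be one of CA, backbone, heavy, all")
  if (length(msg)) msg else TRUE
})
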