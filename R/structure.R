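## Structural comparison: superposition, regional RMSD, clash scanning.
##
## PDB files are parsed with bio3d; the analysis itself (Kabsch
## superposition, global-frame vs local-fit regional RMSD, van der Waals
## overlap scanning) is implemented here.

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# carbon.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
                MG = 1.73, ZN = 1.39, FE = 1.40, BE = 1.53)

.vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_RADII[["C"]]
  unname(r)
}

.elementFromName <- function(name) {
  # PDB convention: strip digits and primes; hydrogens may start with a digit
  core <- gsub("[0-9']", "", name)
  el <- substr(core, 1L, 1L)
  el[el == ""] <- "C"
  el
}

#' Construct a StructureModel from an atom table
#'
#' Missing optional columns (`serial`, `altloc`, `icode`, `occupancy`,
#' `element`, `hetero`) are filled with defaults; `element` is inferred from
#' the atom name when absent.
#'
#' @param atoms `data.frame` with at least `name`, `resname`, `chain`,
#'   `resseq`, `x`, `y`, `z`.
#' @return a [StructureModel-class].
#' @export
structureModel <- function(atoms) {
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$element) || all(is.na(atoms$element)))
    atoms$element <- .elementFromName(atoms$name)
  else {
    miss <- is.na(atoms$element) | !nzchar(atoms$element)
    atoms$element[miss] <- .elementFromName(atoms$name[miss])
  }
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  new("StructureModel", atoms = atoms[, .ATOM_COLS])
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()]: first MODEL only;
#' alternate locations resolved to the highest occupancy (ties prefer blank
#' or `'A'`); waters and hetero ligands retained but flagged `hetero`.
#'
#' @param path PDB file path.
#' @return a [StructureModel-class].
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  df <- data.frame(
    serial = a$eleno,
    name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resseq = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                     .elementFromName(a$elety), a$elesy),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  # altloc resolution: per atom identity keep highest occupancy; on ties the
  # lexicographically first altloc ('' before 'A' before 'B') wins
  key <- paste(df$chain, df$resseq, df$icode, df$name, df$hetero, df$resname)
  df <- df[order(key, -df$occupancy, df$altloc), ]
  df <- df[!duplicated(paste(df$chain, df$resseq, df$icode, df$name,
                             df$hetero, df$resname)), ]
  df <- df[order(df$serial), ]
  rownames(df) <- NULL
  structureModel(df)
}

#' Write a StructureModel as a PDB file
#'
#' Fixed-column ATOM/HETATM records; round-trips through [readPDB()].
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  nm <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
               substr(a$name, 1L, 4L))
  rec <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(a$hetero, "HETATM", "ATOM"),
                 a$serial %% 100000L, nm,
                 ifelse(nzchar(a$altloc), a$altloc, " "),
                 a$resname, a$chain, a$resseq,
                 ifelse(nzchar(a$icode), a$icode, " "),
                 a$x, a$y, a$z, a$occupancy, 0,
                 toupper(a$element))
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Define a chain/residue-range selection
#'
#' @param chain chain identifier (single character).
#' @param start,end inclusive residue-number bounds; vectors give multiple
#'   ranges.
#' @param selection atom subset: `"CA"` (alpha carbons), `"backbone"`
#'   (N, CA, C, O), `"heavy"` (non-hydrogen) or `"all"`.
#' @return a [RegionSpec-class].
#' @examples
#' regionSpec("A", 11, 21)                 # the alpha-A helix of Ypd1
#' @export
regionSpec <- function(chain, start, end, selection = c("CA", "backbone",
                                                        "heavy", "all")) {
  selection <- match.arg(selection)
  new("RegionSpec", chain = as.character(chain),
      ranges = cbind(start = as.integer(start), end = as.integer(end)),
      selection = selection)
}

.selectionMask <- function(atoms, selection) {
  switch(selection,
    CA = atoms$name == "CA" & !atoms$hetero,
    backbone = atoms$name %in% c("N", "CA", "C", "O") & !atoms$hetero,
    heavy = toupper(atoms$element) != "H" & !atoms$hetero,
    all = !atoms$hetero,
    stop("unknown selection"))
}

.regionMask <- function(atoms, region) {
  m <- atoms$chain == region@chain & .selectionMask(atoms, region@selection)
  inR <- rep(FALSE, nrow(atoms))
  for (k in seq_len(nrow(region@ranges)))
    inR <- inR | (atoms$resseq >= region@ranges[k, 1L] &
                  atoms$resseq <= region@ranges[k, 2L])
  m & inR
}

#' Pair equivalent atoms of two structures
#'
#' Pairs atoms by (mapped chain, residue number, insertion code, atom name)
#' over the intersection of the two structures, in deterministic order
#' (chain, residue, insertion code, name). Hetero atoms are excluded.
#'
#' @param a,b [StructureModel-class] objects.
#' @param selection atom subset (see [regionSpec()]), default `"CA"`.
#' @param chainMap optional named character vector mapping chains of `a` to
#'   chains of `b`, e.g. `c(A = "B")`.
#' @return list with `P`, `Q` (n x 3 coordinate matrices of `a` and `b`) and
#'   `keys` (`data.frame` of chain — in `b` naming — `resseq`, `icode`,
#'   `name`).
#' @export
matchAtoms <- function(a, b, selection = c("CA", "backbone", "heavy", "all"),
                       chainMap = NULL) {
  stopifnot(is(a, "StructureModel"), is(b, "StructureModel"))
  selection <- match.arg(selection)
  aa <- a@atoms[.selectionMask(a@atoms, selection), ]
  bb <- b@atoms[.selectionMask(b@atoms, selection), ]
  chainA <- aa$chain
  if (!is.null(chainMap)) {
    mapped <- chainMap[chainA]
    chainA <- ifelse(is.na(mapped), chainA, mapped)
  }
  keyA <- paste(chainA, aa$resseq, aa$icode, aa$name, sep = "\r")
  keyB <- paste(bb$chain, bb$resseq, bb$icode, bb$name, sep = "\r")
  common <- intersect(keyA, keyB)
  if (!length(common))
    stop("no atoms in common between the two structures under this selection")
  ia <- match(common, keyA); ib <- match(common, keyB)
  ord <- order(bb$chain[ib], bb$resseq[ib], bb$icode[ib], bb$name[ib])
  ia <- ia[ord]; ib <- ib[ord]
  list(P = as.matrix(aa[ia, c("x", "y", "z")]),
       Q = as.matrix(bb[ib, c("x", "y", "z")]),
       keys = data.frame(chain = bb$chain[ib], resseq = bb$resseq[ib],
                         icode = bb$icode[ib], name = bb$name[ib]))
}

.rmsd <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation of `P` onto `Q` minimizing the
#' RMSD; reflections are excluded by the usual sign correction on the
#' smallest singular value.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3, non-collinear), rows paired.
#' @return a [Superposition-class]; apply it with [applySuperposition()].
#' @export
kabschSuperpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size")
  if (nrow(P) < 3L) stop("at least 3 paired atoms are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))                 # H = P0' Q0 = U D V'
  if (s$d[2L] < 1e-9 * max(s$d[1L], 1))
    stop("degenerate (collinear) configuration; superposition is not unique")
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)    # maps P-frame onto Q-frame
  Pfit <- P0 %*% t(R)
  new("Superposition", rotation = R,
      translation = as.numeric(cq - R %*% cp),
      rmsd = .rmsd(Pfit, Q0), nAtoms = nrow(P))
}

#' Apply a superposition to coordinates or a structure
#'
#' @param sp a [Superposition-class].
#' @param x an n x 3 coordinate matrix or a [StructureModel-class].
#' @return object of the same kind with transformed coordinates.
#' @export
applySuperposition <- function(sp, x) {
  stopifnot(is(sp, "Superposition"))
  if (is(x, "StructureModel")) {
    xyz <- as.matrix(x@atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(sp@rotation), 2L, sp@translation, `+`)
    at <- x@atoms
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
    return(new("StructureModel", atoms = at))
  }
  sweep(as.matrix(x) %*% t(sp@rotation), 2L, sp@translation, `+`)
}

#' Regional RMSD between two structures
#'
#' `mode = "global_frame"`: superpose `a` onto `b` using all matched atoms of
#' the region's selection type (or of `fitRegion`, when a reference frame
#' excluding the moving part is wanted), then report the RMSD over the region
#' atoms without refitting — deviations are measured relative to the rest of
#' the structure. `mode = "local_fit"`: superpose on the region atoms
#' themselves, reporting only internal deformation. `local_fit` never exceeds
#' `global_frame`.
#'
#' @param a,b [StructureModel-class] objects (`a` is mobile).
#' @param region a [RegionSpec-class] (applied in `b` chain naming).
#' @param mode `"global_frame"` (default) or `"local_fit"`.
#' @param chainMap optional chain mapping for [matchAtoms()].
#' @param fitRegion optional [RegionSpec-class] defining the atoms used to
#'   establish the global frame (default: all matched atoms).
#' @return RMSD in Angstrom.
#' @export
regionRmsd <- function(a, b, region, mode = c("global_frame", "local_fit"),
                       chainMap = NULL, fitRegion = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(region, "RegionSpec"))
  m <- matchAtoms(a, b, selection = region@selection, chainMap = chainMap)
  inRegion <- .regionMask(
    data.frame(chain = m$keys$chain, resseq = m$keys$resseq,
               name = m$keys$name, element = "C", hetero = FALSE),
    region)
  if (!any(inRegion)) stop("region selects no matched atoms")
  fitMask <- if (mode == "local_fit") inRegion
  else if (is.null(fitRegion)) rep(TRUE, nrow(m$P))
  else .regionMask(
    data.frame(chain = m$keys$chain, resseq = m$keys$resseq,
               name = m$keys$name, element = "C", hetero = FALSE),
    fitRegion)
  if (sum(fitMask) < 3L) stop("fewer than 3 atoms available to fit the frame")
  sp <- kabschSuperpose(m$P[fitMask, , drop = FALSE],
                        m$Q[fitMask, , drop = FALSE])
  Pt <- applySuperposition(sp, m$P)
  .rmsd(Pt[inRegion, , drop = FALSE], m$Q[inRegion, , drop = FALSE])
}

#' Van der Waals clash scan between two selections
#'
#' Reports every atom pair (one from each selection) whose van der Waals
#' overlap `r_a + r_b - d` exceeds `overlapThreshold` (0.4 Angstrom, the
#' common severe-clash convention), sorted by overlap descending. The two
#' structures must already share a frame (superpose first). Hydrogens are
#' excluded unless `includeHydrogens = TRUE`; radii come from a built-in
#' Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom, ...).
#'
#' @param mobile,target [StructureModel-class] objects in a common frame.
#' @param mobileSel,targetSel [RegionSpec-class] selections.
#' @param overlapThreshold minimum overlap, Angstrom.
#' @param includeHydrogens include H atoms in the scan.
#' @return `data.frame` with one row per clashing pair: `chain_a`,
#'   `resseq_a`, `name_a`, `chain_b`, `resseq_b`, `name_b`, `distance`,
#'   `overlap`.
#' @export
clashScan <- function(mobile, mobileSel, target, targetSel,
                      overlapThreshold = 0.4, includeHydrogens = FALSE) {
  stopifnot(is(mobile, "StructureModel"), is(target, "StructureModel"),
            is(mobileSel, "RegionSpec"), is(targetSel, "RegionSpec"))
  pick <- function(model, region) {
    at <- model@atoms[.regionMask(model@atoms, region), ]
    if (!includeHydrogens) at <- at[toupper(at$element) != "H", ]
    at
  }
  A <- pick(mobile, mobileSel); B <- pick(target, targetSel)
  if (!nrow(A) || !nrow(B)) stop("empty clash-scan selection")
  dx <- outer(A$x, B$x, `-`); dy <- outer(A$y, B$y, `-`)
  dz <- outer(A$z, B$z, `-`)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  lim <- outer(.vdwRadius(A$element), .vdwRadius(B$element), `+`)
  hit <- which(lim - d > overlapThreshold, arr.ind = TRUE)
  out <- data.frame(
    chain_a = A$chain[hit[, 1L]], resseq_a = A$resseq[hit[, 1L]],
    name_a = A$name[hit[, 1L]],
    chain_b = B$chain[hit[, 2L]], resseq_b = B$resseq[hit[, 2L]],
    name_b = B$name[hit[, 2L]],
    distance = d[hit], overlap = (lim - d)[hit])
  out <- out[order(-out$overlap), , drop = FALSE]
  rownames(out) <- NULL
  out
}
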