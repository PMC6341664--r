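## Seeded generators emulating each analysis input: a gapped family alignment
## with a dominant histidine anchor column and a designed H+k composition, a
## ligand-depletion titration with multiplicative instrument noise and a
## buffer drift series, replicate gel-lane intensities around target
## percent-of-wild-type values, and coordinate pairs with known rigid
## per-region offsets. All are pure functions of their arguments and `seed`.

#' Generate a synthetic family alignment with a planted H+k census
#'
#' Builds `sum(composition)` template rows of uniform random background
#' residues with the anchor residue `"H"` at `anchorCol` and the designed
#' residue at the H+k position (the window `anchorCol .. anchorCol+offsetK`
#' is kept gap-free so the offset is reached in sequence coordinates; other
#' columns gap independently at `gapRate`). Optionally adds: rows lacking the
#' anchor (fraction `anchorDropout`, removed by [findAnchorColumn()]), rows
#' whose sequence ends right after the anchor (`nShortRows`, tallied as "too
#' short" by [countOffsetResidues()]), and near-identical duplicate rows
#' (identity to their template >= 0.98 by construction, collapsed by
#' [removeRedundancy()]).
#'
#' @param composition named integer vector: residue letter at H+k -> number
#'   of template rows carrying it.
#' @param nCols alignment width.
#' @param anchorCol 1-based anchor column; needs `anchorCol + offsetK <=
#'   nCols`.
#' @param offsetK the census offset k (default 4).
#' @param gapRate per-column gap probability outside the protected window,
#'   in `[0, 0.3]`.
#' @param nDuplicates near-identical copies added per duplicated template.
#' @param nDuplicatedTemplates number of templates receiving duplicates.
#' @param mutationRate fraction of residue positions mutated in each
#'   duplicate, at most 0.02 so duplicates stay within the 98% identity
#'   envelope of their template.
#' @param anchorDropout fraction (of templates) of extra rows carrying `"Q"`
#'   instead of the anchor histidine.
#' @param nShortRows extra rows whose chain ends at the anchor.
#' @param seed integer seed.
#' @return list with `alignment` ([HptAlignment-class]) and `truth` (list:
#'   `anchorCol`, `composition`, `residueByRow`, `duplicateGroups`,
#'   `droppedIds`, `shortIds`).
#' @export
generateAlignment <- function(composition, nCols = 60, anchorCol = 20,
                              offsetK = 4, gapRate = 0.1, nDuplicates = 0,
                              nDuplicatedTemplates = 5, mutationRate = 0.01,
                              anchorDropout = 0, nShortRows = 0, seed = 1) {
  stopifnot(length(composition) >= 1L, !is.null(names(composition)),
            all(names(composition) %in% AA_ALPHABET_HPT),
            all(composition >= 0), sum(composition) >= 1,
            anchorCol + offsetK <= nCols, anchorCol >= 1,
            gapRate >= 0, gapRate <= 0.3,
            mutationRate >= 0, mutationRate <= 0.02)
  nSeqs <- sum(composition)
  withr::with_seed(seed, {
    protected <- anchorCol:(anchorCol + offsetK)
    makeRow <- function(h4, anchorResidue = "H", short = FALSE) {
      ch <- sample(AA_STANDARD, nCols, replace = TRUE)
      gap <- runif(nCols) < gapRate
      gap[protected] <- FALSE
      ch[gap] <- GAP_CHAR
      ch[anchorCol] <- anchorResidue
      ch[anchorCol + offsetK] <- h4
      if (short) ch[(anchorCol + 1L):nCols] <- GAP_CHAR
      paste(ch, collapse = "")
    }
    h4ByRow <- sample(rep(names(composition), composition))
    rows <- vapply(h4ByRow, makeRow, "", USE.NAMES = FALSE)
    ids <- sprintf("seq%04d", seq_len(nSeqs))
    nDrop <- round(anchorDropout * nSeqs)
    dropIds <- character(0)
    if (nDrop > 0L) {
      dropIds <- sprintf("nohis%03d", seq_len(nDrop))
      rows <- c(rows, vapply(sample(names(composition), nDrop, TRUE),
                             makeRow, "", anchorResidue = "Q",
                             USE.NAMES = FALSE))
      ids <- c(ids, dropIds)
    }
    shortIds <- character(0)
    if (nShortRows > 0L) {
      shortIds <- sprintf("short%03d", seq_len(nShortRows))
      rows <- c(rows, vapply(seq_len(nShortRows), function(i)
        makeRow(names(composition)[1L], short = TRUE), ""))
      ids <- c(ids, shortIds)
    }
    dupGroups <- list()
    if (nDuplicates > 0L && nDuplicatedTemplates > 0L) {
      tpl <- seq_len(min(nDuplicatedTemplates, nSeqs))
      for (t in tpl) {
        grp <- character(0)
        for (j in seq_len(nDuplicates)) {
          ch <- strsplit(rows[t], "", fixed = TRUE)[[1L]]
          resPos <- setdiff(which(ch != GAP_CHAR), protected)
          nMut <- floor(mutationRate * length(which(ch != GAP_CHAR)))
          if (nMut > 0L) {
            at <- sample(resPos, nMut)
            ch[at] <- vapply(ch[at], function(old)
              sample(setdiff(AA_STANDARD, old), 1L), "")
          }
          id <- sprintf("%s_dup%d", ids[t], j)
          rows <- c(rows, paste(ch, collapse = ""))
          ids <- c(ids, id)
          grp <- c(grp, id)
        }
        dupGroups[[ids[t]]] <- grp
      }
    }
    list(alignment = hptAlignment(ids, rows),
         truth = list(anchorCol = anchorCol, offsetK = offsetK,
                      composition = composition,
                      residueByRow = stats::setNames(h4ByRow,
                                                     sprintf("seq%04d",
                                                             seq_len(nSeqs))),
                      duplicateGroups = dupGroups, droppedIds = dropIds,
                      shortIds = shortIds))
  })
}

#' Generate a synthetic fluorescence titration with buffer series
#'
#' Intensities follow the two-state model used by [fitBinding()]:
#' `F_i = F0 (1 + delta_model_i + drift_i)(1 + e_i)` for the binding series
#' and `F_i = F0 (1 + drift_i)(1 + e_i)` for the matched buffer series, with
#' multiplicative Gaussian noise `e_i ~ N(0, noiseSd)` and a linear drift
#' `drift_i = bufferDriftSlope * L_T_i / max(L_T)` common to both series.
#'
#' @param kd true dissociation constant, molar.
#' @param amplitude true saturating amplitude.
#' @param receptorTotal total receptor, molar (default 15.8 nM: 30 pmol in
#'   1.9 mL).
#' @param lTotal titrant grid, molar; default 20 log-spaced points over
#'   10 nM - 6 uM.
#' @param noiseSd multiplicative noise SD (fraction).
#' @param bufferDriftSlope fractional drift reached at the final addition.
#' @param f0 baseline intensity (arbitrary units).
#' @param seed integer seed.
#' @return list with `ligand` and `buffer` ([Titration-class]) and `truth`.
#' @export
generateTitration <- function(kd = 0.94e-6, amplitude = 0.4,
                              receptorTotal = 15.8e-9,
                              lTotal = 10^seq(log10(1e-8), log10(6e-6),
                                              length.out = 20),
                              noiseSd = 0.01, bufferDriftSlope = 0,
                              f0 = 100, seed = 1) {
  stopifnot(noiseSd >= 0, all(diff(lTotal) > 0))
  withr::with_seed(seed, {
    deltaModel <- predictResponse(kd, amplitude, receptorTotal, lTotal)
    drift <- bufferDriftSlope * lTotal / max(lTotal)
    n <- length(lTotal)
    fLig <- f0 * (1 + deltaModel + drift) * (1 + stats::rnorm(n, 0, noiseSd))
    fBuf <- f0 * (1 + drift) * (1 + stats::rnorm(n, 0, noiseSd))
    list(ligand = titration(receptorTotal, lTotal, fLig, f0),
         buffer = titration(receptorTotal, lTotal, fBuf, f0),
         truth = list(kd = kd, amplitude = amplitude,
                      receptorTotal = receptorTotal, deltaModel = deltaModel,
                      noiseSd = noiseSd, bufferDriftSlope = bufferDriftSlope))
  })
}

#' Generate replicate gel-lane intensities around target activities
#'
#' Each replicate gets its own reference-lane intensity (log-normal exposure
#' variation); every other lane is drawn so its percent-of-reference is the
#' target mean plus Gaussian noise of `sdPercent` percentage points.
#'
#' @param meanPercent named vector of target percent-of-reference activities;
#'   must include `referenceLabel` (typically at 100).
#' @param sdPercent replicate noise, percentage points.
#' @param nReplicates number of replicates.
#' @param referenceLabel the reference (wild-type) label.
#' @param refIntensity nominal reference band intensity.
#' @param seed integer seed.
#' @return list with `lanes` (`data.frame`: `label`, `replicate`,
#'   `intensity`) and `truth` (the target percents).
#' @export
generateGelLanes <- function(meanPercent, sdPercent = 5, nReplicates = 3,
                             referenceLabel = "WT", refIntensity = 1000,
                             seed = 1) {
  stopifnot(!is.null(names(meanPercent)),
            referenceLabel %in% names(meanPercent))
  withr::with_seed(seed, {
    out <- lapply(seq_len(nReplicates), function(r) {
      ref <- refIntensity * stats::rlnorm(1L, 0, 0.1)
      pct <- meanPercent + stats::rnorm(length(meanPercent), 0, sdPercent)
      pct[referenceLabel] <- 100
      pct <- pmax(pct, 0)
      data.frame(label = names(meanPercent), replicate = r,
                 intensity = ref * pct / 100)
    })
    list(lanes = do.call(rbind, out), truth = meanPercent)
  })
}

#' Generate a structure pair with known rigid per-region offsets
#'
#' The base model is a synthetic C-alpha trace on a regular helix (2.3
#' Angstrom radius, 1.5 Angstrom rise, 100 degrees per residue). The partner
#' copy has every listed region rigidly translated by its designed offset
#' magnitude (random seeded direction) plus isotropic Gaussian coordinate
#' noise everywhere.
#'
#' @param nResidues chain length of the trace.
#' @param regions named list; each element `list(start =, end =, offset =)`
#'   gives an inclusive residue range and a translation magnitude in
#'   Angstrom. Ranges must not overlap.
#' @param noiseSd isotropic coordinate noise SD, Angstrom, applied to the
#'   partner copy.
#' @param chain chain identifier for both models.
#' @param seed integer seed.
#' @return list with `ref` and `mob` ([StructureModel-class]) and `truth`
#'   (per-region offsets and directions, plus `noiseSd`).
#' @export
generateStructurePair <- function(nResidues = 167,
                                  regions = list(alphaA = list(start = 11,
                                                               end = 21,
                                                               offset = 1.7)),
                                  noiseSd = 0, chain = "A", seed = 1) {
  stopifnot(nResidues >= 10)
  rng <- do.call(rbind, lapply(regions, function(r) c(r$start, r$end)))
  if (!is.null(rng)) {
    stopifnot(all(rng[, 1L] <= rng[, 2L]), all(rng >= 1),
              all(rng <= nResidues))
    hits <- unlist(apply(rng, 1L, function(r) r[1L]:r[2L]))
    if (anyDuplicated(hits)) stop("region definitions overlap")
  }
  withr::with_seed(seed, {
    t <- seq_len(nResidues)
    ang <- t * 100 * pi / 180
    base <- data.frame(name = "CA", resname = "ALA", chain = chain,
                       resseq = t, x = 2.3 * cos(ang), y = 2.3 * sin(ang),
                       z = 1.5 * t)
    ref <- structureModel(base)
    mobAt <- base
    dirs <- list()
    for (nm in names(regions)) {
      r <- regions[[nm]]
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      dirs[[nm]] <- u * r$offset
      sel <- mobAt$resseq >= r$start & mobAt$resseq <= r$end
      mobAt$x[sel] <- mobAt$x[sel] + u[1L] * r$offset
      mobAt$y[sel] <- mobAt$y[sel] + u[2L] * r$offset
      mobAt$z[sel] <- mobAt$z[sel] + u[3L] * r$offset
    }
    if (noiseSd > 0) {
      mobAt$x <- mobAt$x + stats::rnorm(nResidues, 0, noiseSd)
      mobAt$y <- mobAt$y + stats::rnorm(nResidues, 0, noiseSd)
      mobAt$z <- mobAt$z + stats::rnorm(nResidues, 0, noiseSd)
    }
    list(ref = ref, mob = structureModel(mobAt),
         truth = list(regions = regions, directions = dirs,
                      noiseSd = noiseSd))
  })
}
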