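## Phosphotransfer gel quantification.
##
## Band intensities (e.g. ImageJ densitometry of phosphorimaged SDS-PAGE
## lanes) enter as a flat table; activity is expressed per replicate as a
## percentage of that replicate's reference (wild-type) lane, then averaged
## across replicates with a sample (n-1) standard deviation.

#' Percent-of-wild-type activity from gel lane intensities
#'
#' For every replicate `r` and lane label `x`,
#' `p[x, r] = 100 * I[x, r] / I[ref, r]`; the function reports the mean and
#' sample SD of `p` across replicates for each label. Normalization is
#' per-replicate, so a global exposure change within one replicate cancels.
#' The reference label reports exactly 100 with SD 0 by construction.
#'
#' @param lanes `data.frame` with columns `label`, `replicate`, `intensity`
#'   and optionally `background` (subtracted from `intensity` before
#'   normalization).
#' @param referenceLabel label of the reference (wild-type) lane; every
#'   replicate must contain it with positive intensity.
#' @return `data.frame` with columns `label`, `mean_percent`, `sd_percent`
#'   (`NA` for n = 1), `n`, in first-appearance label order.
#' @examples
#' lanes <- data.frame(label = rep(c("WT", "G68Q"), 3),
#'                     replicate = rep(1:3, each = 2),
#'                     intensity = c(1000, 400, 900, 350, 1100, 450))
#' percentOfWildtype(lanes, "WT")
#' @export
percentOfWildtype <- function(lanes, referenceLabel = "WT") {
  req <- c("label", "replicate", "intensity")
  if (!all(req %in% names(lanes)))
    stop("lanes must have columns label, replicate, intensity")
  if (any(lanes$intensity < 0)) stop("intensities must be non-negative")
  if (!is.null(lanes$background)) {
    lanes$intensity <- pmax(lanes$intensity - lanes$background, 0)
  }
  labels <- unique(lanes$label)
  if (!referenceLabel %in% labels)
    stop(sprintf("reference label '%s' not present", referenceLabel))
  pct <- lapply(split(lanes, lanes$replicate), function(d) {
    ref <- d$intensity[d$label == referenceLabel]
    if (length(ref) != 1L)
      stop(sprintf("replicate %s lacks a unique '%s' reference lane",
                   d$replicate[1L], referenceLabel))
    if (ref <= 0)
      stop(sprintf("replicate %s has non-positive reference intensity",
                   d$replicate[1L]))
    data.frame(label = d$label, percent = 100 * d$intensity / ref)
  })
  pct <- do.call(rbind, pct)
  out <- do.call(rbind, lapply(labels, function(lb) {
    p <- pct$percent[pct$label == lb]
    data.frame(label = lb, mean_percent = mean(p),
               sd_percent = if (length(p) >= 2L) stats::sd(p) else NA_real_,
               n = length(p))
  }))
  rownames(out) <- NULL
  out
}
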