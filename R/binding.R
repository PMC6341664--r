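## Fluorescence titration analysis under ligand depletion.
##
## When receptor and titrant concentrations are comparable (here ~16 nM
## labelled Ypd1 titrated with 10 nM - 6 uM Sln1-R1), the free-ligand
## approximation fails and the complex concentration follows the mass-action
## quadratic. The normalized, buffer-subtracted signal is modelled as
##   delta(L_T) = A * [RL](R_T, L_T, Kd) / R_T,
## a two-state (bound/unbound fluorescence) parameterization in which the
## free-state term is absorbed by F/F0 normalization.

#' Complex concentration under ligand depletion
#'
#' Solves the mass-action quadratic for the complex concentration:
#' `[RL] = ((R_T + L_T + Kd) - sqrt((R_T + L_T + Kd)^2 - 4 R_T L_T)) / 2`,
#' evaluated in the numerically stable form
#' `2 R_T L_T / (b + sqrt(b^2 - 4 R_T L_T))` to avoid cancellation when
#' `Kd` is small relative to the totals.
#'
#' @param rTotal total receptor concentration R_T, molar (scalar or vector).
#' @param lTotal total ligand concentration L_T, molar (scalar or vector).
#' @param kd dissociation constant, molar, > 0.
#' @return complex concentration, molar; always in `[0, min(R_T, L_T)]`.
#' @examples
#' complexConcentration(1e-6, 1e-6, 1e-6)  # (3 - sqrt(5))/2 uM
#' @export
complexConcentration <- function(rTotal, lTotal, kd) {
  if (any(rTotal < 0) || any(lTotal < 0)) stop("concentrations must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  b <- rTotal + lTotal + kd
  disc <- b * b - 4 * rTotal * lTotal
  disc[disc < 0] <- 0                          # guard rounding at Kd -> 0
  2 * rTotal * lTotal / (b + sqrt(disc))
}

#' Construct a titration series
#'
#' @param receptorTotal total receptor concentration R_T, molar (e.g. 30 pmol
#'   in 1.9 mL is about 15.8 nM).
#' @param ltotal strictly increasing total titrant concentrations, molar.
#' @param intensity raw fluorescence intensities after each addition.
#' @param f0 baseline intensity before any addition (L_T = 0).
#' @return a [Titration-class].
#' @export
titration <- function(receptorTotal, ltotal, intensity, f0) {
  new("Titration", receptorTotal = as.numeric(receptorTotal),
      ltotal = as.numeric(ltotal), intensity = as.numeric(intensity),
      f0 = as.numeric(f0))
}

#' Normalize a titration against a buffer-only series
#'
#' Per shared addition index i, the binding signal is
#' `delta_i = F_i/F0 (titrant series) - F_i/F0 (buffer series)`; L_T is taken
#' from the titrant series. The buffer subtraction removes dilution and
#' drift common to both series.
#'
#' @param ligandSeries [Titration-class] with the binding partner titrated in.
#' @param bufferSeries [Titration-class] of matched buffer-only additions.
#' @return a [NormalizedTitration-class].
#' @export
normalizeTitration <- function(ligandSeries, bufferSeries) {
  stopifnot(is(ligandSeries, "Titration"), is(bufferSeries, "Titration"))
  if (length(ligandSeries@ltotal) != length(bufferSeries@ltotal))
    stop("ligand and buffer series must share the same addition schedule")
  delta <- ligandSeries@intensity / ligandSeries@f0 -
    bufferSeries@intensity / bufferSeries@f0
  new("NormalizedTitration", receptorTotal = ligandSeries@receptorTotal,
      ltotal = ligandSeries@ltotal, delta = delta)
}

#' Predicted normalized binding response
#'
#' `delta = A * [RL] / R_T` with `[RL]` from [complexConcentration()];
#' saturates at `A` as L_T grows.
#'
#' @param kd dissociation constant, molar.
#' @param amplitude signed saturating amplitude A.
#' @param rTotal total receptor concentration, molar, > 0.
#' @param lTotal total ligand concentration(s), molar.
#' @return predicted delta, same length as `lTotal`.
#' @export
predictResponse <- function(kd, amplitude, rTotal, lTotal) {
  if (any(rTotal <= 0)) stop("rTotal must be > 0")
  amplitude * complexConcentration(rTotal, lTotal, kd) / rTotal
}

#' Fit the ligand-depletion binding isotherm
#'
#' Unweighted nonlinear least squares of
#' `delta_i ~ A * [RL](R_T, L_T_i, Kd) / R_T` over `(Kd, A)`, with `Kd`
#' parameterized on the log scale and bounded to `[1e-12, 1e-2]` M.
#' Initialization: `Kd0` = L_T at the half-maximal observed response,
#' `A0` = the largest-magnitude observed response. Standard errors come from
#' the local curvature at the optimum (delta method for `Kd`). An optional
#' linear-in-L_T drift nuisance term can be freed with `drift = TRUE`.
#'
#' @param data a [NormalizedTitration-class] with at least 4 points.
#' @param drift add a nuisance term `slope * L_T / max(L_T)` (default off).
#' @param weights optional per-point weights (e.g. 1/variance).
#' @return a [BindingFit-class]. Non-convergence is reported via
#'   `converged = FALSE` rather than an error; degenerate data (constant
#'   response) is an error.
#' @export
fitBinding <- function(data, drift = FALSE, weights = NULL) {
  stopifnot(is(data, "NormalizedTitration"))
  lt <- data@ltotal; y <- data@delta; rt <- data@receptorTotal
  if (length(y) < 4L) stop("at least 4 titration points are required")
  if (max(y) - min(y) <= .Machine$double.eps * max(1, max(abs(y))))
    stop("degenerate titration: all responses are equal; nothing to fit")
  a0 <- y[which.max(abs(y))]
  half <- which.min(abs(y - a0 / 2))
  kd0 <- max(lt[half], 1e-10)
  if (!any(abs(y) < abs(a0) / 2) || !any(abs(y) > abs(a0) / 2))
    warning("responses do not bracket the midpoint; Kd may be poorly determined")
  df <- data.frame(lt = lt, y = y, ltn = lt / max(lt))
  if (is.null(weights)) weights <- rep(1, length(y))
  fml <- if (drift)
    y ~ a * complexConcentration(rt, lt, exp(logkd)) / rt + slope * ltn
  else
    y ~ a * complexConcentration(rt, lt, exp(logkd)) / rt
  start <- c(list(logkd = log(kd0), a = a0), if (drift) list(slope = 0))
  lower <- c(logkd = log(1e-12), a = -Inf, if (drift) c(slope = -Inf))
  upper <- c(logkd = log(1e-2), a = Inf, if (drift) c(slope = Inf))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start, weights = weights,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("BindingFit", kd = NA_real_, amplitude = NA_real_,
               se = c(kd = NA_real_, amplitude = NA_real_), rss = NA_real_,
               converged = FALSE, nPoints = length(y),
               message = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  kd <- exp(cf[["logkd"]])
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  new("BindingFit", kd = kd, amplitude = cf[["a"]],
      se = c(kd = kd * unname(se["logkd"]),     # delta method on log scale
             amplitude = unname(se["a"])),
      rss = sum(stats::residuals(fit)^2), converged = TRUE,
      nPoints = length(y),
      message = fit$convInfo$stopMessage %||% "converged")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize replicate dissociation-constant fits
#'
#' The reported Kd across replicate titrations is the mean of per-replicate
#' estimates with their sample standard deviation, matching the convention of
#' deriving binding constants and standard deviations from replicate
#' titrations.
#'
#' @param fits list of [BindingFit-class] objects (replicates).
#' @return `data.frame` with `kd_mean`, `kd_sd`, `n` (converged fits only).
#' @export
summarizeReplicateFits <- function(fits) {
  kds <- vapply(fits, function(f) if (f@converged) f@kd else NA_real_, 0)
  kds <- kds[is.finite(kds)]
  if (!length(kds)) stop("no converged replicate fits to summarize")
  data.frame(kd_mean = mean(kds),
             kd_sd = if (length(kds) >= 2L) stats::sd(kds) else NA_real_,
             n = length(kds))
}
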