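## Pressure- and tension-response curve fitting.
##
## All dose-response fitting uses the 3-parameter Boltzmann (logistic)
## I = A / (1 + exp(-k (x - x50))) with the stimulus entered as a
## magnitude (suction positive, tension positive). Per-patch analysis
## first fits the raw peak currents against pressure, divides by that
## fit's plateau A to normalise, then fits the normalised currents
## against tension (unbinned). Cohort curves pool normalised points,
## bin tension at 1 mN/m, and fit the bin means weighted by 1/SD^2.

#' Fit a Boltzmann function to response points
#'
#' Nonlinear least squares of \code{A / (1 + exp(-k (x - x50)))}.
#' Initialisation: \code{A} = maximum response, \code{x50} = stimulus at
#' half-maximum by linear interpolation, \code{k} = 4 / stimulus range;
#' bounds keep \code{A > 0} and \code{k > 0}. Fits with fewer than 4
#' points, points on one side of the inflection only, or a maximum
#' response below 0.8 A are flagged low-confidence.
#'
#' @param stimulus numeric vector of stimulus magnitudes (mmHg or mN/m).
#' @param response numeric vector of responses (pA or normalised).
#' @param weights optional fit weights (e.g. 1/SD^2 for binned means).
#' @param stimulusType \code{"tension"} or \code{"pressure"} (metadata
#'   only).
#' @return A \linkS4class{BoltzmannParams}.
#' @export
fitBoltzmann <- function(stimulus, response, weights = NULL,
                         stimulusType = c("tension", "pressure")) {
  stimulusType <- match.arg(stimulusType)
  ok <- is.finite(stimulus) & is.finite(response)
  stimulus <- stimulus[ok]; response <- response[ok]
  if (!is.null(weights)) weights <- weights[ok]
  n <- length(stimulus)
  if (n < 3L) stopf("Boltzmann fit needs >= 3 points, have %d", n)
  if (stats::sd(response) < 1e-12)
    stopf("all responses equal: Boltzmann fit is unidentifiable")
  rng <- diff(range(stimulus))
  if (rng <= 0) stopf("all stimuli equal")
  a0 <- max(response)
  ord <- order(stimulus)
  x50_0 <- tryCatch(
    stats::approx(response[ord], stimulus[ord], xout = a0 / 2,
                  ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(x50_0)) x50_0 <- stats::median(stimulus)
  dat <- data.frame(x = stimulus, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / (1 + exp(-k * (x - x50))), data = dat,
      weights = if (is.null(weights)) rep(1, n) else weights,
      start = list(A = a0, k = 4 / rng, x50 = x50_0),
      lower = c(1e-9, 1e-6, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stopf("Boltzmann fit did not converge (n = %d, range %.3g)", n, rng)
  p <- stats::coef(fit)
  covm <- tryCatch(unname(stats::vcov(fit)),
                   error = function(e) matrix(NA_real_, 3, 3))
  lowConf <- n < 4L ||
    max(response) / p[["A"]] < 0.8 ||
    !any(stimulus < p[["x50"]]) || !any(stimulus > p[["x50"]])
  new("BoltzmannParams", A = unname(p[["A"]]), k = unname(p[["k"]]),
      x50 = unname(p[["x50"]]), cov = covm, stimulusType = stimulusType,
      nPoints = as.integer(n), lowConfidence = lowConf)
}

#' Normalise peak currents by a fit's plateau
#'
#' Divides each peak current by the plateau amplitude \code{A} of a
#' Boltzmann fit; after normalisation a refit has plateau 1 within fit
#' tolerance.
#'
#' @param peaks numeric vector of peak currents (pA).
#' @param fit a \linkS4class{BoltzmannParams} with \code{A > 0}.
#' @return Numeric vector of normalised currents.
#' @export
normalizePeaks <- function(peaks, fit) {
  peaks / plateau(fit)
}

#' Per-patch tension-response fit
#'
#' The full per-patch chain: peak extraction with rundown exclusion,
#' pressure-fit normalisation (the raw peaks are fit against pressure
#' magnitude and divided by that fit's plateau), joining each retained
#' sweep to its dome tension, and an unbinned Boltzmann fit of normalised
#' current against tension yielding the patch's (T50, k).
#'
#' @param patch a \linkS4class{PatchRecord} whose \code{domes} table has
#'   one row per imaged pressure step with columns \code{pressure_mmHg},
#'   \code{r_um} and (optionally) \code{qc_keep}.
#' @param minPeak patch-inclusion threshold (pA), see
#'   \code{\link{qualifyPatch}}.
#' @return list: \code{fit} (\linkS4class{BoltzmannParams} for tension),
#'   \code{pressureFit}, \code{points} (data.frame of joined points with
#'   exclusion flags), \code{excluded} (bookkeeping counts).
#' @export
patchTensionResponse <- function(patch,
                                 minPeak = ptConstants$PEAK_INCLUSION_PA) {
  pk <- patchPeaks(patch)
  qual <- qualifyPatch(pk$Ip, patch@metadata, mode = "cell-attached",
                       minPeak = minPeak)
  if (!qual$include)
    stopf("patch '%s' excluded: %s", patch@patchId,
          paste(qual$reasons, collapse = "; "))
  use <- !pk$rundown
  pfit <- fitBoltzmann(abs(pk$stimulus[use]), pk$Ip[use],
                       stimulusType = "pressure")
  pk$I_norm <- normalizePeaks(pk$Ip, pfit)
  domes <- patch@domes
  if (!nrow(domes)) stopf("patch '%s' has no dome observations",
                          patch@patchId)
  if (!is.null(domes$qc_keep)) domes <- domes[domes$qc_keep, , drop = FALSE]
  pts <- merge(pk, domes[, c("pressure_mmHg", "r_um")],
               by.x = "stimulus", by.y = "pressure_mmHg")
  pts$tension <- computeTension(pts$stimulus, pts$r_um)$tension_mN_per_m
  pts$included <- !pts$rundown
  fitPts <- pts[pts$included, , drop = FALSE]
  if (nrow(fitPts) < 4L)
    stopf("patch '%s': only %d joined points after exclusions",
          patch@patchId, nrow(fitPts))
  tfit <- fitBoltzmann(fitPts$tension, fitPts$I_norm,
                       stimulusType = "tension")
  list(fit = tfit, pressureFit = pfit, points = pts,
       excluded = list(rundown = sum(pk$rundown),
                       noDome = nrow(pk) - nrow(pts),
                       total = nrow(pk)))
}

#' Cohort tension-response curve from pooled, binned points
#'
#' Pools all patches' normalised (tension, response) points, bins tension
#' in 1 mN/m increments (left-closed bins, labelled at the midpoint),
#' computes mean/SD/n per bin, and fits the Boltzmann weighted by 1/SD^2.
#' Bins holding a single point borrow the median SD of the multi-point
#' bins for weighting.
#'
#' @param pointsList list of per-patch data.frames with columns
#'   \code{tension} and \code{I_norm} (e.g. the included points from
#'   \code{\link{patchTensionResponse}}).
#' @param binWidth bin width in mN/m.
#' @return list: \code{bins} (data.frame \code{bin_mid}, \code{mean},
#'   \code{sd}, \code{n}), \code{fit} (\linkS4class{BoltzmannParams}).
#' @export
cohortTensionCurve <- function(pointsList, binWidth = 1) {
  if (length(pointsList) < 3L)
    stopf("cohort curve needs >= 3 qualified patches, have %d",
          length(pointsList))
  pooled <- do.call(rbind, lapply(pointsList, function(p)
    p[, c("tension", "I_norm")]))
  bin <- floor(pooled$tension / binWidth)
  agg <- do.call(rbind, lapply(split(pooled$I_norm, bin), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  agg$bin_mid <- (as.numeric(rownames(agg)) + 0.5) * binWidth
  agg <- agg[order(agg$bin_mid), c("bin_mid", "mean", "sd", "n")]
  rownames(agg) <- NULL
  if (nrow(agg) < 3L)
    stopf("only %d occupied tension bins; need >= 3", nrow(agg))
  multi <- agg$n > 1L & agg$sd > 0
  if (!any(multi))
    stopf("no bin has a finite SD; cannot form weights")
  fillSd <- stats::median(agg$sd[multi])
  agg$sd_weight <- ifelse(multi, agg$sd, fillSd)
  fit <- fitBoltzmann(agg$bin_mid, agg$mean, weights = 1 / agg$sd_weight^2,
                      stimulusType = "tension")
  list(bins = agg[, c("bin_mid", "mean", "sd", "n")], fit = fit)
}

#' Per-patch pressure-response fit
#'
#' Fits the Boltzmann to normalised peak current against pressure
#' magnitude; P50 is reported in mmHg magnitude (suction positive).
#'
#' @param patch a \linkS4class{PatchRecord}.
#' @param minPeak patch-inclusion threshold (pA).
#' @return list: \code{fit} (\linkS4class{BoltzmannParams}, normalised so
#'   its plateau is ~1), \code{rawFit}, \code{points}.
#' @export
pressureResponse <- function(patch,
                             minPeak = ptConstants$PEAK_INCLUSION_PA) {
  pk <- patchPeaks(patch)
  qual <- qualifyPatch(pk$Ip, patch@metadata, mode = "cell-attached",
                       minPeak = minPeak)
  if (!qual$include)
    stopf("patch '%s' excluded: %s", patch@patchId,
          paste(qual$reasons, collapse = "; "))
  use <- !pk$rundown
  raw <- fitBoltzmann(abs(pk$stimulus[use]), pk$Ip[use],
                      stimulusType = "pressure")
  pk$I_norm <- normalizePeaks(pk$Ip, raw)
  fit <- fitBoltzmann(abs(pk$stimulus[use]), pk$I_norm[use],
                      stimulusType = "pressure")
  list(fit = fit, rawFit = raw, points = pk)
}
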