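## Single-channel conductance from amplitude histograms.
##
## Current samples from a handful of isolated opening events are
## histogrammed; the baseline and open levels appear as two modes and are
## fit with a two-Gaussian mixture. The unitary current iu = |c2 - c1|
## per voltage feeds an ordinary least-squares I-V fit whose slope is the
## conductance g (pS when iu is in pA and V in mV).

#' Build an amplitude histogram
#'
#' Bin width defaults to the Freedman-Diaconis rule with a floor of one
#' third of a robust noise SD estimate, so the two levels are resolved
#' without empty-bin shot noise dominating.
#'
#' @param samples numeric vector of current samples (pA).
#' @param binWidth optional bin width (pA).
#' @return list: \code{mids}, \code{counts}, \code{binWidth}.
#' @export
amplitudeHistogram <- function(samples, binWidth = NULL) {
  if (is.null(binWidth)) {
    fd <- 2 * stats::IQR(samples) / length(samples)^(1 / 3)
    noiseSd <- stats::mad(samples)
    binWidth <- max(fd, noiseSd / 3, 1e-4)
  }
  rng <- range(samples)
  breaks <- seq(rng[1] - binWidth, rng[2] + binWidth, by = binWidth)
  if (breaks[length(breaks)] < rng[2]) breaks <- c(breaks, rng[2] + binWidth)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  list(mids = h$mids, counts = h$counts, binWidth = binWidth)
}

#' Fit a double Gaussian to an amplitude histogram
#'
#' Least-squares fit of the two-component scaled-density mixture
#' \code{y = A1 phi((x - c1)/s1) + A2 phi((x - c2)/s2)} to the histogram
#' of samples from 3-5 isolated opening events; the unitary current is
#' \code{iu = |c2 - c1|}. Requires a bimodal histogram: the two candidate
#' levels must be separated by a dip and by more than their pooled widths,
#' otherwise an "insufficient level separation" error is raised.
#'
#' @param samples numeric vector of current samples spanning the closed
#'   and open levels.
#' @param nEvents number of isolated opening events the samples come from
#'   (< 3 raises an "insufficient events" error).
#' @param binWidth optional histogram bin width (pA).
#' @return list: \code{A1}, \code{A2}, \code{c1}, \code{c2},
#'   \code{sigma1}, \code{sigma2}, \code{iu} (pA), \code{histogram}.
#' @export
fitDoubleGaussian <- function(samples, nEvents = 3L, binWidth = NULL) {
  if (nEvents < 3L)
    stopf("insufficient events: %d < 3 isolated openings", nEvents)
  ## candidate levels from 2-means on the samples
  km <- tryCatch(stats::kmeans(samples, centers = 2, nstart = 5),
                 error = function(e) NULL)
  if (is.null(km))
    stopf("insufficient level separation: could not resolve two levels")
  if (is.null(binWidth)) {
    ## within-level spread, not pooled spread: a pooled IQR/MAD straddles
    ## both modes and gives bins too coarse to localise the level centres
    wsd <- vapply(split(samples, km$cluster), stats::mad, numeric(1))
    wsd <- wsd[is.finite(wsd) & wsd > 0]
    sepKm <- abs(diff(as.numeric(km$centers)))
    binWidth <- max(if (length(wsd)) min(wsd) / 3 else sepKm / 200,
                    sepKm / 400, 1e-4)
  }
  h <- amplitudeHistogram(samples, binWidth)
  ctr <- sort(as.numeric(km$centers))
  sdsRaw <- vapply(split(samples, km$cluster), stats::sd, numeric(1))
  sep <- diff(ctr)
  ## noiseless limit: two (near-)discrete levels — the mixture fit is
  ## degenerate, the level centres are the cluster means
  if (all(!is.finite(sdsRaw) | sdsRaw < 1e-9 * max(sep, 1))) {
    ord <- order(as.numeric(km$centers))
    amp <- as.numeric(table(km$cluster)[ord]) * h$binWidth
    return(list(A1 = amp[1], A2 = amp[2], c1 = ctr[1], c2 = ctr[2],
                sigma1 = h$binWidth / 2, sigma2 = h$binWidth / 2,
                iu = sep, histogram = h))
  }
  sds <- sdsRaw
  sds[!is.finite(sds) | sds <= 0] <- h$binWidth
  ## a unimodal distribution split by 2-means gives centres ~1.6 pooled
  ## SDs apart with within-cluster SDs ~0.6 of it; genuine two-level data
  ## separate by many within-level SDs
  if (sep < 3 * max(sds) || sep < 2 * h$binWidth)
    stopf("insufficient level separation: modes %.3g pA apart (widths %.3g)",
          sep, max(sds))
  ## dip check between the modes
  between <- h$mids > ctr[1] & h$mids < ctr[2]
  peakCounts <- vapply(ctr, function(cc)
    max(h$counts[abs(h$mids - cc) <= max(sds, h$binWidth)]), numeric(1))
  if (sum(between) >= 1 && min(h$counts[between]) > 0.5 * min(peakCounts))
    stopf("insufficient level separation: no dip between modes")
  dat <- data.frame(x = h$mids, y = h$counts)
  s0 <- unname(pmax(sds, h$binWidth / 2))
  amp <- vapply(seq_along(ctr), function(i)
    sum(km$cluster == order(as.numeric(km$centers))[i]) * h$binWidth,
    numeric(1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 / (s1 * sqrt(2 * pi)) * exp(-0.5 * ((x - c1) / s1)^2) +
          A2 / (s2 * sqrt(2 * pi)) * exp(-0.5 * ((x - c2) / s2)^2),
      data = dat,
      start = list(A1 = amp[1], c1 = ctr[1], s1 = s0[1],
                   A2 = amp[2], c2 = ctr[2], s2 = s0[2]),
      lower = c(0, -Inf, 1e-6, 0, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stopf("double-Gaussian fit did not converge")
  p <- as.list(stats::coef(fit))
  iu <- abs(p$c2 - p$c1)
  if (iu <= 0) stopf("insufficient level separation: coincident centres")
  list(A1 = p$A1, A2 = p$A2, c1 = p$c1, c2 = p$c2,
       sigma1 = p$s1, sigma2 = p$s2, iu = iu, histogram = h)
}

#' Linear I-V fit for slope conductance
#'
#' Ordinary least squares of signed unitary current against voltage:
#' \code{iu = g V + b}. With iu in pA and V in mV the slope is in nS and
#' is reported in pS. Signed unitary currents (negative at negative
#' potentials for an inward channel) give a positive g for an ohmic
#' channel.
#'
#' @param voltage_mV numeric vector of holding voltages (>= 2 distinct).
#' @param iu_pA signed unitary currents.
#' @return list: \code{g_pS}, \code{b_pA}, \code{fit} (the \code{lm}),
#'   \code{points}.
#' @export
fitIVSlope <- function(voltage_mV, iu_pA) {
  if (length(unique(voltage_mV)) < 2L)
    stopf("I-V fit needs >= 2 distinct voltages")
  fit <- stats::lm(iu_pA ~ voltage_mV)
  list(g_pS = unname(stats::coef(fit)[["voltage_mV"]]) * 1e3,
       b_pA = unname(stats::coef(fit)[["(Intercept)"]]),
       fit = fit,
       points = data.frame(voltage_mV = voltage_mV, iu_pA = iu_pA))
}

#' Conductance from a set of single-channel sweeps
#'
#' For each voltage: pool the samples of the listed event windows, fit
#' the double Gaussian, and take the signed unitary current as the open
#' level minus the closed level (the level closer to zero). Then fit the
#' I-V line across voltages.
#'
#' @param sweeps list of voltage-step \linkS4class{SweepTrace} objects.
#' @param eventRanges list (parallel to \code{sweeps}) of lists of
#'   index ranges \code{c(from, to)} delimiting isolated opening events.
#' @param binWidth optional histogram bin width (pA).
#' @return list: \code{iv} (from \code{\link{fitIVSlope}}),
#'   \code{perVoltage} (data.frame with c1, c2, sigma1, sigma2, iu).
#' @export
singleChannelConductance <- function(sweeps, eventRanges, binWidth = NULL) {
  stopifnot(length(sweeps) == length(eventRanges))
  rows <- lapply(seq_along(sweeps), function(i) {
    tr <- sweeps[[i]]
    ranges <- eventRanges[[i]]
    if (length(ranges) < 3L)
      stopf("insufficient events: %d < 3 at %g mV", length(ranges),
            stimulusValue(tr))
    samp <- unlist(lapply(ranges, function(rg)
      currentTrace(tr)[rg[1]:rg[2]]))
    dg <- fitDoubleGaussian(samp, nEvents = length(ranges),
                            binWidth = binWidth)
    closed <- if (abs(dg$c1) <= abs(dg$c2)) dg$c1 else dg$c2
    open <- if (abs(dg$c1) <= abs(dg$c2)) dg$c2 else dg$c1
    data.frame(voltage_mV = stimulusValue(tr), iu_pA = open - closed,
               c1 = dg$c1, c2 = dg$c2, sigma1 = dg$sigma1,
               sigma2 = dg$sigma2)
  })
  pv <- do.call(rbind, rows)
  list(iv = fitIVSlope(pv$voltage_mV, pv$iu_pA), perVoltage = pv)
}
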