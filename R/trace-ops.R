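## Per-sweep current processing. Traces arrive acquisition-filtered
## (sampled at 10 kHz, 2.9 kHz low-pass in the recordings this pipeline
## targets); no digital re-filtering is applied here.

#' Subtract the pre-stimulus baseline from a sweep
#'
#' Subtracts the mean current measured before stimulus onset. Idempotent:
#' applying twice equals applying once.
#'
#' @param trace a \linkS4class{SweepTrace} with at least 10 pre-onset
#'   samples.
#' @return The baseline-subtracted \linkS4class{SweepTrace}.
#' @export
baselineSubtract <- function(trace) {
  if (trace@onset <= 10L)
    stopf("need >= 10 pre-onset samples, onset is at sample %d",
          trace@onset)
  bl <- mean(trace@current[seq_len(trace@onset - 1L)])
  trace@current <- trace@current - bl
  trace
}

#' Peak current of a sweep
#'
#' Finds the sample of maximal absolute current inside the stimulus window
#' and reports the mean absolute current over that sample and its two
#' neighbours on each side (five samples). When the extremum lies within
#' two samples of the window edge, the 5-sample block is shifted inward so
#' it stays inside the window.
#'
#' @param trace a baseline-subtracted \linkS4class{SweepTrace}; the
#'   stimulus window must hold at least 5 samples.
#' @return list: \code{Ip} (peak magnitude, pA, >= 0), \code{peakIndex}
#'   (sample of the extremum), \code{baseline} (pre-onset mean, pA).
#' @export
peakCurrent <- function(trace) {
  win <- trace@onset:trace@offset
  if (length(win) < 5L)
    stopf("stimulus window has %d < 5 samples", length(win))
  cur <- trace@current
  pk <- win[which.max(abs(cur[win]))]
  lo <- min(max(pk - 2L, trace@onset), trace@offset - 4L)
  block <- lo:(lo + 4L)
  list(Ip = mean(abs(cur[block])), peakIndex = pk,
       baseline = mean(cur[seq_len(trace@onset - 1L)]))
}

#' Flag rundown across a protocol's peak sequence
#'
#' A sweep is flagged as rundown when its peak falls below
#' \code{fraction} (default 0.7, i.e. a more than 30\% reduction) of the
#' reference peak. The default reference is the running maximum of all
#' earlier unflagged peaks — flagged sweeps never raise the reference, so
#' once rundown begins every later sweep is still judged against the
#' pre-rundown maximum. \code{reference = "previous"} instead compares
#' each peak to the immediately preceding unflagged peak.
#'
#' @param peaks numeric vector of peak magnitudes in protocol order.
#' @param fraction flagging threshold as a fraction of the reference.
#' @param reference \code{"runmax"} (default) or \code{"previous"}.
#' @return logical vector, TRUE where the sweep is excluded as rundown.
#' @export
detectRundown <- function(peaks, fraction = ptConstants$RUNDOWN_FRACTION,
                          reference = c("runmax", "previous")) {
  reference <- match.arg(reference)
  n <- length(peaks)
  flags <- logical(n)
  if (n < 2L) return(flags)
  ref <- 0
  for (i in seq_len(n)) {
    if (ref > 0 && peaks[i] < fraction * ref) {
      flags[i] <- TRUE
    } else {
      ref <- if (reference == "runmax") max(ref, peaks[i]) else peaks[i]
    }
  }
  flags
}

#' Qualify a patch for analysis
#'
#' Cell-attached recordings qualify when the maximal peak current reaches
#' 20 pA (inclusive), the seal resistance exceeds 1 GOhm, and the leak
#' current stays below 50 pA. Whole-cell recordings instead require a
#' compensated series resistance below 15 MOhm, leak below 100 pA, and
#' capacitance below 40 pF (the 20 pA peak rule applies to
#' tension-response analysis only, not to indentation recordings).
#'
#' @param peaks numeric vector of per-sweep peak magnitudes (pA).
#' @param metadata named list; cell-attached mode reads \code{seal_GOhm}
#'   and \code{leak_pA}; whole-cell mode reads \code{series_MOhm},
#'   \code{leak_pA}, \code{capacitance_pF}.
#' @param mode \code{"cell-attached"} or \code{"whole-cell"}.
#' @param minPeak inclusion threshold on the maximal peak (pA); set to 0
#'   to disable.
#' @return list with \code{include} and \code{reasons} (character vector
#'   of failed rules; empty when included).
#' @export
qualifyPatch <- function(peaks, metadata,
                         mode = c("cell-attached", "whole-cell"),
                         minPeak = ptConstants$PEAK_INCLUSION_PA) {
  mode <- match.arg(mode)
  need <- if (mode == "cell-attached") c("seal_GOhm", "leak_pA")
          else c("series_MOhm", "leak_pA", "capacitance_pF")
  missing <- setdiff(need, names(metadata))
  if (length(missing))
    stopf("missing patch metadata field(s): %s",
          paste(missing, collapse = ", "))
  reasons <- character()
  if (mode == "cell-attached") {
    if (minPeak > 0 && max(peaks) < minPeak)
      reasons <- c(reasons, sprintf("max peak %.1f pA < %g pA",
                                    max(peaks), minPeak))
    if (metadata$seal_GOhm <= 1)
      reasons <- c(reasons, sprintf("seal %.2f GOhm <= 1 GOhm",
                                    metadata$seal_GOhm))
    if (abs(metadata$leak_pA) >= 50)
      reasons <- c(reasons, sprintf("leak %.0f pA >= 50 pA",
                                    abs(metadata$leak_pA)))
  } else {
    if (metadata$series_MOhm >= 15)
      reasons <- c(reasons, sprintf("series resistance %.1f MOhm >= 15",
                                    metadata$series_MOhm))
    if (abs(metadata$leak_pA) >= 100)
      reasons <- c(reasons, sprintf("leak %.0f pA >= 100 pA",
                                    abs(metadata$leak_pA)))
    if (metadata$capacitance_pF >= 40)
      reasons <- c(reasons, sprintf("capacitance %.1f pF >= 40",
                                    metadata$capacitance_pF))
  }
  list(include = length(reasons) == 0L, reasons = reasons)
}

#' Fit single-exponential inactivation kinetics
#'
#' Fits \code{I(t) = Ib + Ip exp(-t / tau)} from the peak sample to the
#' stimulus offset, with time re-zeroed at the peak. Currents keep their
#' sign (\code{Ip} is negative for inward currents); tau is reported in
#' milliseconds.
#'
#' @param trace a baseline-subtracted \linkS4class{SweepTrace}.
#' @return list: \code{Ib}, \code{Ip} (pA), \code{tau_ms},
#'   \code{fitWindow} (sample range used).
#' @export
fitInactivationTau <- function(trace) {
  pk <- peakCurrent(trace)
  idx <- pk$peakIndex:trace@offset
  if (length(idx) < 20L)
    stopf("need >= 20 samples between peak and stimulus offset, have %d",
          length(idx))
  t_ms <- (trace@time[idx] - trace@time[pk$peakIndex]) * 1e3
  y <- trace@current[idx]
  ibInit <- mean(utils::tail(y, max(5L, length(y) %/% 10L)))
  ipInit <- y[1] - ibInit
  span <- max(t_ms)
  if (abs(ipInit) < 1e-12) stopf("flat post-peak current: nothing to fit")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Ib + Ip * exp(-t / tau),
      data = data.frame(t = t_ms, y = y),
      start = list(Ib = ibInit, Ip = ipInit, tau = span / 5),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stopf("inactivation fit did not converge")
  p <- stats::coef(fit)
  tau <- unname(p[["tau"]])
  if (!is.finite(tau) || tau <= 0 || tau > 10 * span)
    stopf("non-decaying trace: tau estimate %.3g ms outside (0, %.3g]",
          tau, 10 * span)
  list(Ib = unname(p[["Ib"]]), Ip = unname(p[["Ip"]]), tau_ms = tau,
       fitWindow = range(idx))
}

#' Peak table for a patch
#'
#' Applies \code{\link{baselineSubtract}} and \code{\link{peakCurrent}} to
#' every sweep of a patch and marks rundown sweeps. Patches that carry a
#' pre-computed peak table instead of raw sweeps (e.g. peak-level
#' synthetic data or peaks imported from another tool) use it directly;
#' rundown flags are still recomputed here.
#'
#' @param patch a \linkS4class{PatchRecord}.
#' @param rundownReference passed to \code{\link{detectRundown}}.
#' @return data.frame: \code{sweep}, \code{stimulus} (signed),
#'   \code{Ip}, \code{rundown}.
#' @export
patchPeaks <- function(patch, rundownReference = "runmax") {
  if (length(patch@sweeps)) {
    rows <- lapply(seq_along(patch@sweeps), function(i) {
      tr <- baselineSubtract(patch@sweeps[[i]])
      pk <- peakCurrent(tr)
      data.frame(sweep = i, stimulus = stimulusValue(tr), Ip = pk$Ip)
    })
    out <- do.call(rbind, rows)
  } else if (nrow(patch@peaks)) {
    out <- patch@peaks[, c("sweep", "stimulus", "Ip")]
  } else {
    stopf("patch '%s' has neither sweeps nor a peak table", patch@patchId)
  }
  out$rundown <- detectRundown(out$Ip, reference = rundownReference)
  out
}
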