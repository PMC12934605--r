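#' @import methods
NULL

#' SweepTrace: one stimulus step's current time series
#'
#' Container for a single acquired (or simulated) sweep: a uniformly sampled
#' current trace together with the stimulus applied during that sweep
#' (a pressure in mmHg, a holding voltage in mV, or an indentation depth in
#' micrometres) and the sample indices delimiting the stimulus window.
#'
#' Currents are signed pA; at a holding potential of -80 mV inward currents
#' are negative. The stimulus value keeps its acquisition sign (suction
#' negative); magnitude conventions are applied at fitting time, never here.
#'
#' @slot time numeric, seconds, uniform grid.
#' @slot current numeric, pA, same length as \code{time}.
#' @slot stimulusValue numeric(1), mmHg, mV or um depending on
#'   \code{stimulusType}.
#' @slot stimulusType character(1), one of \code{"pressure"},
#'   \code{"voltage"}, \code{"depth"}.
#' @slot onset integer(1), first sample index (1-based) of the stimulus.
#' @slot offset integer(1), last sample index of the stimulus.
#'
#' @export
setClass("SweepTrace",
  representation(
    time = "numeric",
    current = "numeric",
    stimulusValue = "numeric",
    stimulusType = "character",
    onset = "integer",
    offset = "integer"
  )
)

setValidity("SweepTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@current) != n)
    msg <- c(msg, "time and current must have equal length")
  if (n >= 3) {
    dt <- diff(object@time)
    if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]) + 1e-12)
      msg <- c(msg, "time grid must be uniform")
  }
  if (!object@stimulusType %in% c("pressure", "voltage", "depth"))
    msg <- c(msg, "stimulusType must be 'pressure', 'voltage' or 'depth'")
  if (object@onset < 1L || object@onset >= object@offset ||
      object@offset > n)
    msg <- c(msg, "need 1 <= onset < offset <= length(time)")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepTrace
#'
#' @param time numeric vector of sample times (s), uniform grid.
#' @param current numeric vector of currents (pA).
#' @param stimulusValue stimulus applied during the sweep.
#' @param stimulusType one of \code{"pressure"}, \code{"voltage"},
#'   \code{"depth"}.
#' @param onset,offset sample indices (1-based, inclusive) of the stimulus
#'   window.
#' @return A \linkS4class{SweepTrace}.
#' @examples
#' tr <- SweepTrace(seq(0, 0.1, by = 1e-4), rnorm(1001), -20, "pressure",
#'                  onset = 200L, offset = 800L)
#' samplingRate(tr)
#' @export
SweepTrace <- function(time, current, stimulusValue, stimulusType,
                       onset, offset) {
  new("SweepTrace", time = as.numeric(time), current = as.numeric(current),
      stimulusValue = as.numeric(stimulusValue)[1],
      stimulusType = stimulusType,
      onset = as.integer(onset), offset = as.integer(offset))
}

#' CircleFit: fitted dome curvature
#'
#' Result of the weighted circular fit to sub-pixel band centres: circle
#' centre (column \code{h}, row \code{cy}), radius in pixels and micrometres,
#' and the radius standard deviation taken from the fit covariance. The
#' relative standard deviation \code{sigmaR / rPx} drives image-level QC.
#'
#' @slot h numeric(1), centre column (pixels, 0-based image coordinates).
#' @slot cy numeric(1), centre row (pixels).
#' @slot rPx numeric(1), radius in pixels.
#' @slot rUm numeric(1), radius in micrometres.
#' @slot sigmaR numeric(1), standard deviation of the radius (pixels).
#' @slot relSd numeric(1), \code{sigmaR / rPx}.
#' @slot nColumns integer(1), number of band localisations used.
#'
#' @export
setClass("CircleFit",
  representation(
    h = "numeric", cy = "numeric", rPx = "numeric", rUm = "numeric",
    sigmaR = "numeric", relSd = "numeric", nColumns = "integer"
  )
)

setValidity("CircleFit", function(object) {
  msg <- character()
  if (object@rPx <= 0) msg <- c(msg, "rPx must be positive")
  if (object@rUm <= 0) msg <- c(msg, "rUm must be positive")
  if (object@relSd < 0) msg <- c(msg, "relSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BoltzmannParams: three-parameter logistic dose-response fit
#'
#' Parameters of the Boltzmann function A / (1 + exp(-k (x - x50))) fitted
#' to a pressure- or tension-response curve: plateau amplitude \code{A}
#' (pA for raw fits, ~1 for normalized fits), slope \code{k}
#' (per mmHg, or m/mN for tension) and half-maximal stimulus \code{x50}
#' (mmHg or mN/m, magnitude convention).
#'
#' @slot A numeric(1), plateau amplitude.
#' @slot k numeric(1), slope, > 0.
#' @slot x50 numeric(1), half-maximal stimulus.
#' @slot cov matrix, 3x3 covariance of (A, k, x50).
#' @slot stimulusType character(1), \code{"pressure"} or \code{"tension"}.
#' @slot nPoints integer(1), points used in the fit.
#' @slot lowConfidence logical(1), TRUE when the data do not reach a plateau
#'   (max normalized response < 0.8) or span only one side of the inflection.
#'
#' @export
setClass("BoltzmannParams",
  representation(
    A = "numeric", k = "numeric", x50 = "numeric", cov = "matrix",
    stimulusType = "character", nPoints = "integer",
    lowConfidence = "logical"
  ),
  prototype(cov = matrix(NA_real_, 3, 3), stimulusType = "tension",
            nPoints = 0L, lowConfidence = FALSE)
)

setValidity("BoltzmannParams", function(object) {
  msg <- character()
  if (object@A <= 0) msg <- c(msg, "A must be positive")
  if (object@k <= 0) msg <- c(msg, "k must be positive")
  if (length(msg)) msg else TRUE
})

#' PatchRecord: all data for one patched cell
#'
#' Bundles a patch's sweeps, dome observations (one per imaged pressure
#' step), recording metadata used by patch qualification, and the derived
#' per-sweep peak table. QC decisions and fit results are attached by the
#' pipeline stages.
#'
#' @slot patchId character(1).
#' @slot construct character(1), group label (joined only at reporting).
#' @slot sweeps list of \linkS4class{SweepTrace}.
#' @slot domes data.frame with columns \code{pressure_mmHg}, \code{r_um},
#'   \code{sigma_r}, \code{rel_sd} (one row per imaged pressure step).
#' @slot metadata named list: \code{seal_GOhm}, \code{leak_pA},
#'   \code{holding_mV}; whole-cell recordings instead carry
#'   \code{series_MOhm}, \code{leak_pA}, \code{capacitance_pF}.
#' @slot peaks data.frame of per-sweep peak measurements (filled by
#'   \code{\link{patchPeaks}}).
#'
#' @export
setClass("PatchRecord",
  representation(
    patchId = "character", construct = "character",
    sweeps = "list", domes = "data.frame",
    metadata = "list", peaks = "data.frame"
  ),
  prototype(construct = NA_character_, domes = data.frame(),
            metadata = list(), peaks = data.frame())
)

setValidity("PatchRecord", function(object) {
  ok <- vapply(object@sweeps, is, logical(1), class2 = "SweepTrace")
  if (length(ok) && !all(ok)) "all sweeps must be SweepTrace objects" else TRUE
})

#' Construct a PatchRecord
#'
#' @param patchId patch identifier.
#' @param sweeps list of \linkS4class{SweepTrace}.
#' @param domes data.frame of dome radius observations (may be empty).
#' @param metadata named list of recording metadata.
#' @param construct optional group label.
#' @return A \linkS4class{PatchRecord}.
#' @export
PatchRecord <- function(patchId, sweeps, domes = data.frame(),
                        metadata = list(), construct = NA_character_) {
  new("PatchRecord", patchId = as.character(patchId), sweeps = sweeps,
      domes = domes, metadata = metadata,
      construct = as.character(construct))
}

#' GroundTruth: generator parameters attached to synthetic objects
#'
#' Every synthetic generator returns, next to its data, a GroundTruth
#' carrying each parameter actually used (radius and arc centre, per-patch
#' T50/k/A/tau, conductance, contact and threshold depth, ...). Recovery
#' tests read it only for scoring, never during estimation. Round-trips
#' losslessly through JSON.
#'
#' @slot params named list of generated parameters.
#' @export
setClass("GroundTruth", representation(params = "list"))

#' @rdname GroundTruth-class
#' @param ... named parameters to record.
#' @return A \linkS4class{GroundTruth}.
#' @export
GroundTruth <- function(...) new("GroundTruth", params = list(...))

#' @exportMethod show
setMethod("show", "SweepTrace", function(object) {
  cat(sprintf("SweepTrace: %d samples @ %.0f Hz, %s = %g, stimulus [%d, %d]\n",
              length(object@time), samplingRate(object),
              object@stimulusType, object@stimulusValue,
              object@onset, object@offset))
})

setMethod("show", "CircleFit", function(object) {
  cat(sprintf(
    "CircleFit: r = %.2f px (%.4f um), centre (h = %.2f, cy = %.2f), sigma_r/r = %.3f (%d columns)\n",
    object@rPx, object@rUm, object@h, object@cy, object@relSd,
    object@nColumns))
})

setMethod("show", "BoltzmannParams", function(object) {
  unit <- if (object@stimulusType == "tension") c("mN/m", "m/mN")
          else c("mmHg", "/mmHg")
  cat(sprintf("BoltzmannParams (%s): A = %.4g, x50 = %.4g %s, k = %.4g %s%s\n",
              object@stimulusType, object@A, object@x50, unit[1],
              object@k, unit[2],
              if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "PatchRecord", function(object) {
  cat(sprintf("PatchRecord '%s'%s: %d sweeps, %d dome observations\n",
              object@patchId,
              if (is.na(object@construct)) "" else
                paste0(" (", object@construct, ")"),
              length(object@sweeps), nrow(object@domes)))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth with fields:", paste(names(object@params),
                                        collapse = ", "), "\n")
})
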