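#' Sampling rate of a sweep
#' @param x a \linkS4class{SweepTrace}.
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
setMethod("samplingRate", "SweepTrace", function(x) {
  1 / (x@time[2] - x@time[1])
})

#' Stimulus value of a sweep
#' @param x a \linkS4class{SweepTrace}.
#' @return The stimulus applied during the sweep (mmHg, mV or um).
#' @export
setGeneric("stimulusValue", function(x) standardGeneric("stimulusValue"))

#' @rdname stimulusValue
setMethod("stimulusValue", "SweepTrace", function(x) x@stimulusValue)

#' Current trace of a sweep
#' @param x a \linkS4class{SweepTrace}.
#' @return Numeric vector of currents (pA).
#' @export
setGeneric("currentTrace", function(x) standardGeneric("currentTrace"))

#' @rdname currentTrace
setMethod("currentTrace", "SweepTrace", function(x) x@current)

#' Dome radius in micrometres
#' @param x a \linkS4class{CircleFit}.
#' @return Radius in um.
#' @export
setGeneric("radiusUm", function(x) standardGeneric("radiusUm"))

#' @rdname radiusUm
setMethod("radiusUm", "CircleFit", function(x) x@rUm)

#' Relative standard deviation of the fitted radius
#' @param x a \linkS4class{CircleFit}.
#' @return \code{sigma_r / r}, dimensionless.
#' @export
setGeneric("relSd", function(x) standardGeneric("relSd"))

#' @rdname relSd
setMethod("relSd", "CircleFit", function(x) x@relSd)

#' Plateau amplitude of a Boltzmann fit
#' @param x a \linkS4class{BoltzmannParams}.
#' @return Plateau amplitude A.
#' @export
setGeneric("plateau", function(x) standardGeneric("plateau"))

#' @rdname plateau
setMethod("plateau", "BoltzmannParams", function(x) x@A)

#' Slope of a Boltzmann fit
#' @param x a \linkS4class{BoltzmannParams}.
#' @return Slope k (per mmHg or m/mN).
#' @export
setGeneric("slopeK", function(x) standardGeneric("slopeK"))

#' @rdname slopeK
setMethod("slopeK", "BoltzmannParams", function(x) x@k)

#' Half-maximal stimulus of a Boltzmann fit
#' @param x a \linkS4class{BoltzmannParams}.
#' @return x50 (P50 in mmHg or T50 in mN/m, magnitude convention).
#' @export
setGeneric("halfMax", function(x) standardGeneric("halfMax"))

#' @rdname halfMax
setMethod("halfMax", "BoltzmannParams", function(x) x@x50)

#' Ground-truth parameters of a synthetic object
#' @param x a \linkS4class{GroundTruth}.
#' @return Named list of generated parameters.
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))

#' @rdname truthParams
setMethod("truthParams", "GroundTruth", function(x) x@params)

#' Serialise / restore ground truth
#'
#' \code{truthToJSON} writes the parameter list as JSON;
#' \code{truthFromJSON} restores it. The round trip is lossless for
#' numeric, integer, character and logical parameters.
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return \code{truthToJSON}: a JSON string; \code{truthFromJSON}: a
#'   \linkS4class{GroundTruth}.
#' @export
truthToJSON <- function(x) {
  jsonlite::toJSON(truthParams(x), auto_unbox = TRUE, digits = I(17))
}

#' @rdname truthToJSON
#' @param json a JSON string produced by \code{truthToJSON}.
#' @export
truthFromJSON <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  p <- lapply(p, function(v) {
    if (is.character(v)) v[v == "NA"] <- NA
    v
  })
  do.call(GroundTruth, p)
}
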