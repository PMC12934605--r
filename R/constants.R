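## Physical constants and default analysis thresholds, collected in one
## place so every unit conversion in the package is auditable.

#' Unit constants and default thresholds
#'
#' All unit conversions and QC thresholds used by the pipeline.
#' \describe{
#'   \item{PA_PER_MMHG}{133.322 Pa per mmHg.}
#'   \item{KB}{Boltzmann constant, 1.380649e-23 J/K.}
#'   \item{T_ABS}{Absolute temperature used for thermodynamics, 300 K.}
#'   \item{PEAK_INCLUSION_PA}{Minimum maximal peak current for a patch to
#'     enter tension-response analysis (20 pA, inclusive).}
#'   \item{RESPONSIVENESS_PA}{Indentation responsiveness threshold
#'     (10 pA, strict).}
#'   \item{QC_REL_SD}{Maximum sigma_r/r for an image to pass QC (0.10).}
#'   \item{RUNDOWN_FRACTION}{A peak below this fraction of the running
#'     maximum is flagged as rundown (0.7, i.e. a >30\% drop).}
#' }
#' @export
ptConstants <- list(
  PA_PER_MMHG = 133.322,
  KB = 1.380649e-23,
  T_ABS = 300,
  PEAK_INCLUSION_PA = 20,
  RESPONSIVENESS_PA = 10,
  QC_REL_SD = 0.10,
  RUNDOWN_FRACTION = 0.7
)

## Boltzmann (3-parameter logistic) response; x magnitude convention.
boltzmann <- function(x, A, k, x50) A / (1 + exp(-k * (x - x50)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
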