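## Tension-tuning curves and gating thermodynamics.
##
## The tuning curve is the first derivative of the tension-response
## Boltzmann: its peak (A k / 4 at T50) marks the tension of maximal
## incremental sensitivity and its width the dynamic range. Gating
## thermodynamics follow from the fitted parameters alone:
## deltaG = kB Tabs T50 k (reported in kB Tabs units, so numerically
## T50 * k) and deltaA = k kB Tabs (reported in nm^2).

#' Tension-tuning curve (derivative of the Boltzmann)
#'
#' Evaluates \code{y(T) = A k e^{-k (T - T50)} / (1 + e^{-k (T - T50)})^2}
#' on a tension grid and reports the peak location and height. The peak
#' equals \code{A k / 4} at \code{T = T50}; the full width at half maximum
#' is \code{2 ln(3 + 2 sqrt(2)) / k}.
#'
#' @param params a \linkS4class{BoltzmannParams} (tension fit).
#' @param grid numeric vector of tensions (mN/m); default spans
#'   T50 +/- 12/k.
#' @return list: \code{tension}, \code{y} (per mN/m),
#'   \code{peakLocation}, \code{peakHeight}.
#' @export
tuningCurve <- function(params, grid = NULL) {
  A <- plateau(params); k <- slopeK(params); t50 <- halfMax(params)
  if (is.null(grid))
    grid <- seq(t50 - 12 / k, t50 + 12 / k, length.out = 481L)
  e <- exp(-k * (grid - t50))
  y <- A * k * e / (1 + e)^2
  list(tension = grid, y = y, peakLocation = t50, peakHeight = A * k / 4)
}

#' Gibbs free energy of gating
#'
#' \code{deltaG = kB Tabs T50 k}, reported in units of \code{kB Tabs}:
#' with T50 in mN/m and k in m/mN the product is dimensionless and equals
#' deltaG directly.
#'
#' @param T50_mN_per_m tension of half-maximal activation (mN/m).
#' @param k_m_per_mN Boltzmann slope (m/mN).
#' @return deltaG in kB.Tabs units.
#' @examples
#' gibbsEnergy(3.7, 1.2)  # 4.44 kB.T
#' @export
gibbsEnergy <- function(T50_mN_per_m, k_m_per_mN) {
  if (any(T50_mN_per_m < 0) || any(k_m_per_mN < 0))
    stopf("T50 and k must be non-negative")
  T50_mN_per_m * k_m_per_mN
}

#' In-plane area expansion upon channel opening
#'
#' \code{deltaA = k kB Tabs}: the slope k (m/mN = 1e3 m/N) times the
#' thermal energy at \code{Tabs} (default 300 K), expressed in nm^2.
#'
#' @param k_m_per_mN Boltzmann slope (m/mN).
#' @param Tabs absolute temperature (K).
#' @return deltaA in nm^2.
#' @examples
#' areaExpansion(1.2)  # ~4.97 nm^2
#' @export
areaExpansion <- function(k_m_per_mN, Tabs = ptConstants$T_ABS) {
  if (any(k_m_per_mN < 0)) stopf("k must be non-negative")
  k_m_per_mN * 1e3 * ptConstants$KB * Tabs * 1e18
}

#' Per-patch thermodynamics table
#'
#' Computes deltaG and deltaA patch-wise from per-patch (T50, k) and
#' returns both the per-patch values and their mean. Averaging patch-wise
#' products differs from the product of the mean T50 and mean k; both
#' conventions are reported.
#'
#' @param t50 numeric vector of per-patch T50 (mN/m).
#' @param k numeric vector of per-patch k (m/mN).
#' @param Tabs absolute temperature (K).
#' @return list: \code{perPatch} (data.frame \code{T50}, \code{k},
#'   \code{deltaG_kBT}, \code{deltaA_nm2}), \code{meanOfPatches},
#'   \code{productOfMeans}.
#' @export
thermodynamics <- function(t50, k, Tabs = ptConstants$T_ABS) {
  stopifnot(length(t50) == length(k))
  per <- data.frame(T50 = t50, k = k,
                    deltaG_kBT = gibbsEnergy(t50, k),
                    deltaA_nm2 = areaExpansion(k, Tabs))
  list(perPatch = per,
       meanOfPatches = c(deltaG_kBT = mean(per$deltaG_kBT),
                         deltaA_nm2 = mean(per$deltaA_nm2)),
       productOfMeans = c(deltaG_kBT = gibbsEnergy(mean(t50), mean(k)),
                          deltaA_nm2 = areaExpansion(mean(k), Tabs)))
}
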