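## Synthetic data with known ground truth.
##
## Every generator mirrors one acquisition mode of the combined
## pressure-clamp + DIC experiment: dome micrographs (a dark arc with a
## Gaussian cross-section over a brighter background), pressure-step sweep
## sets with Boltzmann-gated peak currents and patch-to-patch (T50, k, A)
## variability, voltage-step telegraph sweeps for single-channel analysis,
## and indentation series with a depth threshold and exponential decay.
## Each returns a GroundTruth recording every parameter used, so the
## analysis stages can be scored by parameter recovery; estimation code
## never reads the ground truth.
##
## All generators call set.seed with the supplied seed: identical spec and
## seed give bit-identical output.

#' Specification for rendering a synthetic dome micrograph
#'
#' @param radius_um dome radius of curvature (um); must be at least
#'   \code{pipette_half_width_um} (a dome cannot be more curved than a
#'   hemisphere spanning the pipette).
#' @param pipette_half_width_um half the pipette lumen width (um); the
#'   rendered arc is clipped to this span.
#' @param band_depth intensity drop of the dome band (arbitrary units).
#' @param band_sigma_px Gaussian cross-section width of the band (pixels).
#' @param noise_sigma additive Gaussian pixel noise SD.
#' @param pixel_size_um micrometres per pixel (0.0325 matches 2x2-binned
#'   acquisition at 100x with a 4x relay).
#' @param image_shape integer(2), rows x cols.
#' @param seed integer RNG seed.
#' @return A validated \code{DomeRenderSpec} (list).
#' @export
domeRenderSpec <- function(radius_um, pipette_half_width_um = 0.9,
                           band_depth = 60, band_sigma_px = 2,
                           noise_sigma = 0, pixel_size_um = 0.0325,
                           image_shape = c(120L, 160L), seed = 1L) {
  if (radius_um <= 0 || pipette_half_width_um <= 0)
    stopf("radius and pipette half-width must be positive")
  if (radius_um < pipette_half_width_um)
    stopf("radius %.3g um < pipette half-width %.3g um: dome cannot be more curved than a hemisphere",
          radius_um, pipette_half_width_um)
  if (band_sigma_px <= 0) stopf("band_sigma_px must be positive")
  if (band_depth <= 0) stopf("band_depth must be positive")
  list(radius_um = radius_um,
       pipette_half_width_um = pipette_half_width_um,
       band_depth = band_depth, band_sigma_px = band_sigma_px,
       noise_sigma = noise_sigma, pixel_size_um = pixel_size_um,
       image_shape = as.integer(image_shape), seed = as.integer(seed))
}

#' Render a synthetic dome micrograph
#'
#' Draws a dark circular arc (apex toward smaller row indices) whose
#' cross-section perpendicular to the arc is an inverted Gaussian of
#' width \code{band_sigma_px} and depth \code{band_depth} over a brighter
#' uniform background, clipped to the pipette walls, with additive
#' Gaussian noise. Each column's profile is a Gaussian centred exactly on
#' the circle with its width scaled by the local arc slope, i.e. the
#' noiseless image realises the column-Gaussian + circle model the
#' estimator fits. The returned ROI covers the band with the margins the
#' column scan needs (in a real experiment the ROI is drawn manually; the
#' generator supplies it as that explicit input).
#'
#' @param spec a \code{\link{domeRenderSpec}}.
#' @return list: \code{image} (matrix), \code{roi}
#'   (\code{\link{regionOfInterest}}), \code{truth}
#'   (\linkS4class{GroundTruth}: \code{radius_um}, \code{r_px},
#'   \code{h}, \code{cy}).
#' @export
genDomeImage <- function(spec) {
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  rPx <- spec$radius_um / spec$pixel_size_um
  hwPx <- spec$pipette_half_width_um / spec$pixel_size_um
  h <- (nc - 1) / 2 + 0.37          # deliberately off-grid centre
  sag <- rPx - sqrt(rPx^2 - hwPx^2) # apex-to-edge drop, rows
  apexRow <- 30
  cy <- apexRow + rPx
  if (apexRow - 15 < 0 || apexRow + sag + 15 > nr - 1 ||
      h - hwPx < 1 || h + hwPx > nc - 2)
    stopf("rendered arc (r = %.1f px, half-width %.1f px, sag %.1f px) does not fit image %d x %d",
          rPx, hwPx, sag, nr, nc)
  bg <- 200
  img <- matrix(bg, nr, nc)
  cols <- 0:(nc - 1); rows <- 0:(nr - 1)
  inPipe <- abs(cols - h) <= hwPx
  ## Per column: inverted Gaussian centred exactly on the circle, width
  ## scaled by the local arc slope (1/cos of the tangent angle) so the
  ## cross-section perpendicular to the arc has width band_sigma_px.
  for (ci in which(inPipe)) {
    halfChord <- sqrt(rPx^2 - (cols[ci] - h)^2)
    arcRow <- cy - halfChord
    wcol <- spec$band_sigma_px * rPx / max(halfChord, 1e-9)
    upper <- rows <= cy
    img[, ci] <- img[, ci] - ifelse(upper,
      spec$band_depth * exp(-0.5 * ((rows - arcRow) / wcol)^2), 0)
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
  roi <- regionOfInterest(
    rowStart = max(0, floor(apexRow - 14)),
    rowEnd = min(nr, ceiling(apexRow + sag + 15)),
    colStart = ceiling(h - hwPx) + 1L,
    colEnd = floor(h + hwPx))
  if (roi$rowEnd - roi$rowStart < 25L) roi$rowEnd <- roi$rowStart + 25L
  list(image = img, roi = roi,
       truth = GroundTruth(radius_um = spec$radius_um, r_px = rPx,
                           h = h, cy = cy, apexRow = apexRow,
                           band_depth = spec$band_depth,
                           band_sigma_px = spec$band_sigma_px,
                           seed = spec$seed))
}

#' Specification for a synthetic stretch-protocol cohort
#'
#' Defaults describe the study conditions the pipeline targets: a
#' pressure-step protocol from 0 to -80 mmHg (delta -5 mmHg, 300 ms) on
#' patches whose tension sensitivity varies around T50 = 3.7 mN/m,
#' k = 1.2 m/mN (patch-to-patch SDs consistent with SEMs of 0.2 and 0.1
#' at n ~ 17), plateau currents around 100 pA, a dome radius shrinking
#' with suction as r(P) = r_min (1 + P_half/|P|), and occasional rundown.
#'
#' @param n_patches cohort size.
#' @param T50_mean,T50_sd per-patch T50 distribution (mN/m).
#' @param k_mean,k_sd per-patch slope distribution (m/mN).
#' @param A_mean,A_sd per-patch plateau current distribution (pA).
#' @param r_min_um saturating dome radius at high suction (um).
#' @param P_half_mmHg pressure scale of the radius law (mmHg).
#' @param radius_rel_noise multiplicative log-normal radius noise SD.
#' @param current_noise_sigma additive peak/current noise SD (pA).
#' @param rundown_prob probability a patch exhibits rundown.
#' @param tau_ms_mean,tau_ms_sd per-patch inactivation tau (ms).
#' @param seed integer RNG seed.
#' @return A validated \code{StretchCohortSpec} (list).
#' @export
stretchCohortSpec <- function(n_patches = 20L, T50_mean = 3.7,
                              T50_sd = 0.8, k_mean = 1.2, k_sd = 0.4,
                              A_mean = 100, A_sd = 40,
                              r_min_um = 1.33, P_half_mmHg = 10,
                              radius_rel_noise = 0.02,
                              current_noise_sigma = 2,
                              rundown_prob = 0.1,
                              tau_ms_mean = 40, tau_ms_sd = 10,
                              seed = 1L) {
  if (any(c(T50_mean, k_mean, A_mean, r_min_um, P_half_mmHg,
            tau_ms_mean) <= 0))
    stopf("all means must be positive")
  if (any(c(T50_sd, k_sd, A_sd, radius_rel_noise, current_noise_sigma,
            tau_ms_sd) < 0))
    stopf("all SDs must be non-negative")
  if (rundown_prob < 0 || rundown_prob > 1)
    stopf("rundown_prob must lie in [0, 1]")
  as.list(environment())
}

## Radius-vs-pressure law: monotone shrinking toward r_min, diverging
## (flat membrane) at P = 0. A flat membrane is represented by a large
## finite radius so tension at P = 0 is exactly 0 anyway (|P| = 0).
radiusOfPressure <- function(pressure_mmHg, r_min_um, P_half_mmHg,
                             flat_um = 50) {
  ifelse(pressure_mmHg == 0, flat_um,
         r_min_um * (1 + P_half_mmHg / abs(pressure_mmHg)))
}

#' Generate one synthetic stretch patch
#'
#' Seventeen pressure steps (0 to -80 mmHg, delta -5 mmHg): per sweep the
#' dome radius follows the r(P) law with small multiplicative noise,
#' tension follows Laplace's law, and the peak current follows the
#' patch's Boltzmann (A, k, T50) with additive Gaussian noise. With
#' probability \code{rundown_prob} the patch runs down: from a random
#' later sweep onward amplitudes are halved (a >30\% drop, so the
#' rundown filter must catch it). With \code{traces = TRUE} full
#' 10 kHz sweeps (100 ms baseline, 300 ms step, exponential decay from
#' the peak) are built; otherwise only the peak table is generated,
#' which is the level at which cohort-scale recovery experiments operate.
#'
#' @param spec a \code{\link{stretchCohortSpec}}.
#' @param patchIndex index of the patch within the cohort (determines its
#'   sub-seed, so patches are independent but reproducible).
#' @param traces build full \linkS4class{SweepTrace} objects?
#' @return list: \code{patch} (\linkS4class{PatchRecord}; its
#'   \code{peaks} table is pre-filled when \code{traces = FALSE}),
#'   \code{peaks} (data.frame \code{pressure_mmHg}, \code{tension},
#'   \code{Ip}), \code{truth} (\linkS4class{GroundTruth}).
#' @export
genStretchPatch <- function(spec, patchIndex = 1L, traces = FALSE) {
  set.seed(spec$seed + 7919L * as.integer(patchIndex))
  rpos <- function(m, s) max(m + stats::rnorm(1, 0, s), 0.05 * m)
  T50 <- rpos(spec$T50_mean, spec$T50_sd)
  k <- rpos(spec$k_mean, spec$k_sd)
  A <- rpos(spec$A_mean, spec$A_sd)
  tau <- rpos(spec$tau_ms_mean, spec$tau_ms_sd)
  pressures <- seq(0, -80, by = -5)
  nswp <- length(pressures)
  r <- radiusOfPressure(pressures, spec$r_min_um, spec$P_half_mmHg) *
    exp(stats::rnorm(nswp, 0, spec$radius_rel_noise))
  tension <- computeTension(pressures, r)$tension_mN_per_m
  amp <- boltzmann(tension, A, k, T50)
  hasRundown <- stats::runif(1) < spec$rundown_prob
  rdFrom <- NA_integer_
  if (hasRundown) {
    ## onset restricted to the plateau region (previous peak >= 0.73 A,
    ## i.e. tension >= T50 + 1/k): there a x0.5 drop is guaranteed to
    ## violate the 70%-of-running-maximum rule, so the filter must fire
    eligible <- which(c(-Inf, tension[-nswp]) >= T50 + 1 / k)
    if (!length(eligible)) eligible <- nswp - 2L
    rdFrom <- if (length(eligible) > 1L) sample(eligible, 1) else eligible
    amp[rdFrom:nswp] <- amp[rdFrom:nswp] * 0.5
  }
  peakNoise <- stats::rnorm(nswp, 0, spec$current_noise_sigma)
  ip <- pmax(amp + peakNoise, 0)
  domes <- data.frame(pressure_mmHg = pressures, r_um = r,
                      sigma_r = 0.02 * r / 0.0325, rel_sd = 0.02,
                      qc_keep = TRUE)
  meta <- list(seal_GOhm = 2, leak_pA = 10, holding_mV = -80)
  sweeps <- list()
  if (traces) {
    rate <- 1e4; pre <- 0.1; stepDur <- 0.3; total <- 0.45
    tgrid <- seq(0, total - 1 / rate, by = 1 / rate)
    onset <- as.integer(pre * rate) + 1L
    offset <- as.integer((pre + stepDur) * rate)
    sweeps <- lapply(seq_len(nswp), function(i) {
      cur <- rep(-3, length(tgrid))   # holding/leak offset
      idx <- onset:offset
      tms <- (tgrid[idx] - tgrid[onset]) * 1e3
      cur[idx] <- cur[idx] - amp[i] * exp(-tms / tau)
      cur <- cur + stats::rnorm(length(cur), 0, spec$current_noise_sigma)
      SweepTrace(tgrid, cur, pressures[i], "pressure", onset, offset)
    })
  }
  patch <- PatchRecord(sprintf("sim-%03d", patchIndex), sweeps,
                       domes = domes, metadata = meta,
                       construct = "synthetic")
  if (!traces)
    patch@peaks <- data.frame(sweep = seq_len(nswp),
                              stimulus = pressures, Ip = ip)
  list(patch = patch,
       peaks = data.frame(pressure_mmHg = pressures, r_um = r,
                          tension = tension, Ip = ip),
       truth = GroundTruth(T50 = T50, k = k, A = A, tau_ms = tau,
                           rundown = hasRundown, rundownFrom = rdFrom,
                           r_min_um = spec$r_min_um,
                           P_half_mmHg = spec$P_half_mmHg,
                           patchIndex = as.integer(patchIndex)))
}

#' Generate a synthetic stretch cohort
#'
#' @param spec a \code{\link{stretchCohortSpec}}.
#' @param traces build full sweeps (see \code{\link{genStretchPatch}})?
#' @return list of per-patch results from \code{\link{genStretchPatch}}.
#' @export
genStretchCohort <- function(spec, traces = FALSE) {
  lapply(seq_len(spec$n_patches), function(i)
    genStretchPatch(spec, i, traces = traces))
}

#' Generate single-channel voltage-step sweeps
#'
#' Telegraph (two-state Markov) current alternating between a closed
#' baseline at 0 pA and an open level of \code{g V + b} at each voltage,
#' with additive Gaussian noise. The ground truth records the true state
#' sequence and a set of isolated opening-event windows (each opening
#' plus flanking baseline) standing in for the manual event isolation of
#' a real analysis.
#'
#' @param g_pS slope conductance (> 0).
#' @param b_pA I-V intercept (pA).
#' @param voltages_mV at least two holding voltages.
#' @param open_prob stationary open probability, in (0, 1).
#' @param noise_sigma current noise SD (pA).
#' @param seed integer RNG seed.
#' @param duration_s sweep duration (s).
#' @param rate_Hz sampling rate.
#' @return list: \code{sweeps} (list of \linkS4class{SweepTrace}),
#'   \code{eventRanges} (per-voltage list of index ranges),
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
genSingleChannel <- function(g_pS, b_pA = 0, voltages_mV = c(-60, -80, -100),
                             open_prob = 0.3, noise_sigma = 0.2,
                             seed = 1L, duration_s = 1, rate_Hz = 1e4) {
  if (g_pS <= 0) stopf("conductance must be positive")
  if (length(voltages_mV) < 2L) stopf("need >= 2 voltages")
  if (open_prob <= 0 || open_prob >= 1)
    stopf("open_prob must lie strictly in (0, 1)")
  set.seed(seed)
  n <- as.integer(duration_s * rate_Hz)
  tgrid <- seq(0, duration_s - 1 / rate_Hz, by = 1 / rate_Hz)
  meanOpen <- 100                       # samples (10 ms at 10 kHz)
  pClose <- 1 / meanOpen
  pOpen <- pClose * open_prob / (1 - open_prob)
  out <- lapply(voltages_mV, function(V) {
    state <- integer(n)
    s <- 0L
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      s <- if (s == 1L) { if (u[i] < pClose) 0L else 1L }
           else { if (u[i] < pOpen) 1L else 0L }
      state[i] <- s
    }
    level <- g_pS * 1e-3 * V + b_pA
    cur <- state * level + stats::rnorm(n, 0, noise_sigma)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    op <- which(r$values == 1L & r$lengths >= 20L)
    margin <- 50L
    ranges <- lapply(utils::head(op, 5L), function(j)
      c(max(1L, starts[j] - margin), min(n, ends[j] + margin)))
    list(trace = SweepTrace(tgrid, cur, V, "voltage", 2L, n),
         state = state, ranges = ranges)
  })
  list(sweeps = lapply(out, `[[`, "trace"),
       eventRanges = lapply(out, `[[`, "ranges"),
       truth = GroundTruth(g_pS = g_pS, b_pA = b_pA,
                           voltages_mV = voltages_mV,
                           open_prob = open_prob,
                           noise_sigma = noise_sigma, seed = seed,
                           nEvents = vapply(out, function(o)
                             length(o$ranges), integer(1))))
}

#' Generate a whole-cell indentation series
#'
#' Protocol of 1 um indentation steps (500 ms each); sweeps before the
#' contact step carry no evoked current, and from the threshold depth on
#' the peak grows linearly with depth and decays with a single
#' exponential.
#'
#' @param contact_index protocol step at which the probe first touches
#'   the cell.
#' @param threshold_depth_um minimal post-contact depth evoking current
#'   (>= 1).
#' @param amp_slope_pA_per_um peak growth per um above threshold.
#' @param tau_ms decay time constant.
#' @param noise_sigma current noise SD (pA).
#' @param seed integer RNG seed.
#' @param n_steps total protocol steps (protocol runs until rupture;
#'   truncation is encoded here).
#' @param rate_Hz sampling rate.
#' @return list: \code{sweeps}, \code{contactIndex}, \code{truth}.
#' @export
genIndentationSeries <- function(contact_index = 1L, threshold_depth_um = 4,
                                 amp_slope_pA_per_um = 25, tau_ms = 40,
                                 noise_sigma = 1, seed = 1L,
                                 n_steps = 10L, rate_Hz = 1e4) {
  if (threshold_depth_um < 1) stopf("threshold depth must be >= 1 um")
  set.seed(seed)
  pre <- 0.05; stepDur <- 0.5; total <- 0.6
  tgrid <- seq(0, total - 1 / rate_Hz, by = 1 / rate_Hz)
  onset <- as.integer(pre * rate_Hz) + 1L
  offset <- as.integer((pre + stepDur) * rate_Hz)
  sweeps <- lapply(seq_len(n_steps), function(i) {
    depth <- i - contact_index
    amp <- if (depth >= threshold_depth_um)
      amp_slope_pA_per_um * (depth - threshold_depth_um + 1) else 0
    cur <- rep(-2, length(tgrid))
    if (amp > 0) {
      idx <- onset:offset
      tms <- (tgrid[idx] - tgrid[onset]) * 1e3
      cur[idx] <- cur[idx] - amp * exp(-tms / tau_ms)
    }
    cur <- cur + stats::rnorm(length(cur), 0, noise_sigma)
    SweepTrace(tgrid, cur, depth, "depth", onset, offset)
  })
  list(sweeps = sweeps, contactIndex = as.integer(contact_index),
       truth = GroundTruth(contact_index = as.integer(contact_index),
                           threshold_depth_um = threshold_depth_um,
                           amp_slope_pA_per_um = amp_slope_pA_per_um,
                           tau_ms = tau_ms, noise_sigma = noise_sigma,
                           seed = seed, n_steps = as.integer(n_steps)))
}
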