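## Dome curvature from DIC micrographs.
##
## The membrane dome appears as a dark band inside the patch pipette. Its
## radius of curvature is estimated in three stages: (1) per image column,
## locate the darkest 5-pixel segment and extract a 25-pixel window around
## it; (2) fit an inverted Gaussian (with baseline offset) to each window
## for a sub-pixel band centre and its width; (3) fit a half-circle to the
## (column, centre) points weighted by 1/sigma1^2. Tension then follows
## from Laplace's law, T = |P| r / 2.
##
## Pixel coordinates are 0-based throughout the public interface; ROI
## bounds are half-open.

#' Define a region of interest on a micrograph
#'
#' Bounds are 0-based, half-open pixel indices (\code{rowStart} included,
#' \code{rowEnd} excluded), matching how the ROI would be read off an image
#' viewer. Columns that are visibly not part of the membrane dome (pipette
#' wall reflections, debris) are listed in \code{excludedColumns} and
#' skipped by the band scan.
#'
#' @param rowStart,rowEnd,colStart,colEnd 0-based half-open bounds.
#' @param excludedColumns integer vector of 0-based column indices to skip.
#' @return A \code{RegionOfInterest} (list with class attribute).
#' @export
regionOfInterest <- function(rowStart, rowEnd, colStart, colEnd,
                             excludedColumns = integer()) {
  if (rowEnd <= rowStart || colEnd <= colStart)
    stopf("ROI bounds must be non-empty (half-open)")
  structure(list(rowStart = as.integer(rowStart),
                 rowEnd = as.integer(rowEnd),
                 colStart = as.integer(colStart),
                 colEnd = as.integer(colEnd),
                 excludedColumns = as.integer(excludedColumns)),
            class = "RegionOfInterest")
}

checkRoi <- function(image, roi) {
  if (roi$rowStart < 0 || roi$colStart < 0 ||
      roi$rowEnd > nrow(image) || roi$colEnd > ncol(image))
    stopf("ROI [%d,%d) x [%d,%d) outside image %d x %d",
          roi$rowStart, roi$rowEnd, roi$colStart, roi$colEnd,
          nrow(image), ncol(image))
  cols <- setdiff(seq(roi$colStart, roi$colEnd - 1L), roi$excludedColumns)
  if (!length(cols)) stopf("ROI empty after column exclusions")
  cols
}

#' Locate the dome band in each image column
#'
#' For every retained ROI column, computes the mean intensity of all
#' contiguous 5-pixel segments, picks the segment with the lowest mean
#' (ties broken by the lowest row index), and returns the centre pixel of
#' that segment together with the 25-pixel window centred on it. Windows
#' that would leave the ROI are shifted inward so they always hold 25
#' pixels.
#'
#' @param image numeric matrix (rows x cols), larger values brighter.
#' @param roi a \code{\link{regionOfInterest}}; its row span must be at
#'   least 25 pixels.
#' @return data.frame with 0-based columns \code{col}, \code{center},
#'   \code{winStart}, \code{winEnd} (inclusive).
#' @export
columnBandScan <- function(image, roi) {
  cols <- checkRoi(image, roi)
  nr <- roi$rowEnd - roi$rowStart
  if (nr < 25L) stopf("ROI height %d < 25 pixels", nr)
  rows1 <- (roi$rowStart + 1L):roi$rowEnd   # 1-based matrix rows
  out <- lapply(cols, function(cc) {
    v <- image[rows1, cc + 1L]
    seg <- stats::filter(v, rep(1 / 5, 5), sides = 2)  # centred 5-mean
    seg <- seg[3:(nr - 2)]                             # valid centres
    ctr <- which.min(seg) + 2L                         # 1-based within ROI
    ws <- min(max(ctr - 12L, 1L), nr - 24L)
    data.frame(col = cc,
               center = roi$rowStart + ctr - 1L,
               winStart = roi$rowStart + ws - 1L,
               winEnd = roi$rowStart + ws + 23L)
  })
  do.call(rbind, out)
}

#' Fit an inverted Gaussian to one column window
#'
#' Least-squares fit of \code{y = b + a exp(-((x - c1)/sigma1)^2 / 2)} to
#' the 25 window intensities, with \code{a} negative for the dark band.
#' The reported amplitude \code{A1 = a sigma1 sqrt(2 pi)} follows the
#' scaled-density parameterisation; \code{c1} is the sub-pixel band centre
#' and \code{sigma1} its width, used downstream as the localisation
#' uncertainty. A baseline offset is included so a dark band on a bright
#' background is representable.
#'
#' @param intensities numeric(25) window intensities.
#' @param rows numeric(25) row coordinates of the window pixels.
#' @return list with \code{A1}, \code{c1}, \code{sigma1}, \code{offset},
#'   \code{depth} (the signed peak deviation \code{a}) and \code{valid};
#'   \code{valid = FALSE} when the fit fails to converge or
#'   \code{sigma1} exceeds the window width.
#' @export
fitColumnGaussian <- function(intensities, rows) {
  stopifnot(length(intensities) == 25L, length(rows) == 25L)
  if (!all(is.finite(intensities))) stopf("non-finite window intensities")
  b0 <- stats::median(intensities)
  i0 <- which.min(intensities)
  a0 <- intensities[i0] - b0
  if (a0 == 0) a0 <- -1e-6 * max(abs(intensities), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-0.5 * ((x - c1) / s)^2),
      data = data.frame(x = rows, y = intensities),
      start = list(b = b0, a = a0, c1 = rows[i0], s = 2),
      lower = c(-Inf, -Inf, min(rows), 0.5),
      upper = c(Inf, Inf, max(rows), 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A1 = NA_real_, c1 = NA_real_, sigma1 = NA_real_,
                offset = NA_real_, depth = NA_real_, valid = FALSE))
  p <- stats::coef(fit)
  rsd <- sqrt(mean(stats::residuals(fit)^2))
  ## a one-pixel noise spike can masquerade as a band: require a width
  ## away from the lower bound and a depth well above the residual noise
  valid <- is.finite(p[["c1"]]) && p[["s"]] > 0.55 && p[["s"]] <= 25 &&
    p[["c1"]] >= min(rows) && p[["c1"]] <= max(rows) && p[["a"]] < 0 &&
    abs(p[["a"]]) > 3 * rsd
  list(A1 = unname(p[["a"]] * p[["s"]] * sqrt(2 * pi)),
       c1 = unname(p[["c1"]]), sigma1 = unname(p[["s"]]),
       offset = unname(p[["b"]]), depth = unname(p[["a"]]),
       valid = valid)
}

## Unweighted algebraic (Kasa) circle fit: linear least squares on
## x^2 + y^2 = 2 a x + 2 b y + c. Used only to initialise the geometric fit.
kasaCircle <- function(x, y) {
  d <- x^2 + y^2
  fit <- stats::lm(d ~ x + y)
  a <- stats::coef(fit)[["x"]] / 2
  b <- stats::coef(fit)[["y"]] / 2
  r2 <- stats::coef(fit)[["(Intercept)"]] + a^2 + b^2
  list(h = a, cy = b, r = if (r2 > 0) sqrt(r2) else NA_real_)
}

#' Weighted circular fit to band centres
#'
#' Fits the half-circle \code{row = cy -/+ sqrt(r^2 - (col - h)^2)} to the
#' sub-pixel band centres by weighted nonlinear least squares, with weights
#' \code{1/sigma1^2} per column. The sign follows the dome orientation:
#' with \code{apex = "up"} (default) the dome apex points toward smaller
#' row indices (toward the pipette tip). Initialised from an unweighted
#' algebraic circle fit. \code{sigmaR} is taken from the fit covariance.
#'
#' @param bands data.frame with columns \code{col}, \code{c1},
#'   \code{sigma1} (from \code{\link{fitColumnGaussian}}); rows with
#'   non-finite entries are dropped.
#' @param pixelSizeUm pixel size in micrometres per pixel.
#' @param apex \code{"up"} or \code{"down"}: direction the dome apex
#'   points along the row axis.
#' @return A \linkS4class{CircleFit}.
#' @export
fitCircleWeighted <- function(bands, pixelSizeUm, apex = c("up", "down")) {
  apex <- match.arg(apex)
  keep <- is.finite(bands$col) & is.finite(bands$c1) &
    is.finite(bands$sigma1) & bands$sigma1 > 0
  bands <- bands[keep, , drop = FALSE]
  if (nrow(bands) < 3L)
    stopf("circle fit needs >= 3 valid columns, have %d", nrow(bands))
  x <- bands$col
  ## flip rows so the arc is always the upper half (y = cy + sqrt(...))
  y <- if (apex == "up") -bands$c1 else bands$c1
  w <- 1 / pmax(bands$sigma1, 0.5)^2   # floor: sub-half-pixel widths are
                                       # optically implausible, cap weight
  if (stats::sd(y) < 1e-12 || stats::sd(x) < 1e-12)
    stopf("degenerate band geometry: points are collinear")
  runFit <- function(x, y, w) {
    init <- kasaCircle(x, y)
    if (!is.finite(init$r) || init$r <= 0)
      stopf("circle fit failed: collinear or degenerate points")
    dat <- data.frame(x = x, y = y, w = w)
    minpack.lm::nlsLM(
      y ~ cy + sqrt(pmax(r^2 - (x - h)^2, 1e-12)),
      data = dat, weights = w,
      start = list(h = init$h, cy = init$cy - init$r * 1e-6, r = init$r),
      lower = c(-Inf, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fit <- tryCatch(runFit(x, y, w), error = function(e) NULL)
  ## one robust pass: drop gross outlier columns (the automated analogue
  ## of the visual-inspection discard) and refit
  if (!is.null(fit)) {
    res <- abs(stats::residuals(fit))
    scale <- stats::median(res) + 1e-9
    keepPts <- res <= 6 * scale
    if (sum(keepPts) >= 3L && any(!keepPts))
      fit <- tryCatch(runFit(x[keepPts], y[keepPts], w[keepPts]),
                      error = function(e) fit)
  }
  if (is.null(fit)) stopf("weighted circle fit did not converge")
  p <- stats::coef(fit)
  r <- unname(p[["r"]])
  if (!is.finite(r) || r <= 0) stopf("circle fit radius non-finite")
  sigmaR <- tryCatch({
    v <- stats::vcov(fit)
    s <- sqrt(diag(v))[["r"]]
    if (is.finite(s)) s else 0
  }, error = function(e) 0)
  cy <- unname(p[["cy"]])
  new("CircleFit",
      h = unname(p[["h"]]),
      cy = if (apex == "up") -cy else cy,
      rPx = r, rUm = r * pixelSizeUm,
      sigmaR = sigmaR, relSd = sigmaR / r,
      nColumns = nrow(bands))
}

#' Image-level QC on a circle fit
#'
#' An image is discarded when the relative standard deviation of its
#' fitted radius exceeds 10\%, except at 0 mmHg where the membrane is
#' nearly flat and a poorly constrained radius is expected (and unused,
#' since tension is zero there).
#'
#' @param fit a \linkS4class{CircleFit}.
#' @param pressure_mmHg applied pressure for this image.
#' @param maxRelSd QC threshold (default 0.10).
#' @return list with \code{keep} (logical) and \code{reason}.
#' @export
qcCircleFit <- function(fit, pressure_mmHg,
                        maxRelSd = ptConstants$QC_REL_SD) {
  if (relSd(fit) > maxRelSd && pressure_mmHg != 0)
    list(keep = FALSE,
         reason = sprintf("rel_sd %.3f > %.2f at P = %g mmHg",
                          relSd(fit), maxRelSd, pressure_mmHg))
  else list(keep = TRUE, reason = "")
}

#' Patch-level QC from image decisions
#'
#' A patch is excluded when more than two of its images failed
#' \code{\link{qcCircleFit}}.
#'
#' @param decisions list of decisions from \code{\link{qcCircleFit}}, one
#'   per imaged pressure step.
#' @return list with \code{keep}, \code{nDiscarded}.
#' @export
qcPatchImages <- function(decisions) {
  nd <- sum(!vapply(decisions, function(d) isTRUE(d$keep), logical(1)))
  list(keep = nd <= 2L, nDiscarded = nd)
}

#' Membrane tension from Laplace's law
#'
#' \code{T = |P| r / 2}: pressure converted at 133.322 Pa/mmHg, radius in
#' metres, tension reported in mN/m. Suction (negative applied pressure)
#' gives positive tension by the magnitude convention.
#'
#' @param pressure_mmHg applied pressure (signed).
#' @param radius_um dome radius of curvature in micrometres.
#' @return data.frame row: \code{pressure_mmHg}, \code{radius_um},
#'   \code{tension_mN_per_m}.
#' @examples
#' computeTension(-15, 1.0)  # ~1.00 mN/m
#' @export
computeTension <- function(pressure_mmHg, radius_um) {
  if (any(radius_um <= 0)) stopf("radius must be positive")
  tension <- abs(pressure_mmHg) * ptConstants$PA_PER_MMHG *
    radius_um * 1e-6 / 2 * 1e3
  data.frame(pressure_mmHg = pressure_mmHg, radius_um = radius_um,
             tension_mN_per_m = tension)
}

#' Full per-image dome pipeline
#'
#' Runs band scan, per-column Gaussian fits, the weighted circle fit, QC
#' and Laplace conversion on one micrograph, and draws the fitted arc onto
#' a copy of the input for visual inspection.
#'
#' @param image numeric matrix.
#' @param roi a \code{\link{regionOfInterest}}.
#' @param pressure_mmHg applied pressure for this image.
#' @param pixelSizeUm micrometres per pixel.
#' @param apex dome orientation, see \code{\link{fitCircleWeighted}}.
#' @return list: \code{circle} (\linkS4class{CircleFit}), \code{qc},
#'   \code{tension} (data.frame row, or NULL when QC fails),
#'   \code{bands} (per-column localisations), \code{overlay} (matrix with
#'   the fitted arc burnt in).
#' @export
estimateDomeTension <- function(image, roi, pressure_mmHg, pixelSizeUm,
                                apex = "up") {
  scan <- columnBandScan(image, roi)
  bands <- do.call(rbind, lapply(seq_len(nrow(scan)), function(i) {
    rows <- scan$winStart[i]:scan$winEnd[i]
    g <- fitColumnGaussian(image[rows + 1L, scan$col[i] + 1L], rows)
    data.frame(col = scan$col[i], c1 = g$c1, sigma1 = g$sigma1,
               A1 = g$A1, valid = g$valid)
  }))
  ok <- bands$valid
  circle <- fitCircleWeighted(bands[ok, , drop = FALSE], pixelSizeUm,
                              apex = apex)
  qc <- qcCircleFit(circle, pressure_mmHg)
  tension <- if (qc$keep) computeTension(pressure_mmHg, radiusUm(circle))
             else NULL
  list(circle = circle, qc = qc, tension = tension, bands = bands,
       overlay = drawArcOverlay(image, circle,
                                cols = range(bands$col[ok])))
}

## Burn the fitted arc into a copy of the image (darkest value), columns
## restricted to the fitted span.
drawArcOverlay <- function(image, circle, cols) {
  out <- image
  lo <- min(image)
  for (cc in seq(cols[1], cols[2])) {
    d2 <- circle@rPx^2 - (cc - circle@h)^2
    if (d2 <= 0) next
    for (rr in c(circle@cy - sqrt(d2), circle@cy + sqrt(d2))) {
      ri <- round(rr) + 1L
      if (ri >= 1L && ri <= nrow(out)) out[ri, cc + 1L] <- lo
    }
  }
  out
}
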