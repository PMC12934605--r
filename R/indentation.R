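## Whole-cell indentation (poke) analysis: align depths to the contact
## step identified from video, find the minimal depth evoking a current
## above the 10 pA responsiveness threshold, and build cohort
## depth-response curves. Threshold computation never sees construct
## labels; grouping happens only at reporting.

#' Align an indentation protocol to cell contact
#'
#' Re-expresses each sweep's depth relative to the step at which the
#' probe first touched the cell (supplied externally, e.g. from video
#' inspection): the contact step becomes depth 0, later steps 1, 2, ...
#' micrometres. Pre-contact sweeps are retained with depth <= 0 and are
#' excluded from thresholding.
#'
#' @param sweeps list of depth-step \linkS4class{SweepTrace} objects in
#'   protocol order (1 um increments).
#' @param contactIndex 1-based protocol step of first contact.
#' @return list: \code{depths} (aligned, um), \code{peaks} (pA, from
#'   \code{\link{peakCurrent}} after baseline subtraction),
#'   \code{postContact} (logical).
#' @export
alignToContact <- function(sweeps, contactIndex) {
  n <- length(sweeps)
  if (contactIndex < 1L || contactIndex > n)
    stopf("contact index %d outside protocol of %d steps",
          contactIndex, n)
  depths <- seq_len(n) - contactIndex
  peaks <- vapply(sweeps, function(tr)
    peakCurrent(baselineSubtract(tr))$Ip, numeric(1))
  list(depths = depths, peaks = peaks, postContact = depths >= 1)
}

#' Indentation threshold depth
#'
#' The threshold d is the first post-contact depth whose peak current
#' exceeds 10 pA (strict). If no depth is responsive the patch is
#' reported non-responsive (\code{d = NA}). When a supra-threshold depth
#' is followed by sub-threshold ones the first crossing still sets d and
#' the series is flagged non-monotone.
#'
#' @param series result of \code{\link{alignToContact}}.
#' @param threshold_pA responsiveness criterion (default 10 pA, strict).
#' @return list: \code{d_um} (NA when non-responsive), \code{responsive}
#'   (logical per post-contact depth), \code{depths} (post-contact
#'   depths), \code{nonMonotone}.
#' @export
indentationThreshold <- function(series,
                                 threshold_pA = ptConstants$RESPONSIVENESS_PA) {
  sel <- series$postContact
  depths <- series$depths[sel]
  if (!length(depths))
    return(list(d_um = NA_real_, responsive = logical(), depths = depths,
                nonMonotone = FALSE))
  resp <- series$peaks[sel] > threshold_pA
  first <- which(resp)[1]
  d <- if (is.na(first)) NA_real_ else depths[first]
  nonMono <- !is.na(first) && any(!resp[seq_along(resp) >= first])
  list(d_um = d, responsive = resp, depths = depths,
       nonMonotone = nonMono)
}

#' Cohort indentation response curve
#'
#' Depth-wise mean and SEM of peak current across patches; only depths
#' present in at least two patches are reported.
#'
#' @param seriesList list of aligned series (from
#'   \code{\link{alignToContact}}), one per patch.
#' @return data.frame: \code{depth_um}, \code{mean_pA}, \code{sem_pA},
#'   \code{n}.
#' @export
indentationResponseCurve <- function(seriesList) {
  if (!length(seriesList)) stopf("empty cohort")
  if (length(seriesList) < 2L)
    stopf("cohort curve needs >= 2 patches, have %d", length(seriesList))
  rows <- do.call(rbind, lapply(seriesList, function(s)
    data.frame(depth = s$depths[s$postContact],
               peak = s$peaks[s$postContact])))
  agg <- do.call(rbind, lapply(split(rows$peak, rows$depth), function(v)
    data.frame(mean_pA = mean(v),
               sem_pA = stats::sd(v) / sqrt(length(v)),
               n = length(v))))
  agg$depth_um <- as.numeric(rownames(agg))
  agg <- agg[agg$n >= 2L, c("depth_um", "mean_pA", "sem_pA", "n")]
  agg <- agg[order(agg$depth_um), ]
  rownames(agg) <- NULL
  agg
}
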