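#' Construct the SSI coefficient set
#'
#' The static sciatic index is the linear model
#' \deqn{SSI = 108.44\,TSF + 31.85\,ITSF - 5.49}
#' with TSF and ITSF the toe-spread factors of [toeSpreadFactor()]. The
#' published constants are the defaults; override them only for research
#' into re-calibrated indices.
#'
#' @param wTsf weight on TSF.
#' @param wItsf weight on ITSF.
#' @param intercept model intercept.
#' @return An [SSICoefficients-class] object.
#' @examples
#' ssiCoefficients()
#' @export
ssiCoefficients <- function(wTsf = 108.44, wItsf = 31.85, intercept = -5.49) {
  new("SSICoefficients", wTsf = wTsf, wItsf = wItsf, intercept = intercept)
}

#' Construct a pair of toe-spread measurements
#'
#' @param tsO,tsC toe spread of the operated / control paw (pixels).
#' @param itsO,itsC intermediate toe spread of the operated / control paw
#'   (pixels).
#' @return A [SpreadPair-class] object.
#' @examples
#' spreadPair(tsO = 60, tsC = 80, itsO = 30, itsC = 40)
#' @export
spreadPair <- function(tsO, tsC, itsO, itsC) {
  new("SpreadPair", tsO = as.numeric(tsO), tsC = as.numeric(tsC),
      itsO = as.numeric(itsO), itsC = as.numeric(itsC))
}

#' Toe spread factor
#'
#' Relative deviation of the operated paw's spread from the control paw's,
#' `(operated - control) / control`. The same function serves the toe
#' spread (TSF) and the intermediate toe spread (ITSF). Being a ratio it is
#' invariant under uniform rescaling of both distances, so no physical
#' pixel calibration is needed.
#'
#' @param operated spread of the operated paw (pixels); vectorised.
#' @param control spread of the control paw (pixels); must be strictly
#'   positive.
#' @param frame optional frame indices used in error messages.
#' @return Numeric vector of factors (dimensionless).
#' @examples
#' toeSpreadFactor(60, 80)   # -0.25
#' toeSpreadFactor(20, 20)   # 0
#' @export
toeSpreadFactor <- function(operated, control, frame = NULL) {
  if (length(operated) != length(control))
    stop("operated and control must have the same length")
  bad <- !is.finite(control) | control <= 0
  if (any(bad)) {
    at <- if (is.null(frame)) which(bad) else frame[bad]
    stop(sprintf("non-positive control spread at frame(s) %s",
                 paste(utils::head(at, 5L), collapse = ", ")))
  }
  if (any(!is.finite(operated) | operated < 0))
    stop("operated spreads must be finite and non-negative")
  (operated - control) / control
}

#' Static sciatic index
#'
#' Evaluates the SSI linear model at the given toe-spread factors. An SSI
#' near 0 indicates a healthy, symmetric toe spread; values near -100
#' indicate complete loss of spreading in the operated paw.
#'
#' @param tsf toe spread factor(s).
#' @param itsf intermediate toe spread factor(s).
#' @param coeffs an [SSICoefficients-class] object.
#' @return Numeric vector of SSI values (dimensionless).
#' @examples
#' staticSciaticIndex(0, 0)          # -5.49, the healthy baseline
#' staticSciaticIndex(-0.25, -0.25)  # -40.5625 + ... (injured pattern)
#' @export
staticSciaticIndex <- function(tsf, itsf, coeffs = ssiCoefficients()) {
  stopifnot(is(coeffs, "SSICoefficients"))
  if (length(tsf) != length(itsf))
    stop("tsf and itsf must have the same length")
  if (any(!is.finite(tsf)) || any(!is.finite(itsf)))
    stop("toe-spread factors must be finite")
  coeffs@wTsf * tsf + coeffs@wItsf * itsf + coeffs@intercept
}

#' SSI from a spread pair
#'
#' Convenience wrapper computing TSF, ITSF and SSI from the four raw
#' spreads of one frame.
#'
#' @param spreads a [SpreadPair-class] object.
#' @param coeffs an [SSICoefficients-class] object.
#' @return Named list with `tsf`, `itsf`, `ssi`.
#' @examples
#' ssiFromSpreads(spreadPair(60, 80, 30, 40))
#' @export
ssiFromSpreads <- function(spreads, coeffs = ssiCoefficients()) {
  stopifnot(is(spreads, "SpreadPair"))
  tsf <- toeSpreadFactor(spreads@tsO, spreads@tsC)
  itsf <- toeSpreadFactor(spreads@itsO, spreads@itsC)
  list(tsf = tsf, itsf = itsf,
       ssi = staticSciaticIndex(tsf, itsf, coeffs))
}

#' Build a per-frame SSI record table
#'
#' Assembles the per-frame measurement table from raw spreads, computing
#' the factors and the index, and flags outliers with [flagOutliers()].
#'
#' @param frameIndex integer vector of 0-based frame indices.
#' @param tsO,itsO,tsC,itsC numeric vectors of spreads (pixels).
#' @param coeffs an [SSICoefficients-class] object.
#' @param plausibleRange,tukeyK outlier settings passed to [flagOutliers()].
#' @return A data.frame with columns `frame_index`, `TSo`, `ITSo`, `TSc`,
#'   `ITSc`, `TSF`, `ITSF`, `SSI`, `outlier`.
#' @export
ssiRecords <- function(frameIndex, tsO, itsO, tsC, itsC,
                       coeffs = ssiCoefficients(),
                       plausibleRange = c(-150, 50), tukeyK = 1.5) {
  tsf <- toeSpreadFactor(tsO, tsC, frame = frameIndex)
  itsf <- toeSpreadFactor(itsO, itsC, frame = frameIndex)
  ssi <- staticSciaticIndex(tsf, itsf, coeffs)
  out <- if (length(ssi)) flagOutliers(ssi, plausibleRange, tukeyK) else logical(0)
  data.frame(frame_index = as.integer(frameIndex),
             TSo = tsO, ITSo = itsO, TSc = tsC, ITSc = itsC,
             TSF = tsf, ITSF = itsf, SSI = ssi, outlier = out)
}

#' Flag outlying SSI values
#'
#' Two-stage flagging. Stage one removes physiologically implausible
#' values outside an absolute window (default \[-150, +50\], generously
#' bracketing the observed SSI range of roughly -80 to +10). Stage two
#' applies Tukey's boxplot fences to the surviving values: anything outside
#' \[q25 - k IQR, q75 + k IQR\] is flagged, with quartiles by linear
#' interpolation. With fewer than 4 values no flags are raised.
#'
#' @param ssi numeric vector of per-frame SSI values.
#' @param plausibleRange absolute plausibility window `c(lo, hi)`.
#' @param tukeyK fence multiplier (1.5 = standard boxplot whiskers).
#' @return Logical vector, TRUE where the value is an outlier; order
#'   preserved.
#' @examples
#' flagOutliers(c(-9, -10, -11, -9, -10, -12, -60))
#' @export
flagOutliers <- function(ssi, plausibleRange = c(-150, 50), tukeyK = 1.5) {
  if (length(ssi) == 0L) stop("flagOutliers: empty input")
  if (!is.numeric(ssi) || any(!is.finite(ssi)))
    stop("flagOutliers: ssi must be finite numeric")
  n <- length(ssi)
  if (n < 4L) return(rep(FALSE, n))
  flags <- ssi < plausibleRange[1] | ssi > plausibleRange[2]
  keep <- ssi[!flags]
  if (length(keep) >= 4L) {
    q <- stats::quantile(keep, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - tukeyK * iqr
    hi <- q[2] + tukeyK * iqr
    flags <- flags | ssi < lo | ssi > hi
  }
  flags
}

#' Summarise a video's SSI records
#'
#' Draws a seeded uniform subsample of up to `sampleSize` non-outlier
#' records (all of them when fewer) and computes the per-video summary
#' statistics: mean, SD (n-1 denominator), median and quartiles (linear
#' interpolation). The video-level QC verdict requires more than 50
#' labeled frames.
#'
#' @param records data.frame from [ssiRecords()] (must carry the `outlier`
#'   column).
#' @param nFramesTotal total frames read from the video.
#' @param sampleSize maximum number of records used for the statistics.
#' @param seed integer seed for the subsample draw; the same seed gives a
#'   bit-identical summary.
#' @return A [VideoSummary-class] object.
#' @examples
#' r <- ssiRecords(0:9, rep(60, 10), rep(30, 10), rep(80, 10), rep(40, 10))
#' summarizeVideo(r, nFramesTotal = 100L)
#' @export
summarizeVideo <- function(records, nFramesTotal = nrow(records),
                           sampleSize = 1000L, seed = 0L) {
  stopifnot(is.data.frame(records))
  nLab <- nrow(records)
  retained <- if (nLab) records$SSI[!records$outlier] else numeric(0)
  nRet <- length(retained)
  vals <- retained
  if (nRet > sampleSize)
    vals <- withLocalSeed(seed, retained[sample.int(nRet, sampleSize)])
  if (length(vals) == 0L) {
    return(new("VideoSummary",
               nFramesTotal = as.integer(nFramesTotal),
               nFramesLabeled = as.integer(nLab), nFramesRetained = 0L,
               nSampled = 0L, meanSsi = NA_real_, sdSsi = NA_real_,
               medianSsi = NA_real_, q25Ssi = NA_real_, q75Ssi = NA_real_,
               retentionFraction = if (nFramesTotal > 0) nLab / nFramesTotal else NA_real_,
               qcPass = FALSE,
               qcReasons = unique(c("NO_FRAMES",
                                    if (nLab <= 50L) "TOO_FEW_FRAMES"))))
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  reasons <- character(0)
  if (nLab <= 50L) reasons <- "TOO_FEW_FRAMES"
  new("VideoSummary",
      nFramesTotal = as.integer(nFramesTotal),
      nFramesLabeled = as.integer(nLab),
      nFramesRetained = as.integer(nRet),
      nSampled = length(vals),
      meanSsi = mean(vals),
      sdSsi = if (length(vals) > 1L) stats::sd(vals) else 0,
      medianSsi = q[2], q25Ssi = q[1], q75Ssi = q[3],
      retentionFraction = if (nFramesTotal > 0) nLab / nFramesTotal else NA_real_,
      qcPass = nLab > 50L, qcReasons = reasons)
}
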