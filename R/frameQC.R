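#' Frame QC parameters
#'
#' @param tsBodyBand plausible toe-spread range as a fraction of the body
#'   major-axis length; spreads outside it indicate segmentation artifacts
#'   (e.g. reflections merged into a paw). Deliberately loose by default.
#' @return Named list.
#' @export
frameQcParams <- function(tsBodyBand = c(0.05, 0.6)) {
  list(tsBodyBand = tsBodyBand)
}

#' Construct a frame verdict
#'
#' @param frameIndex 0-based frame ordinal.
#' @param reason reason code; `"OK"` means accepted.
#' @return A [FrameVerdict-class] object.
#' @export
frameVerdict <- function(frameIndex, reason = "OK") {
  new("FrameVerdict", frameIndex = as.integer(frameIndex),
      accepted = identical(reason, "OK"), reason = reason)
}

#' Decide whether a frame yields a valid measurement
#'
#' A frame is accepted only when the detection found a body, the heading
#' resolved unambiguously, both paws have exactly 5 digits, and the
#' geometry is plausible: ITS strictly smaller than TS on both paws and TS
#' within `tsBodyBand` times the body major-axis length. Verdicts are a
#' pure function of their inputs.
#'
#' @param detection a [FrameDetection-class].
#' @param axis a [BodyAxis-class] (or `NULL` when detection was rejected).
#' @param pawStatus list with `leftStatus`, `rightStatus` from
#'   [splitPaws()] (or `NULL`).
#' @param left,right [PawMeasurement-class] objects (or `NULL`).
#' @param params list from [frameQcParams()].
#' @return A [FrameVerdict-class] object.
#' @export
validateFrame <- function(detection, axis = NULL, pawStatus = NULL,
                          left = NULL, right = NULL,
                          params = frameQcParams()) {
  fi <- detection@frameIndex
  if (!is.na(detection@rejectReason))
    return(frameVerdict(fi, detection@rejectReason))
  if (is.null(axis) || axis@degenerate || axis@ambiguous ||
      axis@headingSign == 0)
    return(frameVerdict(fi, "AMBIGUOUS_HEADING"))
  if (!is.null(pawStatus)) {
    st <- c(pawStatus$leftStatus, pawStatus$rightStatus)
    if ("PAW_NOT_VISIBLE" %in% st)
      return(frameVerdict(fi, "PAW_NOT_VISIBLE"))
    if ("MISSING_DIGITS" %in% st)
      return(frameVerdict(fi, "MISSING_DIGITS"))
  }
  if (is.null(left) || is.null(right))
    return(frameVerdict(fi, "PAW_NOT_VISIBLE"))
  band <- params$tsBodyBand * axis@majorAxisLength
  for (paw in list(left, right)) {
    if (paw@its >= paw@ts)
      return(frameVerdict(fi, "IMPLAUSIBLE_GEOMETRY"))
    if (paw@ts < band[1] || paw@ts > band[2])
      return(frameVerdict(fi, "IMPLAUSIBLE_GEOMETRY"))
  }
  frameVerdict(fi, "OK")
}

#' Set the video-level QC verdict
#'
#' A video's measurement set is acceptable only when more than 50 frames
#' were labeled; the retention fraction is reported but not enforced
#' beyond that floor.
#'
#' @param summary a [VideoSummary-class].
#' @return The summary with `qcPass` / `qcReasons` (re)computed.
#' @export
validateVideo <- function(summary) {
  stopifnot(is(summary, "VideoSummary"))
  reasons <- character(0)
  if (summary@nFramesLabeled <= 50L) reasons <- c(reasons, "TOO_FEW_FRAMES")
  if (summary@nFramesRetained == 0L) reasons <- c(reasons, "NO_FRAMES")
  summary@qcPass <- length(reasons) == 0L
  summary@qcReasons <- reasons
  summary
}
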