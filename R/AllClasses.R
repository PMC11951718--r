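#' @import methods
NULL

#' SSI regression coefficients
#'
#' Weights of the linear static sciatic index model
#' \deqn{SSI = 108.44\,TSF + 31.85\,ITSF - 5.49.}
#' The defaults are the published constants; they are configurable only via
#' an explicit override for research use.
#'
#' @slot wTsf weight on the toe spread factor (dimensionless).
#' @slot wItsf weight on the intermediate toe spread factor (dimensionless).
#' @slot intercept model intercept (dimensionless).
#' @seealso [staticSciaticIndex()]
#' @export
setClass("SSICoefficients",
  representation(wTsf = "numeric", wItsf = "numeric", intercept = "numeric"),
  prototype(wTsf = 108.44, wItsf = 31.85, intercept = -5.49),
  validity = function(object) {
    if (length(object@wTsf) != 1L || length(object@wItsf) != 1L ||
        length(object@intercept) != 1L)
      return("all coefficients must be scalars")
    if (!all(is.finite(c(object@wTsf, object@wItsf, object@intercept))))
      return("coefficients must be finite")
    TRUE
  })

#' Paired toe-spread measurements for one frame
#'
#' Toe spread (TS, digits 1-5) and intermediate toe spread (ITS, digits 2-4)
#' of the operated (o) and control (c) hind paws, in pixels. A zero control
#' spread would make the toe-spread factors undefined, so all four distances
#' must be strictly positive, and the intermediate spread must be smaller
#' than the full spread on each paw.
#'
#' @slot tsO,tsC toe spread of operated / control paw (pixels).
#' @slot itsO,itsC intermediate toe spread of operated / control paw (pixels).
#' @export
setClass("SpreadPair",
  representation(tsO = "numeric", tsC = "numeric",
                 itsO = "numeric", itsC = "numeric"),
  validity = function(object) {
    v <- c(object@tsO, object@tsC, object@itsO, object@itsC)
    if (length(object@tsO) != 1L || length(object@tsC) != 1L ||
        length(object@itsO) != 1L || length(object@itsC) != 1L)
      return("spreads must be scalars")
    if (!all(is.finite(v)) || any(v <= 0))
      return("all four spreads must be strictly positive and finite")
    if (object@itsO >= object@tsO)
      return("itsO must be smaller than tsO (intermediate digits lie inside outer digits)")
    if (object@itsC >= object@tsC)
      return("itsC must be smaller than tsC (intermediate digits lie inside outer digits)")
    TRUE
  })

#' Body position and orientation in one frame
#'
#' Centroid and principal axis of the body mask. The axis direction is a
#' unit vector; the heading (which end of the axis is the head) is resolved
#' separately from the digit positions and stored as a sign. A heading sign
#' of 0 means unresolved.
#'
#' @slot centroid numeric length-2, (x, y) pixel coordinates (0-based,
#'   origin top-left, y downward).
#' @slot direction numeric length-2 unit vector along the major axis.
#' @slot headingSign +1 or -1 once resolved (heading = headingSign *
#'   direction points toward the head), 0 while unresolved.
#' @slot majorAxisLength full body length estimate (pixels), from second
#'   moments as for an equivalent ellipse.
#' @slot degenerate TRUE when the mask is nearly isotropic and the axis
#'   direction is arbitrary.
#' @slot ambiguous TRUE when heading resolution was attempted but the digit
#'   cloud straddles the centroid within tolerance.
#' @export
setClass("BodyAxis",
  representation(centroid = "numeric", direction = "numeric",
                 headingSign = "numeric", majorAxisLength = "numeric",
                 degenerate = "logical", ambiguous = "logical"),
  prototype(headingSign = 0, degenerate = FALSE, ambiguous = FALSE),
  validity = function(object) {
    if (length(object@centroid) != 2L || length(object@direction) != 2L)
      return("centroid and direction must have length 2")
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
      return("direction must be a unit vector")
    if (!object@headingSign %in% c(-1, 0, 1))
      return("headingSign must be -1, 0 or +1")
    TRUE
  })

#' Per-frame detection result
#'
#' Output of the segmentation backend for one cropped frame: the body mask
#' plus digit candidate blobs (centroid, area, mean intensity). Centroids
#' are intensity-weighted and may be fractional; coordinates are 0-based
#' pixels in the original (uncropped) frame system.
#'
#' @slot frameIndex frame ordinal within the video (0-based).
#' @slot bodyMask logical matrix (rows = y, cols = x) of the body component;
#'   empty (0x0) when no body was found.
#' @slot bodyArea body component area in pixels (0 when absent).
#' @slot candidates data.frame with columns `x`, `y`, `area`,
#'   `meanIntensity`, one row per digit candidate.
#' @slot rejectReason `NA_character_` when usable, otherwise a reason code
#'   such as `"NO_ANIMAL"`.
#' @export
setClass("FrameDetection",
  representation(frameIndex = "integer", bodyMask = "matrix",
                 bodyArea = "numeric", candidates = "data.frame",
                 rejectReason = "character"),
  prototype(rejectReason = NA_character_))

#' One paw's ordered digits and spreads
#'
#' Digits are ordered 1 (innermost toe, nearest the body axis) to 5
#' (outermost toe). TS is the Euclidean distance between digits 1 and 5,
#' ITS between digits 2 and 4, both in pixels.
#'
#' @slot side `"left"` or `"right"` in the animal's frame of reference.
#' @slot role `"operated"`, `"control"` or `NA` before role assignment.
#' @slot digits 5x2 numeric matrix of (x, y) digit centroids, rows ordered
#'   digit 1 to digit 5.
#' @slot ts,its toe spread and intermediate toe spread (pixels).
#' @export
setClass("PawMeasurement",
  representation(side = "character", role = "character",
                 digits = "matrix", ts = "numeric", its = "numeric"),
  prototype(role = NA_character_),
  validity = function(object) {
    if (!identical(dim(object@digits), c(5L, 2L)))
      return("digits must be a 5x2 matrix")
    if (!object@side %in% c("left", "right"))
      return("side must be 'left' or 'right'")
    if (!is.na(object@role) && !object@role %in% c("operated", "control"))
      return("role must be 'operated', 'control' or NA")
    TRUE
  })

#' Per-frame quality-control verdict
#'
#' A frame is accepted exactly when its reason code is `"OK"`. Reason codes:
#' `OK`, `NO_ANIMAL`, `MISSING_DIGITS`, `PAW_NOT_VISIBLE`,
#' `AMBIGUOUS_HEADING`, `IMPLAUSIBLE_GEOMETRY`.
#'
#' @slot frameIndex frame ordinal (0-based).
#' @slot accepted logical, derived from the reason code.
#' @slot reason reason code string.
#' @export
setClass("FrameVerdict",
  representation(frameIndex = "integer", accepted = "logical",
                 reason = "character"),
  validity = function(object) {
    codes <- c("OK", "NO_ANIMAL", "MISSING_DIGITS", "PAW_NOT_VISIBLE",
               "AMBIGUOUS_HEADING", "IMPLAUSIBLE_GEOMETRY")
    if (!object@reason %in% codes)
      return(sprintf("unknown reason code '%s'", object@reason))
    if (!identical(object@accepted, identical(object@reason, "OK")))
      return("accepted must be TRUE exactly when reason is 'OK'")
    TRUE
  })

#' Per-video aggregate of SSI measurements
#'
#' Summary statistics over the retained (non-outlier) per-frame SSI values,
#' computed from a seeded random subsample of at most `sampleSize` records,
#' together with frame-retention accounting and the video-level QC verdict.
#'
#' @slot nFramesTotal frames read from the video.
#' @slot nFramesLabeled frames that yielded a valid SSI measurement.
#' @slot nFramesRetained labeled frames surviving outlier removal.
#' @slot nSampled records actually used for the summary statistics.
#' @slot meanSsi,sdSsi,medianSsi,q25Ssi,q75Ssi summary statistics of SSI
#'   (SD uses the n-1 denominator; quartiles use linear interpolation).
#' @slot retentionFraction nFramesLabeled / nFramesTotal.
#' @slot qcPass video-level QC verdict (requires more than 50 labeled
#'   frames).
#' @slot qcReasons character vector of reason codes
#'   (`TOO_FEW_FRAMES`, `NO_FRAMES`), empty when qcPass is TRUE.
#' @export
setClass("VideoSummary",
  representation(nFramesTotal = "integer", nFramesLabeled = "integer",
                 nFramesRetained = "integer", nSampled = "integer",
                 meanSsi = "numeric", sdSsi = "numeric",
                 medianSsi = "numeric", q25Ssi = "numeric",
                 q75Ssi = "numeric", retentionFraction = "numeric",
                 qcPass = "logical", qcReasons = "character"),
  validity = function(object) {
    if (object@nFramesRetained > object@nFramesLabeled)
      return("nFramesRetained cannot exceed nFramesLabeled")
    if (object@nFramesLabeled > object@nFramesTotal)
      return("nFramesLabeled cannot exceed nFramesTotal")
    if (isTRUE(object@qcPass) && object@nFramesLabeled <= 50L)
      return("qcPass must be FALSE when 50 or fewer frames are labeled")
    TRUE
  })

#' Specification of a synthetic under-box scene
#'
#' Describes a synthetic video of a light-coated rat seen from below: a
#' bright body ellipse, two hind paws of five bright Gaussian digit blobs
#' each with configurable toe spreads, background noise, and optional
#' artifacts (a reflective patch, occlusion of one paw). Rendering is fully
#' deterministic given the seed: frame `i` of a spec always looks the same.
#'
#' @slot frameSize (width, height) in pixels.
#' @slot bodyCenter (x, y) of the body ellipse center.
#' @slot bodySemiAxes (semi-major, semi-minor) of the body ellipse (pixels).
#' @slot headingDeg heading angle in degrees; 0 points along +x, angles
#'   increase clockwise on screen (y grows downward).
#' @slot spreads named list with elements `left` and `right`, each
#'   `c(ts = ..., its = ...)` in pixels.
#' @slot pawLateralOffset distance from the body axis to each paw center
#'   (pixels).
#' @slot pawCaudalOffset distance from the body centroid to the paw centers
#'   along the caudal direction (pixels).
#' @slot blobRadius digit blob radius parameter (pixels); the Gaussian
#'   profile has sd blobRadius / 2.
#' @slot bodyIntensity,digitIntensity,background intensities in [0, 1].
#' @slot noiseSd Gaussian pixel noise sd (intensity units).
#' @slot jitterSd per-frame, per-digit centroid jitter sd (pixels).
#' @slot reflectivePatch numeric length-5 `c(x, y, w, h, intensity)` or
#'   numeric(0) for none.
#' @slot occludePaw `"none"`, `"left"` or `"right"`.
#' @slot seed integer seed controlling noise and jitter.
#' @seealso [sceneSpec()], [renderFrame()], [renderVideo()]
#' @export
setClass("SceneSpec",
  representation(frameSize = "numeric", bodyCenter = "numeric",
                 bodySemiAxes = "numeric", headingDeg = "numeric",
                 spreads = "list", pawLateralOffset = "numeric",
                 pawCaudalOffset = "numeric", blobRadius = "numeric",
                 bodyIntensity = "numeric", digitIntensity = "numeric",
                 background = "numeric", noiseSd = "numeric",
                 jitterSd = "numeric", reflectivePatch = "numeric",
                 occludePaw = "character", seed = "integer"),
  validity = function(object) {
    if (length(object@frameSize) != 2L || any(object@frameSize < 16))
      return("frameSize must be (width, height), each at least 16 px")
    for (side in c("left", "right")) {
      sp <- object@spreads[[side]]
      if (is.null(sp) || !all(c("ts", "its") %in% names(sp)))
        return(sprintf("spreads$%s must contain 'ts' and 'its'", side))
      if (sp[["its"]] >= sp[["ts"]])
        return(sprintf("spreads$%s: its must be smaller than ts", side))
      if (any(sp <= 0)) return("spreads must be strictly positive")
    }
    if (!object@occludePaw %in% c("none", "left", "right"))
      return("occludePaw must be 'none', 'left' or 'right'")
    if (!length(object@reflectivePatch) %in% c(0L, 5L))
      return("reflectivePatch must be numeric(0) or c(x, y, w, h, intensity)")
    TRUE
  })

#' A readable stream of video frames
#'
#' Abstraction over video containers: frames are obtained lazily through
#' `getFrame(i)` (1-based position in the possibly strided stream), each a
#' numeric matrix in [0, 1] with rows = y and columns = x. `frameIndex`
#' maps stream positions back to 0-based frame indices in the source video.
#'
#' @slot name video name (file stem) used for output files.
#' @slot nFrames number of frames available through this source.
#' @slot fps frames per second when known, `NA` otherwise.
#' @slot frameIndex integer vector of 0-based source frame indices.
#' @slot getFrame function(i) returning frame at stream position i.
#' @export
setClass("FrameSource",
  representation(name = "character", nFrames = "integer", fps = "numeric",
                 frameIndex = "integer", getFrame = "function"))
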