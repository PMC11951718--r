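# show() methods and accessor generics for the S4 containers.

#' @describeIn SSICoefficients-class compact display.
#' @param object an object of the documented class.
#' @export
setMethod("show", "SSICoefficients", function(object) {
  cat(sprintf("SSI coefficients: %.2f * TSF + %.2f * ITSF + (%.2f)\n",
              object@wTsf, object@wItsf, object@intercept))
})

#' @describeIn SpreadPair-class compact display.
#' @export
setMethod("show", "SpreadPair", function(object) {
  cat(sprintf(
    "SpreadPair: TSo=%.2f ITSo=%.2f | TSc=%.2f ITSc=%.2f (px)\n",
    object@tsO, object@itsO, object@tsC, object@itsC))
})

#' @describeIn BodyAxis-class compact display.
#' @export
setMethod("show", "BodyAxis", function(object) {
  head <- if (object@headingSign == 0) "unresolved"
          else sprintf("(%+.3f, %+.3f)", object@headingSign * object@direction[1],
                       object@headingSign * object@direction[2])
  cat(sprintf(
    "BodyAxis: centroid (%.1f, %.1f), length %.1f px, heading %s%s%s\n",
    object@centroid[1], object@centroid[2], object@majorAxisLength, head,
    if (object@degenerate) " [DEGENERATE]" else "",
    if (object@ambiguous) " [AMBIGUOUS]" else ""))
})

#' @describeIn FrameDetection-class compact display.
#' @export
setMethod("show", "FrameDetection", function(object) {
  cat(sprintf("FrameDetection: frame %d, body area %d px, %d digit candidate(s)%s\n",
              object@frameIndex, round(object@bodyArea),
              nrow(object@candidates),
              if (is.na(object@rejectReason)) ""
              else sprintf(" [%s]", object@rejectReason)))
})

#' @describeIn PawMeasurement-class compact display.
#' @export
setMethod("show", "PawMeasurement", function(object) {
  cat(sprintf("PawMeasurement: %s paw%s, TS=%.2f px, ITS=%.2f px\n",
              object@side,
              if (is.na(object@role)) "" else paste0(" (", object@role, ")"),
              object@ts, object@its))
})

#' @describeIn FrameVerdict-class compact display.
#' @export
setMethod("show", "FrameVerdict", function(object) {
  cat(sprintf("FrameVerdict: frame %d %s (%s)\n", object@frameIndex,
              if (object@accepted) "accepted" else "rejected",
              object@reason))
})

#' @describeIn VideoSummary-class compact display.
#' @export
setMethod("show", "VideoSummary", function(object) {
  cat(sprintf(
    "VideoSummary: %d/%d frames labeled (%.1f%%), %d retained\n",
    object@nFramesLabeled, object@nFramesTotal,
    100 * object@retentionFraction, object@nFramesRetained))
  if (is.finite(object@meanSsi))
    cat(sprintf("  SSI mean %.2f, SD %.2f, median %.2f [IQR %.2f, %.2f]\n",
                object@meanSsi, object@sdSsi, object@medianSsi,
                object@q25Ssi, object@q75Ssi))
  cat(sprintf("  QC: %s\n",
              if (object@qcPass) "pass"
              else paste("fail -", paste(object@qcReasons, collapse = ", "))))
})

#' @describeIn SceneSpec-class compact display.
#' @export
setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px, left ts/its %.0f/%.0f, right %.0f/%.0f, jitter %.1f px, seed %d%s\n",
              object@frameSize[1], object@frameSize[2],
              object@spreads$left[["ts"]], object@spreads$left[["its"]],
              object@spreads$right[["ts"]], object@spreads$right[["its"]],
              object@jitterSd, object@seed,
              if (object@occludePaw != "none")
                paste0(", ", object@occludePaw, " paw occluded") else ""))
})

#' @describeIn FrameSource-class compact display.
#' @export
setMethod("show", "FrameSource", function(object) {
  cat(sprintf("FrameSource '%s': %d frame(s)%s\n", object@name,
              object@nFrames,
              if (is.na(object@fps)) "" else sprintf(" @ %.1f fps", object@fps)))
})

#' Accessors for video summaries and paw measurements
#'
#' Small accessor family so downstream code never touches slots directly.
#'
#' @param x a [VideoSummary-class] or [PawMeasurement-class] object.
#' @return The requested scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))
#' @rdname accessors
#' @export
setMethod("qcPass", "VideoSummary", function(x) x@qcPass)

#' @rdname accessors
#' @export
setGeneric("qcReasons", function(x) standardGeneric("qcReasons"))
#' @rdname accessors
#' @export
setMethod("qcReasons", "VideoSummary", function(x) x@qcReasons)

#' @rdname accessors
#' @export
setGeneric("meanSsi", function(x) standardGeneric("meanSsi"))
#' @rdname accessors
#' @export
setMethod("meanSsi", "VideoSummary", function(x) x@meanSsi)

#' @rdname accessors
#' @export
setGeneric("sdSsi", function(x) standardGeneric("sdSsi"))
#' @rdname accessors
#' @export
setMethod("sdSsi", "VideoSummary", function(x) x@sdSsi)

#' @rdname accessors
#' @export
setGeneric("nFramesLabeled", function(x) standardGeneric("nFramesLabeled"))
#' @rdname accessors
#' @export
setMethod("nFramesLabeled", "VideoSummary", function(x) x@nFramesLabeled)

#' @rdname accessors
#' @export
setGeneric("nFramesRetained", function(x) standardGeneric("nFramesRetained"))
#' @rdname accessors
#' @export
setMethod("nFramesRetained", "VideoSummary", function(x) x@nFramesRetained)

#' @rdname accessors
#' @export
setGeneric("retentionFraction", function(x) standardGeneric("retentionFraction"))
#' @rdname accessors
#' @export
setMethod("retentionFraction", "VideoSummary", function(x) x@retentionFraction)

#' @rdname accessors
#' @export
setGeneric("toeSpread", function(x) standardGeneric("toeSpread"))
#' @rdname accessors
#' @export
setMethod("toeSpread", "PawMeasurement", function(x) x@ts)

#' @rdname accessors
#' @export
setGeneric("intermediateToeSpread",
           function(x) standardGeneric("intermediateToeSpread"))
#' @rdname accessors
#' @export
setMethod("intermediateToeSpread", "PawMeasurement", function(x) x@its)
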