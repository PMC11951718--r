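#' Full pipeline parameter set
#'
#' Collects the tunables of every stage in one place. All defaults are the
#' package's documented operating point; see the methods vignette for the
#' rationale behind each.
#'
#' @param segmentation list from [segmentationParams()].
#' @param qc list from [frameQcParams()].
#' @param coeffs an [SSICoefficients-class].
#' @param plausibleRange,tukeyK outlier settings ([flagOutliers()]).
#' @param sampleSize,seed summary subsample settings ([summarizeVideo()]).
#' @param flipLR mirrored-rig override for the left/right convention.
#' @param headingTol heading-ambiguity tolerance in pixels (`NULL` =
#'   scale with body length).
#' @return Named list of class `ssiPipelineParams`.
#' @export
pipelineParams <- function(segmentation = segmentationParams(),
                           qc = frameQcParams(),
                           coeffs = ssiCoefficients(),
                           plausibleRange = c(-150, 50), tukeyK = 1.5,
                           sampleSize = 1000L, seed = 0L,
                           flipLR = FALSE, headingTol = NULL) {
  structure(list(segmentation = segmentation, qc = qc, coeffs = coeffs,
                 plausibleRange = plausibleRange, tukeyK = tukeyK,
                 sampleSize = as.integer(sampleSize), seed = as.integer(seed),
                 flipLR = flipLR, headingTol = headingTol),
            class = "ssiPipelineParams")
}

#' Measure one frame
#'
#' Runs segmentation, body-axis estimation, heading resolution, paw
#' splitting, digit ordering, spread measurement and the frame QC verdict
#' for a single frame. This is the unit of work [processVideo()] repeats
#' over a stream.
#'
#' @param frame grayscale matrix in [0, 1].
#' @param roi optional ROI polygon.
#' @param operatedSide `"left"` or `"right"`.
#' @param params list from [pipelineParams()].
#' @param frameIndex 0-based frame ordinal.
#' @param roiMaskCached optional precomputed ROI mask.
#' @return List with `verdict` ([FrameVerdict-class]) and, when accepted,
#'   `spreads` ([SpreadPair-class]), `operated`, `control`
#'   ([PawMeasurement-class]) and `axis` ([BodyAxis-class]).
#' @export
measureFrame <- function(frame, roi = NULL, operatedSide = "left",
                         params = pipelineParams(), frameIndex = 0L,
                         roiMaskCached = NULL) {
  det <- segmentFrame(frame, roi = roi, params = params$segmentation,
                      frameIndex = frameIndex, mask = roiMaskCached)
  if (!is.na(det@rejectReason))
    return(list(verdict = validateFrame(det)))
  axis <- bodyAxis(det@bodyMask)
  if (nrow(det@candidates) >= 1L)
    axis <- resolveHeading(axis, det@candidates, tol = params$headingTol)
  if (axis@degenerate || axis@ambiguous || axis@headingSign == 0)
    return(list(verdict = validateFrame(det, axis), axis = axis))
  paws <- splitPaws(det@candidates, axis, flipLR = params$flipLR)
  if (paws$leftStatus != "OK" || paws$rightStatus != "OK")
    return(list(verdict = validateFrame(det, axis, paws), axis = axis))
  left <- measurePaw(paws$left, axis, "left")
  right <- measurePaw(paws$right, axis, "right")
  verdict <- validateFrame(det, axis, paws, left, right, params$qc)
  if (!verdict@accepted)
    return(list(verdict = verdict, axis = axis))
  roles <- assignRoles(left, right, operatedSide)
  list(verdict = verdict, spreads = roles$spreads,
       operated = roles$operated, control = roles$control, axis = axis)
}

#' Process one video end to end
#'
#' Streams frames from a [FrameSource-class], measures each frame with
#' [measureFrame()], assembles the per-frame record table, flags outliers
#' and computes the per-video summary with the video-level QC verdict.
#'
#' @param source a [FrameSource-class] (from [readFrames()] or
#'   [syntheticFrameSource()]).
#' @param roi optional ROI polygon applied to every frame.
#' @param operatedSide which paw was operated.
#' @param params list from [pipelineParams()].
#' @param progressEvery print a progress line every this many frames
#'   (0 = silent).
#' @return List of class `ssiVideoResult` with `records` (data.frame of
#'   labeled frames), `verdicts` (data.frame of all frames), `summary`
#'   ([VideoSummary-class]) and `name`.
#' @export
processVideo <- function(source, roi = NULL,
                         operatedSide = c("left", "right"),
                         params = pipelineParams(), progressEvery = 0L) {
  operatedSide <- match.arg(operatedSide)
  stopifnot(is(source, "FrameSource"))
  n <- source@nFrames
  mask <- NULL
  reasons <- character(n)
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    frame <- source@getFrame(i)
    if (is.null(mask) && !is.null(roi))
      mask <- roiMask(roi, ncol(frame), nrow(frame))
    fi <- source@frameIndex[i]
    m <- measureFrame(frame, roi = NULL, operatedSide = operatedSide,
                      params = params, frameIndex = fi,
                      roiMaskCached = mask)
    reasons[i] <- m$verdict@reason
    if (m$verdict@accepted) meas[[i]] <- m
    if (progressEvery > 0L && i %% progressEvery == 0L)
      message(sprintf("  frame %d/%d (%d labeled)", i, n,
                      sum(reasons[1:i] == "OK")))
  }
  ok <- !vapply(meas, is.null, logical(1))
  records <- if (any(ok)) {
    sp <- lapply(meas[ok], `[[`, "spreads")
    ssiRecords(frameIndex = source@frameIndex[ok],
               tsO = vapply(sp, function(s) s@tsO, numeric(1)),
               itsO = vapply(sp, function(s) s@itsO, numeric(1)),
               tsC = vapply(sp, function(s) s@tsC, numeric(1)),
               itsC = vapply(sp, function(s) s@itsC, numeric(1)),
               coeffs = params$coeffs,
               plausibleRange = params$plausibleRange,
               tukeyK = params$tukeyK)
  } else {
    ssiRecords(integer(0), numeric(0), numeric(0), numeric(0), numeric(0))
  }
  summary <- summarizeVideo(records, nFramesTotal = n,
                            sampleSize = params$sampleSize,
                            seed = params$seed)
  summary <- validateVideo(summary)
  structure(list(records = records,
                 verdicts = data.frame(frame_index = source@frameIndex,
                                       accepted = reasons == "OK",
                                       reason = reasons),
                 summary = summary, name = source@name),
            class = "ssiVideoResult")
}

#' Batch-process a folder of videos
#'
#' The three-stage workflow as a batch job: every video in `inputDir` is
#' cropped per the crop configuration, segmented and measured, and its
#' per-frame table plus summary written to the output folder (XLSX + CSV,
#' one pair per video), together with a YAML run manifest (configuration,
#' seed, package version, per-video status). Failures are isolated per
#' video: the batch continues and the failure is recorded in the manifest.
#'
#' @param inputDir directory containing videos (`.mp4`, `.tif`, `.tiff`).
#' @param cropConfig a `cropConfig` from [readCropConfig()], a path to a
#'   YAML crop config, or `NULL` to process every video full-frame.
#' @param outputDir output directory; default is an `Output` folder inside
#'   `inputDir`.
#' @param operatedSide experiment-level operated side (per-video entries
#'   in the crop config override it).
#' @param params list from [pipelineParams()].
#' @param stride frame subsampling passed to [readFrames()].
#' @param progressEvery per-video progress interval (frames).
#' @return Invisibly, a data.frame with one row per video: name, status,
#'   frames labeled/retained, mean and SD of SSI, QC verdict. Attribute
#'   `"failures"` counts failed videos.
#' @export
processFolder <- function(inputDir, cropConfig = NULL,
                          outputDir = file.path(inputDir, "Output"),
                          operatedSide = c("left", "right"),
                          params = pipelineParams(), stride = 1L,
                          progressEvery = 0L) {
  operatedSide <- match.arg(operatedSide)
  if (is.character(cropConfig)) cropConfig <- readCropConfig(cropConfig)
  files <- list.files(inputDir, pattern = "\\.(mp4|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- files[!grepl("_groundtruth", basename(files))]
  if (length(files) == 0L)
    stop(sprintf("no videos (.mp4/.tif/.tiff) found in %s", inputDir))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); status <- character(length(files))
  for (k in seq_along(files)) {
    f <- files[k]
    nm <- sub("\\.[A-Za-z0-9]+$", "", basename(f))
    res <- tryCatch({
      crop <- if (is.null(cropConfig))
        list(roi = NULL, operatedSide = operatedSide)
      else lookupCrop(cropConfig, nm, operatedSide)
      src <- readFrames(f, stride = stride)
      out <- processVideo(src, roi = crop$roi,
                          operatedSide = crop$operatedSide,
                          params = params, progressEvery = progressEvery)
      writeResults(out$records, out$summary, outputDir, nm)
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[k] <- paste0("ERROR: ", conditionMessage(res))
      message(sprintf("video %s failed: %s", nm, conditionMessage(res)))
      rows[[k]] <- data.frame(video = nm, status = "error",
                              n_labeled = NA_integer_,
                              n_retained = NA_integer_,
                              mean_ssi = NA_real_, sd_ssi = NA_real_,
                              qc_pass = NA)
    } else {
      status[k] <- "ok"
      s <- res$summary
      rows[[k]] <- data.frame(video = nm, status = "ok",
                              n_labeled = s@nFramesLabeled,
                              n_retained = s@nFramesRetained,
                              mean_ssi = s@meanSsi, sd_ssi = s@sdSsi,
                              qc_pass = s@qcPass)
      message(sprintf(
        "video %s: %d/%d frames labeled (%.1f%%), mean SSI %.2f (SD %.2f), QC %s",
        nm, s@nFramesLabeled, s@nFramesTotal,
        100 * s@retentionFraction, s@meanSsi, s@sdSsi,
        if (s@qcPass) "pass" else paste(s@qcReasons, collapse = ",")))
    }
  }
  manifest <- list(
    package = "pawSSI",
    version = as.character(utils::packageVersion("pawSSI")),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = params$seed, stride = stride,
    operated_side = operatedSide,
    backend = params$segmentation$backend,
    videos = stats::setNames(as.list(status),
                             sub("\\.[A-Za-z0-9]+$", "", basename(files))))
  yaml::write_yaml(manifest, file.path(outputDir, "run_manifest.yaml"))
  out <- do.call(rbind, rows)
  attr(out, "failures") <- sum(out$status != "ok")
  invisible(out)
}

#' Render a synthetic video to disk (wrapper)
#'
#' Thin wrapper over [sceneSpec()] and [renderVideo()] matching the
#' command-line `simulate` interface.
#'
#' @param out output path (`.tif`, `.mp4`, or extension-less for a PNG
#'   directory).
#' @param nFrames frames to render.
#' @param tsO,itsO spreads of the operated (left) paw in pixels.
#' @param tsC,itsC spreads of the control (right) paw in pixels.
#' @param jitterSd per-frame centroid jitter sd (pixels).
#' @param seed scene seed.
#' @param frameSize c(width, height).
#' @param ... further arguments to [sceneSpec()].
#' @return Invisibly, the output path.
#' @export
simulateVideo <- function(out, nFrames = 100L, tsO = 60, itsO = 30,
                          tsC = 80, itsC = 40, jitterSd = 1, seed = 0L,
                          frameSize = c(1920, 1080), ...) {
  spec <- sceneSpec(frameSize = frameSize, tsLeft = tsO, itsLeft = itsO,
                    tsRight = tsC, itsRight = itsC, jitterSd = jitterSd,
                    seed = seed, ...)
  renderVideo(spec, nFrames, out)
}
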