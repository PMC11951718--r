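#' Open a video as a frame stream
#'
#' Supported containers:
#' \itemize{
#'   \item multi-page TIFF (`.tif`, `.tiff`) via the tiff package;
#'   \item a directory of PNG or TIFF frames (lexicographic order);
#'   \item MP4 (`.mp4`) when an `ffmpeg` executable is on the PATH, which
#'     decodes frames to a temporary directory.
#' }
#' Frames are returned as grayscale matrices in [0, 1] with rows = y.
#' `stride` subsamples the stream: stride 2 yields source frames
#' 0, 2, 4, ...
#'
#' @param path video file or frame directory.
#' @param stride keep every stride-th frame.
#' @return A [FrameSource-class].
#' @export
readFrames <- function(path, stride = 1L) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  if (!file.exists(path)) stop(sprintf("video not found: %s", path))
  name <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  fps <- NA_real_
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop(sprintf("no frame images in %s", path))
    name <- basename(path)
    reader <- function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE))
        asGrayMatrix(png::readPNG(f))
      else asGrayMatrix(tiff::readTIFF(f))
    }
    total <- length(files)
    keep <- seq(1L, total, by = stride)
    getFrame <- function(i) reader(files[keep[i]])
  } else if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(frames) || (is.array(frames) && length(dim(frames)) == 3L))
      frames <- list(frames)
    total <- length(frames)
    keep <- seq(1L, total, by = stride)
    getFrame <- function(i) asGrayMatrix(frames[[keep[i]]])
  } else if (ext == "mp4") {
    if (Sys.which("ffmpeg") == "")
      stop(sprintf("cannot decode %s: MP4 support requires an 'ffmpeg' executable on the PATH", path))
    tmp <- file.path(tempdir(), paste0("frames_", name, "_", Sys.getpid()))
    dir.create(tmp, showWarnings = FALSE, recursive = TRUE)
    status <- system2("ffmpeg",
                      c("-y", "-loglevel", "error", "-i", shQuote(path),
                        file.path(tmp, "frame_%06d.png")),
                      stdout = FALSE, stderr = FALSE)
    files <- sort(list.files(tmp, pattern = "\\.png$", full.names = TRUE))
    if (status != 0L || length(files) == 0L)
      stop(sprintf("ffmpeg failed to decode %s", path))
    total <- length(files)
    keep <- seq(1L, total, by = stride)
    getFrame <- function(i) asGrayMatrix(png::readPNG(files[keep[i]]))
  } else {
    stop(sprintf("unsupported video container '.%s' (%s)", ext, path))
  }
  new("FrameSource", name = name, nFrames = length(keep), fps = fps,
      frameIndex = as.integer((keep - 1L)), getFrame = getFrame)
}

# Encode frames to MP4 through ffmpeg (near-lossless profile).
writeMp4 <- function(frames, out, fps = 30) {
  if (Sys.which("ffmpeg") == "")
    stop("MP4 encoding requires an 'ffmpeg' executable on the PATH; ",
         "use a .tif output instead")
  tmp <- file.path(tempdir(), paste0("enc_", basename(out), "_", Sys.getpid()))
  dir.create(tmp, showWarnings = FALSE, recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]], file.path(tmp, sprintf("frame_%06d.png", i)))
  status <- system2("ffmpeg",
                    c("-y", "-loglevel", "error", "-framerate", fps,
                      "-i", file.path(tmp, "frame_%06d.png"),
                      "-c:v", "libx264", "-qp", "0", "-pix_fmt", "yuv444p",
                      shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop(sprintf("ffmpeg failed to encode %s", out))
  invisible(out)
}

#' Read a crop configuration
#'
#' The crop configuration replaces the interactive cropping step: a YAML
#' file mapping each video name to its 4-point ROI polygon (8 numbers,
#' `x1,y1,...,x4,y4`, 0-based pixels in click order) and, optionally, a
#' per-video `operated_side`. A `default` entry (with `full_frame: true`
#' or an explicit `roi`) applies to videos without their own entry.
#'
#' @param path YAML file.
#' @return List of class `cropConfig`.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("videos:", "  vid1:", "    roi: [0,0, 100,0, 100,80, 0,80]",
#'              "default:", "  full_frame: true"), cfg)
#' readCropConfig(cfg)
#' @export
readCropConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("crop config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$videos)) cfg$videos <- list()
  structure(cfg, class = "cropConfig")
}

#' Write a crop configuration
#'
#' @param config `cropConfig` list (or plain list with a `videos` element).
#' @param path output YAML file.
#' @return Invisibly, `path`.
#' @export
writeCropConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Add or replace one video's crop entry
#'
#' @param config `cropConfig` (or `NULL` to start a new one).
#' @param video video name (file stem).
#' @param roi 8 numbers `x1,y1,...,x4,y4`.
#' @param operatedSide optional per-video operated side override.
#' @return Updated `cropConfig`.
#' @export
setCropEntry <- function(config, video, roi, operatedSide = NULL) {
  if (is.null(config)) config <- structure(list(videos = list()),
                                           class = "cropConfig")
  checkRoiPolygon(as.numeric(roi))
  entry <- list(roi = as.numeric(roi))
  if (!is.null(operatedSide)) entry$operated_side <- operatedSide
  config$videos[[video]] <- entry
  config
}

# Resolve the ROI polygon (4x2 matrix or NULL for full frame) and the
# operated side for one video.
lookupCrop <- function(config, video, operatedSide) {
  entry <- NULL
  if (!is.null(config)) {
    entry <- config$videos[[video]]
    if (is.null(entry)) entry <- config$default
  }
  if (is.null(entry))
    stop(sprintf("no crop entry (and no default) for video '%s'", video))
  roi <- NULL
  if (!isTRUE(entry$full_frame)) {
    if (is.null(entry$roi))
      stop(sprintf("crop entry for '%s' has neither 'roi' nor 'full_frame: true'", video))
    roi <- checkRoiPolygon(as.numeric(entry$roi))
  }
  if (!is.null(entry$operated_side)) operatedSide <- entry$operated_side
  list(roi = roi, operatedSide = match.arg(operatedSide, c("left", "right")))
}

#' Write per-video measurement tables
#'
#' Writes `<video>.xlsx` with two sheets -- `measurements` (one row per
#' labeled frame: frame_index, TSo, ITSo, TSc, ITSc, TSF, ITSF, SSI,
#' outlier) and `summary` (the [VideoSummary-class] fields) -- plus a CSV
#' mirror of the measurements sheet (`<video>.csv`, numbers at 6 decimal
#' places).
#'
#' @param records data.frame from [ssiRecords()].
#' @param summary a [VideoSummary-class].
#' @param outDir output directory (created if needed).
#' @param videoName file stem for the outputs.
#' @return Invisibly, named character vector of the files written.
#' @export
writeResults <- function(records, summary, outDir, videoName) {
  stopifnot(is(summary, "VideoSummary"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", outDir))
  sumDf <- data.frame(
    n_frames_total = summary@nFramesTotal,
    n_frames_labeled = summary@nFramesLabeled,
    n_frames_retained = summary@nFramesRetained,
    n_sampled = summary@nSampled,
    mean_ssi = summary@meanSsi, sd_ssi = summary@sdSsi,
    median_ssi = summary@medianSsi, q25_ssi = summary@q25Ssi,
    q75_ssi = summary@q75Ssi,
    retention_fraction = summary@retentionFraction,
    qc_pass = summary@qcPass,
    qc_reasons = paste(summary@qcReasons, collapse = ";"))
  xlsxPath <- file.path(outDir, paste0(videoName, ".xlsx"))
  csvPath <- file.path(outDir, paste0(videoName, ".csv"))
  writeXlsx(list(measurements = records, summary = sumDf), xlsxPath)
  fmt <- records
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.6f", fmt[[j]])
  utils::write.csv(fmt, csvPath, row.names = FALSE, quote = FALSE)
  invisible(c(xlsx = xlsxPath, csv = csvPath))
}
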