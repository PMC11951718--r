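#' Describe a synthetic under-box scene
#'
#' Builds a [SceneSpec-class] for the synthetic renderer. The scene
#' emulates the geometry of an under-box recording of a light-coated rat:
#' a bright body ellipse on a darker noisy background with two hind paws
#' of five bright digit blobs trailing the body, plus optional artifacts
#' (a bright reflective patch, occlusion of one paw).
#'
#' Digit blob centers are placed as a symmetric fan: lateral offsets
#' (-ts/2, -its/2, 0, its/2, ts/2) from the paw center along the axis
#' perpendicular to the heading, with a symmetric longitudinal bow, so the
#' requested chords |digit1 - digit5| = ts and |digit2 - digit4| = its are
#' exact by construction for any its < ts.
#'
#' @param frameSize c(width, height); the default matches full-HD video.
#' @param tsLeft,itsLeft,tsRight,itsRight requested spreads (pixels).
#' @param bodyCenter,bodySemiAxes,headingDeg body ellipse geometry; the
#'   defaults center the animal and scale with the frame.
#' @param pawLateralOffset,pawCaudalOffset paw-center placement (pixels);
#'   defaults keep digits clear of the body so components stay separate.
#' @param blobRadius,bodyIntensity,digitIntensity,background,noiseSd
#'   rendering intensities and noise (intensity units in [0, 1]).
#' @param jitterSd per-frame digit-centroid jitter sd (pixels).
#' @param reflectivePatch `c(x, y, w, h, intensity)` or `NULL`.
#' @param occludePaw `"none"`, `"left"` or `"right"`.
#' @param seed integer; all noise and jitter derive from it.
#' @return A validated [SceneSpec-class].
#' @examples
#' sp <- sceneSpec(tsLeft = 60, itsLeft = 30, tsRight = 80, itsRight = 40)
#' expectedSsi(sp, operatedSide = "left")  # -39.565
#' @export
sceneSpec <- function(frameSize = c(1920, 1080),
                      tsLeft = 60, itsLeft = 30,
                      tsRight = 80, itsRight = 40,
                      bodyCenter = frameSize / 2 + c(0, -0.12 * frameSize[2]),
                      bodySemiAxes = c(0.16, 0.065) * frameSize[1],
                      headingDeg = -90,
                      pawLateralOffset = max(tsLeft, tsRight) * 0.75 + 30,
                      pawCaudalOffset = bodySemiAxes[1] * 1.25 + 40,
                      blobRadius = 9,
                      bodyIntensity = 0.85, digitIntensity = 1,
                      background = 0.12, noiseSd = 0.03,
                      jitterSd = 0, reflectivePatch = NULL,
                      occludePaw = "none", seed = 0L) {
  new("SceneSpec", frameSize = as.numeric(frameSize),
      bodyCenter = as.numeric(bodyCenter),
      bodySemiAxes = as.numeric(bodySemiAxes),
      headingDeg = as.numeric(headingDeg),
      spreads = list(left = c(ts = tsLeft, its = itsLeft),
                     right = c(ts = tsRight, its = itsRight)),
      pawLateralOffset = pawLateralOffset,
      pawCaudalOffset = pawCaudalOffset,
      blobRadius = blobRadius, bodyIntensity = bodyIntensity,
      digitIntensity = digitIntensity, background = background,
      noiseSd = noiseSd, jitterSd = jitterSd,
      reflectivePatch = if (is.null(reflectivePatch)) numeric(0)
                        else as.numeric(reflectivePatch),
      occludePaw = occludePaw, seed = as.integer(seed))
}

# Unjittered digit centers of one paw: 5 x 2 matrix, rows = digits 1-5
# (medial to lateral). Heading h, outward lateral unit p (away from the
# body axis on that side).
pawDigitCenters <- function(spec, side) {
  th <- spec@headingDeg * pi / 180
  h <- c(cos(th), sin(th))
  pLeft <- c(-h[2], h[1])        # animal's left, ventral view, y-down
  p <- if (side == "left") pLeft else -pLeft
  sp <- spec@spreads[[side]]
  ts <- sp[["ts"]]; its <- sp[["its"]]
  lat <- c(-ts / 2, -its / 2, 0, its / 2, ts / 2)
  bow <- 0.25 * ts * (1 - (2 * lat / ts)^2)   # symmetric: chords exact
  pc <- spec@bodyCenter - h * spec@pawCaudalOffset + p * spec@pawLateralOffset
  centers <- t(vapply(1:5, function(i) pc + p * lat[i] - h * bow[i],
                      numeric(2)))
  dimnames(centers) <- list(paste0("digit", 1:5), c("x", "y"))
  centers
}

#' Expected SSI of a scene
#'
#' Applies the toe-spread-factor and SSI formulas to the requested
#' (ground-truth) spreads of a scene.
#'
#' @param spec a [SceneSpec-class].
#' @param operatedSide which paw is treated as operated.
#' @param coeffs an [SSICoefficients-class].
#' @return The expected SSI (scalar).
#' @export
expectedSsi <- function(spec, operatedSide = c("left", "right"),
                        coeffs = ssiCoefficients()) {
  operatedSide <- match.arg(operatedSide)
  controlSide <- setdiff(c("left", "right"), operatedSide)
  o <- spec@spreads[[operatedSide]]; c0 <- spec@spreads[[controlSide]]
  ssiFromSpreads(spreadPair(o[["ts"]], c0[["ts"]], o[["its"]], c0[["its"]]),
                 coeffs)$ssi
}

#' Render one synthetic frame
#'
#' Draws the noisy background, the body ellipse, the digit blobs
#' (Gaussian intensity profile, sd = blobRadius / 2) and any reflective
#' patch. Per-frame jitter and noise come from a generator seeded by
#' (scene seed, frame index), so any frame can be re-rendered identically
#' in isolation. Ground truth is recorded after jitter.
#'
#' @param spec a [SceneSpec-class].
#' @param frameIndex 0-based frame ordinal.
#' @return List with `image` (matrix in [0, 1], rows = y) and
#'   `groundTruth`: digit centers per rendered paw (post-jitter), the
#'   requested spreads, the realized (post-jitter) spreads, and the body
#'   ellipse parameters.
#' @export
renderFrame <- function(spec, frameIndex = 0L) {
  stopifnot(is(spec, "SceneSpec"))
  w <- spec@frameSize[1]; h <- spec@frameSize[2]
  withLocalSeed(frameSeed(spec@seed, frameIndex), {
    img <- matrix(spec@background, h, w)
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(w * h, 0, spec@noiseSd), h, w)
    if (length(spec@reflectivePatch) == 5L) {
      rp <- spec@reflectivePatch
      xs <- max(1, floor(rp[1]) + 1):min(w, floor(rp[1] + rp[3]))
      ys <- max(1, floor(rp[2]) + 1):min(h, floor(rp[2] + rp[4]))
      img[ys, xs] <- rp[5]
    }
    img <- drawEllipse(img, spec@bodyCenter, spec@bodySemiAxes,
                       spec@headingDeg, spec@bodyIntensity)
    sides <- setdiff(c("left", "right"), spec@occludePaw)
    gt <- list()
    for (side in sides) {
      centers <- pawDigitCenters(spec, side)
      if (spec@jitterSd > 0)
        centers <- centers + matrix(stats::rnorm(10, 0, spec@jitterSd), 5, 2)
      if (any(centers[, 1] < 0 | centers[, 1] > w - 1 |
              centers[, 2] < 0 | centers[, 2] > h - 1))
        stop("sceneSpec places digits outside the frame")
      for (i in 1:5)
        img <- drawBlob(img, centers[i, ], spec@blobRadius,
                        spec@digitIntensity, spec@background)
      gt[[side]] <- centers
    }
    realized <- lapply(gt, function(m)
      c(ts = pointDist(m[1, ], m[5, ]), its = pointDist(m[2, ], m[4, ])))
    list(image = pmin(pmax(img, 0), 1),
         groundTruth = list(frameIndex = as.integer(frameIndex),
                            digits = gt,
                            requestedSpreads = spec@spreads[sides],
                            realizedSpreads = realized,
                            body = list(center = spec@bodyCenter,
                                        semiAxes = spec@bodySemiAxes,
                                        headingDeg = spec@headingDeg)))
  })
}

# Fill an ellipse (rotated) with the given intensity.
drawEllipse <- function(img, center, semiAxes, angleDeg, intensity) {
  h <- nrow(img); w <- ncol(img)
  th <- angleDeg * pi / 180
  a <- semiAxes[1]; b <- semiAxes[2]
  x0 <- max(1, floor(center[1] - a)); x1 <- min(w, ceiling(center[1] + a) + 1)
  y0 <- max(1, floor(center[2] - a)); y1 <- min(h, ceiling(center[2] + a) + 1)
  xs <- (x0:x1) - 1; ys <- (y0:y1) - 1
  dx <- outer(ys - center[2], xs - center[1], function(yy, xx) xx)
  dy <- outer(ys - center[2], xs - center[1], function(yy, xx) yy)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[y0:y1, x0:x1, drop = FALSE]
  sub[inside] <- intensity
  img[y0:y1, x0:x1] <- sub
  img
}

# Add a Gaussian-profile blob: intensity decays from `peak` at the center
# toward the background; drawn in a local window of 3 sd.
drawBlob <- function(img, center, radius, peak, background) {
  h <- nrow(img); w <- ncol(img)
  sd <- radius / 2
  r <- ceiling(3 * sd)
  x0 <- max(1, floor(center[1]) - r + 1); x1 <- min(w, floor(center[1]) + r + 1)
  y0 <- max(1, floor(center[2]) - r + 1); y1 <- min(h, floor(center[2]) + r + 1)
  xs <- (x0:x1) - 1; ys <- (y0:y1) - 1
  d2 <- outer((ys - center[2])^2, (xs - center[1])^2, "+")
  g <- (peak - background) * exp(-d2 / (2 * sd^2))
  img[y0:y1, x0:x1] <- pmax(img[y0:y1, x0:x1], background + g)
  img
}

#' A frame source that renders a synthetic video on demand
#'
#' Frames are rendered lazily by [renderFrame()]; nothing is written to
#' disk. Useful for large property checks where encoding a real file
#' would dominate the runtime.
#'
#' @param spec a [SceneSpec-class].
#' @param nFrames number of frames in the synthetic video.
#' @param name video name used for outputs.
#' @return A [FrameSource-class].
#' @export
syntheticFrameSource <- function(spec, nFrames, name = "synthetic") {
  stopifnot(is(spec, "SceneSpec"), nFrames >= 1)
  new("FrameSource", name = name, nFrames = as.integer(nFrames),
      fps = NA_real_, frameIndex = seq_len(nFrames) - 1L,
      getFrame = function(i) renderFrame(spec, i - 1L)$image)
}

#' Ground-truth table of a synthetic video
#'
#' @param spec a [SceneSpec-class].
#' @param nFrames frames to tabulate.
#' @return data.frame with one row per frame and rendered paw: frame
#'   index, side, requested and realized ts/its, and the 5 digit
#'   centroids.
#' @export
groundTruthTable <- function(spec, nFrames) {
  rows <- lapply(seq_len(nFrames) - 1L, function(fi) {
    gt <- renderFrame(spec, fi)$groundTruth
    do.call(rbind, lapply(names(gt$digits), function(side) {
      m <- gt$digits[[side]]
      data.frame(frame_index = fi, side = side,
                 ts_requested = gt$requestedSpreads[[side]][["ts"]],
                 its_requested = gt$requestedSpreads[[side]][["its"]],
                 ts_realized = gt$realizedSpreads[[side]][["ts"]],
                 its_realized = gt$realizedSpreads[[side]][["its"]],
                 x1 = m[1, 1], y1 = m[1, 2], x2 = m[2, 1], y2 = m[2, 2],
                 x3 = m[3, 1], y3 = m[3, 2], x4 = m[4, 1], y4 = m[4, 2],
                 x5 = m[5, 1], y5 = m[5, 2])
    }))
  })
  do.call(rbind, rows)
}

#' Render a synthetic video to disk
#'
#' Writes the rendered frames to a video container plus a ground-truth
#' CSV (`<stem>_groundtruth.csv`). Containers: multi-page TIFF (`.tif` /
#' `.tiff`, deflate-compressed, effectively lossless), a directory of PNG
#' frames (path without extension), or MP4 when an `ffmpeg` executable is
#' available on the PATH.
#'
#' @param spec a [SceneSpec-class].
#' @param nFrames frames to render.
#' @param out output path; the extension selects the container.
#' @return Invisibly, the output path.
#' @export
renderVideo <- function(spec, nFrames, out) {
  ext <- tolower(tools::file_ext(out))
  frames <- lapply(seq_len(nFrames) - 1L, function(fi) renderFrame(spec, fi)$image)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(frames, out, bits.per.sample = 16L,
                    compression = "deflate")
  } else if (ext == "mp4") {
    writeMp4(frames, out)
  } else if (ext == "") {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frames))
      png::writePNG(frames[[i]], file.path(out, sprintf("frame_%05d.png", i - 1L)))
  } else stop(sprintf("unsupported video container '.%s'", ext))
  gtPath <- paste0(sub("\\.[A-Za-z0-9]+$", "", out), "_groundtruth.csv")
  utils::write.csv(groundTruthTable(spec, nFrames), gtPath, row.names = FALSE)
  invisible(out)
}
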