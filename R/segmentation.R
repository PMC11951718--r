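#' Segmentation backend parameters
#'
#' Settings of the frame segmentation backend. Area limits are defined at
#' the 1920x1080 reference resolution and scaled by frame area for other
#' resolutions, so the same configuration works across cameras.
#'
#' @param backend `"classical"` (shipped baseline) or `"cnn"` (contract
#'   slot for a plug-in network backend; none ships with the package).
#' @param invert set TRUE when the animal is darker than the background;
#'   the baseline assumes a light-coated animal on a darker background.
#' @param areaRange digit candidate area limits in px^2 at 1080p.
#' @param bodyMinArea minimum body component area in px^2 at 1080p.
#' @param solidityMin minimum candidate solidity (convexity) in [0, 1].
#' @param maxCandidates at most this many candidates are returned (largest
#'   by area).
#' @param openingRadius disk radius (pixels) of the morphological opening
#'   applied to the binary image before labeling.
#' @return Named list of parameters.
#' @export
segmentationParams <- function(backend = c("classical", "cnn"),
                               invert = FALSE,
                               areaRange = c(30, 2000),
                               bodyMinArea = 5000,
                               solidityMin = 0.7,
                               maxCandidates = 10L,
                               openingRadius = 1L) {
  list(backend = match.arg(backend), invert = invert,
       areaRange = areaRange, bodyMinArea = bodyMinArea,
       solidityMin = solidityMin, maxCandidates = as.integer(maxCandidates),
       openingRadius = as.integer(openingRadius))
}

#' Mask a frame to a region of interest
#'
#' Sets every pixel outside the 4-vertex ROI polygon to zero. Frame
#' dimensions are preserved (masking, not cropping), so all downstream
#' coordinates stay in the original frame system.
#'
#' @param frame numeric matrix (rows = y) or h x w x channel array.
#' @param roi 4x2 vertex matrix or 8 numbers `x1,y1,...,x4,y4` (0-based
#'   pixel coordinates, click order); `NULL` leaves the frame untouched.
#' @param mask optional precomputed logical mask from [roiMask()]; supply
#'   it when processing many frames with the same ROI.
#' @return Masked grayscale matrix.
#' @examples
#' f <- matrix(1, 20, 20)
#' g <- applyRoi(f, c(0, 0, 9, 0, 9, 19, 0, 19))  # left half kept
#' @export
applyRoi <- function(frame, roi, mask = NULL) {
  frame <- asGrayMatrix(frame)
  if (is.null(roi) && is.null(mask)) return(frame)
  if (is.null(mask))
    mask <- roiMask(roi, ncol(frame), nrow(frame))
  frame * mask
}

#' Rasterise an ROI polygon
#'
#' @param roi 4-vertex polygon (see [applyRoi()]).
#' @param width,height frame size in pixels.
#' @return Logical matrix, TRUE inside the polygon.
#' @export
roiMask <- function(roi, width, height) {
  v <- checkRoiPolygon(roi, width, height)
  polygonMask(v, width, height)
}

#' Segment one frame into body mask and digit candidates
#'
#' The classical baseline: grayscale conversion, Otsu threshold computed
#' within the ROI, morphological opening (disk radius `openingRadius`),
#' connected-component labeling. The largest bright component is the body;
#' remaining compact bright components within the area and solidity limits
#' become digit candidates. A paw-sized component (larger than the digit
#' maximum) containing two or more intensity peaks is split by
#' nearest-peak assignment. Centroids are intensity-weighted.
#'
#' The backend contract (image in, [FrameDetection-class] out) is what the
#' rest of the pipeline depends on; a trained network honouring the same
#' contract can replace the baseline via `params$backend`.
#'
#' @param frame numeric matrix in [0, 1] (rows = y) or h x w x c array.
#' @param roi optional ROI polygon (see [applyRoi()]).
#' @param params list from [segmentationParams()].
#' @param frameIndex 0-based frame ordinal recorded in the result.
#' @param mask optional precomputed ROI mask ([roiMask()]).
#' @return A [FrameDetection-class] object. When no body-sized component
#'   exists the reject reason is `"NO_ANIMAL"`.
#' @export
segmentFrame <- function(frame, roi = NULL, params = segmentationParams(),
                         frameIndex = 0L, mask = NULL) {
  if (params$backend == "cnn")
    stop("no trained CNN backend ships with this package; ",
         "use backend = 'classical' or plug in a model honouring the ",
         "FrameDetection contract")
  img <- asGrayMatrix(frame)
  h <- nrow(img); w <- ncol(img)
  if (!is.null(roi) || !is.null(mask)) {
    if (is.null(mask)) mask <- roiMask(roi, w, h)
    img <- img * mask
  } else mask <- NULL
  scale <- (w * h) / (1920 * 1080)
  areaMin <- max(params$areaRange[1] * scale, 4)
  areaMax <- params$areaRange[2] * scale
  bodyMin <- params$bodyMinArea * scale

  roiPix <- if (is.null(mask)) img else img[mask]
  thr <- otsuThreshold(roiPix)
  bin <- if (params$invert) (img < thr) & (if (is.null(mask)) TRUE else mask)
         else img > thr
  # a threshold that floods most of the ROI means there is no figure to
  # separate from the ground (blank or saturated frame)
  nRoi <- if (is.null(mask)) length(img) else sum(mask)
  if (sum(bin) > 0.6 * nRoi) {
    return(new("FrameDetection", frameIndex = as.integer(frameIndex),
               bodyMask = matrix(FALSE, 0, 0), bodyArea = 0,
               candidates = emptyCandidates(), rejectReason = "NO_ANIMAL"))
  }

  # opening removes speckle noise below the structuring element
  eb <- EBImage::Image(t(bin))
  if (params$openingRadius > 0) {
    brush <- EBImage::makeBrush(2L * params$openingRadius + 1L, shape = "disc")
    eb <- EBImage::opening(eb, brush)
  }
  lab <- t(EBImage::imageData(EBImage::bwlabel(eb)))
  noDetection <- function(reason) {
    new("FrameDetection", frameIndex = as.integer(frameIndex),
        bodyMask = matrix(FALSE, 0, 0), bodyArea = 0,
        candidates = emptyCandidates(), rejectReason = reason)
  }
  nlab <- max(lab)
  if (nlab == 0L) return(noDetection("NO_ANIMAL"))

  idx <- which(lab > 0)
  li <- lab[idx]
  areas <- tabulate(li, nlab)
  bodyLab <- which.max(areas)
  if (areas[bodyLab] < bodyMin) return(noDetection("NO_ANIMAL"))

  ys <- ((idx - 1L) %% h)          # 0-based y
  xs <- ((idx - 1L) %/% h)         # 0-based x
  wt <- img[idx]
  sw <- rowsum(wt, li)
  cx <- rowsum(wt * xs, li) / sw
  cy <- rowsum(wt * ys, li) / sw
  meanInt <- sw / areas

  bodyMask <- matrix(FALSE, h, w)
  bodyMask[idx[li == bodyLab]] <- TRUE

  cand <- data.frame(label = seq_len(nlab), x = as.numeric(cx),
                     y = as.numeric(cy), area = areas,
                     meanIntensity = as.numeric(meanInt),
                     solidity = NA_real_)
  cand <- cand[cand$label != bodyLab, , drop = FALSE]

  # split paw-sized merged components before the area filter
  merged <- cand[cand$area > areaMax & cand$area < areas[bodyLab], , drop = FALSE]
  cand <- cand[cand$area <= areaMax, , drop = FALSE]
  for (lb in merged$label) {
    pieces <- splitByIntensityPeaks(img, lab, lb, h)
    if (!is.null(pieces)) cand <- rbind(cand, pieces)
  }

  keep <- cand$area >= areaMin & cand$area <= areaMax
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand)) {
    sol <- vapply(seq_len(nrow(cand)), function(i) {
      if (!is.na(cand$solidity[i])) return(cand$solidity[i])
      ii <- idx[li == cand$label[i]]
      blobSolidity((ii - 1L) %/% h, (ii - 1L) %% h)
    }, numeric(1))
    cand <- cand[sol >= params$solidityMin, , drop = FALSE]
  }
  ord <- order(-cand$area, cand$x, cand$y)
  cand <- cand[utils::head(ord, params$maxCandidates), , drop = FALSE]
  rownames(cand) <- NULL
  new("FrameDetection", frameIndex = as.integer(frameIndex),
      bodyMask = bodyMask, bodyArea = as.numeric(areas[bodyLab]),
      candidates = cand[, c("x", "y", "area", "meanIntensity"), drop = FALSE],
      rejectReason = NA_character_)
}

emptyCandidates <- function() {
  data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
             meanIntensity = numeric(0))
}

# Split component `lb` of label matrix `lab` by its intensity peaks:
# local maxima (3x3, plateau-merged) of the intensity inside the
# component; each pixel is assigned to the nearest peak. Returns a
# candidate data.frame (solidity precomputed) or NULL if < 2 peaks.
splitByIntensityPeaks <- function(img, lab, lb, h) {
  ii <- which(lab == lb)
  ys <- (ii - 1L) %% h
  xs <- (ii - 1L) %/% h
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  sub <- img[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE]
  inMask <- matrix(FALSE, nrow(sub), ncol(sub))
  inMask[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- TRUE
  sub[!inMask] <- 0
  # 3x3 max filter via dilation in EBImage
  mx <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(sub)), EBImage::makeBrush(3L, shape = "box"))))
  peaks <- which(inMask & sub >= mx & sub > 0, arr.ind = TRUE)
  if (nrow(peaks) < 2L) return(NULL)
  # merge plateau/adjacent peaks closer than 3 px (greedy)
  px <- peaks[, 2] - 1L + x0; py <- peaks[, 1] - 1L + y0
  keep <- rep(TRUE, length(px))
  for (i in seq_along(px)) if (keep[i]) {
    d2 <- (px - px[i])^2 + (py - py[i])^2
    keep[d2 < 9 & seq_along(px) > i] <- FALSE
  }
  px <- px[keep]; py <- py[keep]
  if (length(px) < 2L) return(NULL)
  d2 <- outer(xs, px, "-")^2 + outer(ys, py, "-")^2
  assign <- max.col(-d2, ties.method = "first")
  wt <- img[ii]
  out <- lapply(seq_along(px), function(k) {
    sel <- assign == k
    if (!any(sel)) return(NULL)
    wk <- wt[sel]
    data.frame(label = NA_integer_,
               x = sum(wk * xs[sel]) / sum(wk),
               y = sum(wk * ys[sel]) / sum(wk),
               area = sum(sel), meanIntensity = mean(wk),
               solidity = blobSolidity(xs[sel], ys[sel]))
  })
  do.call(rbind, out)
}
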