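#' Body centroid and principal axis
#'
#' Computes the body centroid and the major principal axis from the
#' second-order central moments of the body mask (the orientation of the
#' equivalent ellipse). The axis direction is sign-ambiguous until the
#' heading is resolved with [resolveHeading()]. Near-isotropic masks
#' (moment eigenvalue ratio above `degenerateRatio`) are flagged
#' degenerate: any direction is as good as another.
#'
#' @param bodyMask logical (or 0/1) matrix, rows = y.
#' @param degenerateRatio eigenvalue ratio (minor/major) above which the
#'   axis is considered undefined.
#' @return A [BodyAxis-class] object with heading unresolved.
#' @export
bodyAxis <- function(bodyMask, degenerateRatio = 0.9) {
  idx <- which(bodyMask != 0)
  if (length(idx) == 0L) stop("bodyAxis: empty body mask")
  h <- nrow(bodyMask)
  ys <- (idx - 1L) %% h
  xs <- (idx - 1L) %/% h
  n <- length(idx)
  mx <- mean(xs); my <- mean(ys)
  dx <- xs - mx; dy <- ys - my
  mu20 <- sum(dx * dx) / n
  mu02 <- sum(dy * dy) / n
  mu11 <- sum(dx * dy) / n
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2) / 2
  lam1 <- (mu20 + mu02) / 2 + common
  lam2 <- (mu20 + mu02) / 2 - common
  degen <- lam1 <= 0 || (lam2 / lam1) > degenerateRatio
  new("BodyAxis", centroid = c(mx, my),
      direction = c(cos(theta), sin(theta)),
      headingSign = 0, majorAxisLength = 4 * sqrt(max(lam1, 0)),
      degenerate = degen, ambiguous = FALSE)
}

#' Resolve which end of the body axis is the head
#'
#' Hind paws trail the body: the mean digit-candidate position must lie on
#' the caudal side of the body centroid, so the heading sign is chosen to
#' point away from the digit cloud. When the digit mean projects within
#' `tol` of the centroid the heading is flagged ambiguous and such frames
#' are dropped rather than guessed.
#'
#' @param axis a [BodyAxis-class] from [bodyAxis()].
#' @param digits data.frame with `x`, `y` columns (digit candidates) or an
#'   n x 2 matrix.
#' @param tol projection tolerance in pixels; default scales with body
#'   length.
#' @return The axis with `headingSign` set (and possibly `ambiguous`).
#' @export
resolveHeading <- function(axis, digits, tol = NULL) {
  stopifnot(is(axis, "BodyAxis"))
  xy <- digitMatrix(digits)
  if (nrow(xy) < 1L) stop("resolveHeading: no digit candidates")
  if (is.null(tol)) tol <- max(2, 0.02 * axis@majorAxisLength)
  m <- colMeans(xy)
  proj <- sum((m - axis@centroid) * axis@direction)
  axis@ambiguous <- abs(proj) <= tol
  axis@headingSign <- if (proj >= 0) -1 else 1
  axis
}

# Heading unit vector (points rostrally) of a resolved axis.
headingVector <- function(axis) {
  if (axis@headingSign == 0) stop("heading not resolved")
  axis@headingSign * axis@direction
}

digitMatrix <- function(digits) {
  if (is.data.frame(digits)) as.matrix(digits[, c("x", "y"), drop = FALSE])
  else matrix(digits, ncol = 2)
}

#' Partition digit candidates into left and right paws
#'
#' Candidates are split by the sign of the 2D cross product of the heading
#' vector with the centroid-to-candidate vector. The camera views the
#' animal's ventral side from below, so a positive cross product (in the
#' image's y-down coordinate system) is the animal's left; set
#' `flipLR = TRUE` for mirrored rigs. When more than 5 candidates fall on
#' one side, the 5 largest by area are kept (small noise blobs lose).
#'
#' @param candidates data.frame with `x`, `y`, `area`.
#' @param axis heading-resolved [BodyAxis-class].
#' @param flipLR swap the left/right convention.
#' @return List with elements `left` and `right`, each a data.frame of at
#'   most 5 candidates, plus `leftStatus`/`rightStatus` codes (`"OK"`,
#'   `"MISSING_DIGITS"` for 1-4 candidates, `"PAW_NOT_VISIBLE"` for none).
#' @export
splitPaws <- function(candidates, axis, flipLR = FALSE) {
  stopifnot(is(axis, "BodyAxis"))
  hv <- headingVector(axis)
  vx <- candidates$x - axis@centroid[1]
  vy <- candidates$y - axis@centroid[2]
  cross <- hv[1] * vy - hv[2] * vx
  leftSel <- if (flipLR) cross <= 0 else cross > 0
  pick <- function(df) {
    if (nrow(df) > 5L) {
      ord <- order(-df$area, df$x, df$y)
      df <- df[ord[1:5], , drop = FALSE]
    }
    rownames(df) <- NULL
    df
  }
  status <- function(df) {
    if (nrow(df) == 0L) "PAW_NOT_VISIBLE"
    else if (nrow(df) < 5L) "MISSING_DIGITS"
    else "OK"
  }
  left <- pick(candidates[leftSel, , drop = FALSE])
  right <- pick(candidates[!leftSel, , drop = FALSE])
  list(left = left, right = right,
       leftStatus = status(left), rightStatus = status(right))
}

#' Order a paw's digits from medial to lateral
#'
#' Digits are sorted by their unsigned perpendicular distance from the
#' body-axis line: digit 1 is the innermost toe (nearest the axis), digit
#' 5 the outermost. Ties are broken by distance to the body centroid, then
#' by x and y, keeping the ordering total and deterministic.
#'
#' @param paw data.frame (or 5 x 2 matrix) of exactly 5 digit centroids.
#' @param axis heading-resolved [BodyAxis-class].
#' @return 5 x 2 matrix of (x, y) centroids, rows = digits 1 to 5.
#' @export
orderDigits <- function(paw, axis) {
  xy <- digitMatrix(paw)
  if (nrow(xy) != 5L) stop("orderDigits: exactly 5 digit centroids required")
  d <- axis@direction
  vx <- xy[, 1] - axis@centroid[1]
  vy <- xy[, 2] - axis@centroid[2]
  perp <- abs(d[1] * vy - d[2] * vx)        # distance from the axis line
  toC <- vx^2 + vy^2
  ord <- order(perp, toC, xy[, 1], xy[, 2])
  out <- xy[ord, , drop = FALSE]
  dimnames(out) <- list(paste0("digit", 1:5), c("x", "y"))
  out
}

#' Toe spreads of an ordered paw
#'
#' TS is the Euclidean distance between the centroids of digits 1 and 5;
#' ITS between digits 2 and 4. Distances are in pixels; no physical
#' calibration is needed because the SSI uses only ratios.
#'
#' @param digits 5 x 2 matrix of ordered digit centroids ([orderDigits()]).
#' @return Named numeric vector `c(ts = ..., its = ...)`.
#' @examples
#' d <- cbind(x = c(0, 1, 2, 3, 4), y = c(0, 2, 3, 2, 0))
#' toeSpreads(d)  # ts = 4, its = 2
#' @export
toeSpreads <- function(digits) {
  stopifnot(is.matrix(digits), nrow(digits) == 5L)
  c(ts = pointDist(digits[1, ], digits[5, ]),
    its = pointDist(digits[2, ], digits[4, ]))
}

#' Measure one paw
#'
#' Orders the digits and computes the spreads, packaging the result.
#'
#' @param paw 5 digit centroids (data.frame or matrix).
#' @param axis heading-resolved [BodyAxis-class].
#' @param side `"left"` or `"right"`.
#' @return A [PawMeasurement-class] object.
#' @export
measurePaw <- function(paw, axis, side) {
  dg <- orderDigits(paw, axis)
  sp <- toeSpreads(dg)
  new("PawMeasurement", side = side, role = NA_character_,
      digits = dg, ts = unname(sp["ts"]), its = unname(sp["its"]))
}

#' Attach operated/control roles to the paw pair
#'
#' The experiment declares which side was operated; the contralateral paw
#' is the within-animal control. The operated paw's spreads become
#' (TSo, ITSo) and the control's (TSc, ITSc) of the [SpreadPair-class].
#'
#' @param left,right [PawMeasurement-class] objects for the two sides.
#' @param operatedSide `"left"` or `"right"`.
#' @return List with `operated`, `control` (role-stamped paw measurements)
#'   and `spreads` (a [SpreadPair-class]).
#' @export
assignRoles <- function(left, right, operatedSide = c("left", "right")) {
  operatedSide <- match.arg(operatedSide)
  stopifnot(is(left, "PawMeasurement"), is(right, "PawMeasurement"))
  if (left@side != "left" || right@side != "right")
    stop("assignRoles: pass the left paw first and the right paw second")
  op <- if (operatedSide == "left") left else right
  ct <- if (operatedSide == "left") right else left
  op@role <- "operated"; ct@role <- "control"
  list(operated = op, control = ct,
       spreads = spreadPair(op@ts, ct@ts, op@its, ct@its))
}
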