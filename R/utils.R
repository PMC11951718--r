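# Internal helpers shared across modules.

# Evaluate expr with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards. Keeps pipeline randomness independent of user
# code and bit-reproducible for a given seed.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-frame seed from a base seed; stays inside 32-bit range.
frameSeed <- function(seed, frameIndex) {
  as.integer((as.double(seed) * 7919 + as.double(frameIndex) * 104729) %%
               2147483587)
}

# Otsu threshold from a 256-bin histogram of intensities in [0, 1].
# Returns the bin-edge threshold maximising between-class variance;
# foreground is v > threshold.
otsuThreshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsuThreshold: no finite pixels")
  bin <- pmin(pmax(floor(v * nbins) + 1, 1L), nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / sum(counts)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[ok] <- (muT * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  k <- which.max(bcv)
  k / nbins
}

# Logical mask (rows = y, cols = x) of pixels whose centers fall inside
# or on the boundary of a simple polygon (even-odd rule plus explicit
# boundary inclusion). Vertices are 0-based pixel coordinates.
polygonMask <- function(vertices, width, height) {
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  inside <- rep(FALSE, width * height)
  onEdge <- rep(FALSE, width * height)
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # points lying on an edge segment count as inside
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      t <- ((px - xi) * ex + (py - yi) * ey) / len2
      cross <- (px - xi) * ey - (py - yi) * ex
      onEdge <- onEdge | (t >= 0 & t <= 1 & abs(cross) <= 1e-9 * sqrt(len2))
    }
    j <- i
  }
  matrix(inside | onEdge, nrow = height, ncol = width)
}

# Shoelace area of a polygon given as n x 2 matrix.
polygonArea <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Do segments p1-p2 and p3-p4 properly intersect?
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Validate a 4-vertex ROI polygon; returns the vertex matrix.
checkRoiPolygon <- function(roi, width = NULL, height = NULL) {
  v <- roi
  if (!is.matrix(v) && is.numeric(v) && length(v) == 8L)
    v <- matrix(v, ncol = 2, byrow = TRUE)
  if (!is.matrix(v) || !identical(dim(v), c(4L, 2L)))
    stop("ROI polygon must be 4 vertices (a 4x2 matrix or 8 numbers x1,y1,...,x4,y4)")
  # simple quadrilateral: non-adjacent edges must not cross
  if (segmentsIntersect(v[1, ], v[2, ], v[3, ], v[4, ]) ||
      segmentsIntersect(v[2, ], v[3, ], v[4, ], v[1, ]))
    stop("ROI polygon is self-intersecting")
  if (polygonArea(v) <= 0)
    stop("degenerate ROI polygon: zero area")
  if (!is.null(width)) {
    if (any(v[, 1] < 0 | v[, 1] > width - 1 | v[, 2] < 0 | v[, 2] > height - 1))
      stop("ROI polygon vertices fall outside the frame bounds")
  }
  v
}

# Solidity of a pixel blob: area / convex hull area, with each pixel
# treated as a unit square (hull over pixel corners), so compact blobs
# score ~1 regardless of size.
blobSolidity <- function(xs, ys) {
  n <- length(xs)
  if (n <= 2L) return(1)
  cx <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  cy <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  h <- grDevices::chull(cx, cy)
  ha <- polygonArea(cbind(cx[h], cy[h]))
  min(n / max(ha, 1), 1)
}

# Euclidean distance between two points given as length-2 vectors.
pointDist <- function(a, b) sqrt(sum((a - b)^2))

# Convert an image to a grayscale matrix (rows = y). Accepts matrices or
# h x w x channels arrays (Rec. 709 luma for 3+ channels).
asGrayMatrix <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3L) {
    if (dim(frame)[3] >= 3L)
      return(0.2126 * frame[, , 1] + 0.7152 * frame[, , 2] + 0.0722 * frame[, , 3])
    return(frame[, , 1])
  }
  stop("frame must be a matrix or an array with rows = y, cols = x")
}
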