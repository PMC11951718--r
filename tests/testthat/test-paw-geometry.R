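# Rasterise a filled ellipse mask (0-based pixel centers).
ellipseMask <- function(w, h, cx, cy, a, b, angleDeg = 0) {
  th <- angleDeg * pi / 180
  xs <- matrix(rep(0:(w - 1), each = h), h, w) - cx
  ys <- matrix(rep(0:(h - 1), times = w), h, w) - cy
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

angleDiffDeg <- function(a, b) {
  # axis directions are sign-ambiguous: compare modulo 180 degrees
  d <- abs(((a - b) %% 180 + 180) %% 180)
  min(d, 180 - d)
}

test_that("body axis recovers ellipse orientation from moments", {
  m <- ellipseMask(300, 300, 150, 150, 100, 30, 0)
  ax <- bodyAxis(m)
  expect_false(ax@degenerate)
  got <- atan2(ax@direction[2], ax@direction[1]) * 180 / pi
  expect_lt(angleDiffDeg(got, 0), 2)
  expect_equal(ax@centroid, c(150, 150), tolerance = 0.5)
  # major-axis length estimate ~ 2a for an ellipse
  expect_equal(ax@majorAxisLength, 200, tolerance = 6)

  m30 <- ellipseMask(300, 300, 150, 150, 100, 30, 30)
  got30 <- atan2(bodyAxis(m30)@direction[2], bodyAxis(m30)@direction[1]) * 180 / pi
  expect_lt(angleDiffDeg(got30, 30), 2)
  # agrees with an independent eigen-decomposition oracle
  idx <- which(m30)
  ys <- (idx - 1) %% 300; xs <- (idx - 1) %/% 300
  expect_lt(angleDiffDeg(got30, oracleAxisAngle(xs, ys) * 180 / pi), 0.5)
})

test_that("isotropic masks are flagged degenerate; empty masks error", {
  circ <- ellipseMask(120, 120, 60, 60, 40, 40)
  expect_true(bodyAxis(circ)@degenerate)
  expect_error(bodyAxis(matrix(FALSE, 10, 10)), "empty")
})

test_that("heading points away from the digit cloud and flips under mirroring", {
  m <- ellipseMask(300, 200, 150, 100, 90, 30, 0)
  ax <- bodyAxis(m)
  digitsLeftEnd <- data.frame(x = c(30, 35, 40, 45, 50), y = rep(100, 5))
  r <- resolveHeading(ax, digitsLeftEnd)
  hv <- r@headingSign * r@direction
  expect_gt(hv[1], 0.9)  # digits at left end -> heading points right
  expect_false(r@ambiguous)
  # mirrored scene: digits at the right end
  digitsRightEnd <- data.frame(x = 300 - digitsLeftEnd$x, y = digitsLeftEnd$y)
  r2 <- resolveHeading(ax, digitsRightEnd)
  expect_lt((r2@headingSign * r2@direction)[1], -0.9)
  # symmetric straddle -> ambiguous
  sym <- data.frame(x = c(50, 250, 50, 250, 150), y = rep(100, 5))
  expect_true(resolveHeading(ax, sym)@ambiguous)
})

test_that("paws split by the cross-product rule with ventral-view chirality", {
  ax <- new("BodyAxis", centroid = c(100, 100), direction = c(0, -1),
            headingSign = 1, majorAxisLength = 120,
            degenerate = FALSE, ambiguous = FALSE)
  # heading up-screen: animal's left is viewer's right (+x)
  cand <- data.frame(
    x = c(130, 135, 140, 145, 150, 70, 65, 60, 55, 50),
    y = rep(160, 10), area = rep(30, 10))
  sp <- splitPaws(cand, ax)
  expect_identical(sp$leftStatus, "OK")
  expect_identical(sp$rightStatus, "OK")
  expect_true(all(sp$left$x > 100))
  expect_true(all(sp$right$x < 100))
  # flipLR override swaps the convention
  spF <- splitPaws(cand, ax, flipLR = TRUE)
  expect_true(all(spF$left$x < 100))
})

test_that("oversubscribed sides keep the 5 largest; starved sides are flagged", {
  ax <- new("BodyAxis", centroid = c(100, 100), direction = c(0, -1),
            headingSign = 1, majorAxisLength = 120,
            degenerate = FALSE, ambiguous = FALSE)
  cand <- data.frame(x = c(130, 135, 140, 145, 150, 132),
                     y = rep(160, 6),
                     area = c(30, 31, 32, 33, 34, 5))  # small noise blob
  sp <- splitPaws(cand, ax)
  expect_identical(sp$leftStatus, "OK")
  expect_false(5 %in% sp$left$area)  # noise blob dropped
  expect_identical(sp$rightStatus, "PAW_NOT_VISIBLE")
  cand4 <- cand[1:4, ]
  expect_identical(splitPaws(cand4, ax)$leftStatus, "MISSING_DIGITS")
})

test_that("digits order medially to laterally, reversing under reflection", {
  ax <- new("BodyAxis", centroid = c(0, 0), direction = c(0, -1),
            headingSign = 1, majorAxisLength = 100,
            degenerate = FALSE, ambiguous = FALSE)
  # colinear perpendicular to the body axis
  paw <- cbind(x = c(30, 10, 50, 20, 40), y = rep(40, 5))
  ord <- orderDigits(paw, ax)
  expect_equal(ord[, "x"], c(10, 20, 30, 40, 50), ignore_attr = TRUE)
  # reflect across the body axis: order by distance is preserved mirror-wise
  pawR <- cbind(x = -paw[, 1], y = paw[, 2])
  ordR <- orderDigits(pawR, ax)
  expect_equal(ordR[, "x"], -c(10, 20, 30, 40, 50), ignore_attr = TRUE)
  expect_error(orderDigits(paw[1:4, ], ax), "exactly 5")
})

test_that("arc-arranged synthetic paws order like the renderer's digit indices", {
  spec <- smallScene(noiseSd = 0, seed = 3L)
  rf <- renderFrame(spec, 0L)
  det <- segmentFrame(rf$image)
  ax <- resolveHeading(bodyAxis(det@bodyMask), det@candidates)
  sp <- splitPaws(det@candidates, ax)
  for (side in c("left", "right")) {
    ord <- orderDigits(sp[[side]], ax)
    gt <- rf$groundTruth$digits[[side]]
    for (i in 1:5)
      expect_lt(sqrt(sum((ord[i, ] - gt[i, ])^2)), 1.5)
  }
})

test_that("toe spreads are the 1-5 and 2-4 centroid distances", {
  d <- cbind(x = c(0, 1, 2, 3, 4), y = c(0, 2, 3, 2, 0))
  sp <- toeSpreads(d)
  expect_equal(unname(sp["ts"]), 4)
  expect_equal(unname(sp["its"]), 2)
  # coincident digits give zero spreads (later rejected by QC)
  z <- matrix(1, 5, 2)
  expect_equal(unname(toeSpreads(z)), c(0, 0))
})

test_that("role assignment forwards the declared operated side", {
  ax <- new("BodyAxis", centroid = c(0, 0), direction = c(0, -1),
            headingSign = 1, majorAxisLength = 100,
            degenerate = FALSE, ambiguous = FALSE)
  left <- measurePaw(cbind(x = c(10, 20, 30, 40, 50), y = rep(40, 5)), ax, "left")
  right <- measurePaw(cbind(x = -c(12, 22, 32, 42, 52), y = rep(40, 5)), ax, "right")
  rl <- assignRoles(left, right, "left")
  expect_identical(rl$operated@side, "left")
  expect_equal(rl$spreads@tsO, left@ts)
  expect_equal(rl$spreads@tsC, right@ts)
  rr <- assignRoles(left, right, "right")
  expect_equal(rr$spreads@tsO, right@ts)
  expect_equal(rr$spreads@itsC, left@its)
})

test_that("the geometry chain is equivariant under rigid rotation and translation", {
  set.seed(42)
  baseAx <- new("BodyAxis", centroid = c(0, 0), direction = c(0, -1),
                headingSign = 1, majorAxisLength = 200,
                degenerate = FALSE, ambiguous = FALSE)
  mkPaw <- function(sgn) cbind(x = sgn * (20 + c(0, 8, 16, 24, 32)),
                               y = 60 + c(0, 4, 6, 4, 0) + rnorm(5, 0, 0.5))
  for (rep in 1:20) {
    L <- mkPaw(1); R <- mkPaw(-1)
    ssi0 <- ssiFromSpreads(assignRoles(
      measurePaw(L, baseAx, "left"), measurePaw(R, baseAx, "right"),
      "left")$spreads)$ssi
    ang <- runif(1, 0, 2 * pi)
    tr <- runif(2, -50, 50)
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    rot <- function(m) sweep(m %*% t(Rm), 2, -tr)
    axR <- new("BodyAxis", centroid = c(Rm %*% c(0, 0)) + tr,
               direction = c(Rm %*% c(0, -1)), headingSign = 1,
               majorAxisLength = 200, degenerate = FALSE, ambiguous = FALSE)
    ssiR <- ssiFromSpreads(assignRoles(
      measurePaw(sweep(L %*% t(Rm), 2, tr, "+"), axR, "left"),
      measurePaw(sweep(R %*% t(Rm), 2, tr, "+"), axR, "right"),
      "left")$spreads)$ssi
    expect_equal(ssiR, ssi0, tolerance = 1e-6)
  }
})

test_that("mirroring the scene and swapping the operated side preserves the SSI", {
  ax <- new("BodyAxis", centroid = c(0, 0), direction = c(0, -1),
            headingSign = 1, majorAxisLength = 200,
            degenerate = FALSE, ambiguous = FALSE)
  L <- cbind(x = 20 + c(0, 8, 16, 24, 32), y = 60 + c(0, 3, 5, 3, 0))
  R <- cbind(x = -(25 + c(0, 9, 18, 27, 36)), y = 60 + c(0, 4, 6, 4, 0))
  ssi0 <- ssiFromSpreads(assignRoles(
    measurePaw(L, ax, "left"), measurePaw(R, ax, "right"), "left")$spreads)$ssi
  # mirror across the body axis (x -> -x): left and right exchange
  Lm <- cbind(x = -R[, 1], y = R[, 2])
  Rm <- cbind(x = -L[, 1], y = L[, 2])
  ssiM <- ssiFromSpreads(assignRoles(
    measurePaw(Lm, ax, "left"), measurePaw(Rm, ax, "right"), "right")$spreads)$ssi
  expect_equal(ssiM, ssi0, tolerance = 1e-9)
})
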