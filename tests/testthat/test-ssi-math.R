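test_that("toe spread factor matches its definition and is scale invariant", {
  cases <- list(
    list(op = 20, ct = 20, want = 0),
    list(op = 10, ct = 20, want = -0.5),
    list(op = 24.6, ct = 20.5, want = 0.2))
  for (cs in cases)
    expect_equal(toeSpreadFactor(cs$op, cs$ct), cs$want, tolerance = 1e-12)
  # vectorised
  expect_equal(toeSpreadFactor(c(20, 10), c(20, 20)), c(0, -0.5))
  # scale invariance
  for (k in c(0.5, 2, 10))
    expect_equal(toeSpreadFactor(24.6 * k, 20.5 * k), 0.2, tolerance = 1e-12)
})

test_that("toe spread factor rejects non-positive control spreads, naming the frame", {
  expect_error(toeSpreadFactor(10, 0), "non-positive control")
  expect_error(toeSpreadFactor(c(10, 10), c(20, -1), frame = c(7L, 9L)), "9")
  expect_error(toeSpreadFactor(-1, 20), "operated")
})

test_that("static sciatic index evaluates the published linear model", {
  expect_identical(staticSciaticIndex(0, 0), -5.49)
  expect_equal(staticSciaticIndex(1, 0), 102.95, tolerance = 1e-12)
  expect_equal(staticSciaticIndex(-0.5, -0.5), -75.635, tolerance = 1e-12)
  expect_error(staticSciaticIndex(NA_real_, 0), "finite")
  # coefficient override is honoured
  co <- ssiCoefficients(wTsf = 100, wItsf = 30, intercept = -5)
  expect_equal(staticSciaticIndex(0.1, 0.1, co), 10 + 3 - 5)
})

test_that("SSI from spreads matches longhand arithmetic", {
  r <- ssiFromSpreads(spreadPair(60, 80, 30, 40))
  expect_equal(r$tsf, -0.25)
  expect_equal(r$itsf, -0.25)
  expect_equal(r$ssi, oracleSsi(60, 80, 30, 40))
  expect_equal(r$ssi, -40.5625, tolerance = 1e-12)
})

test_that("spread pairs enforce positivity and its < ts", {
  expect_error(spreadPair(60, 80, 30, 0), "positive")
  expect_error(spreadPair(60, 80, 70, 40), "itsO")
  expect_error(spreadPair(60, 80, 30, 90), "itsC")
  expect_s4_class(spreadPair(60, 80, 30, 40), "SpreadPair")
})

test_that("outlier flags follow plausibility window then Tukey fences", {
  expect_equal(flagOutliers(rep(-10, 4)), rep(FALSE, 4))
  x <- c(-9, -10, -11, -9, -10, -12, -60)
  expect_equal(flagOutliers(x), c(rep(FALSE, 6), TRUE))
  # plausibility stage catches values no fence would, order preserved
  y <- c(rep(-5.49, 100), 200)
  f <- flagOutliers(y)
  expect_true(f[101])
  expect_false(any(f[1:100]))
  # fewer than 4 values: no flags; empty input errors
  expect_equal(flagOutliers(c(-500, 500, 0)), rep(FALSE, 3))
  expect_error(flagOutliers(numeric(0)), "empty")
})

test_that("outlier flags agree with the brute-force oracle on random sequences", {
  set.seed(20)
  for (i in 1:300) {
    n <- sample(1:30, 1)
    x <- round(rnorm(n, -30, 25), 2)
    if (runif(1) < 0.3) x[sample(n, 1)] <- runif(1, -400, 400)
    expect_identical(flagOutliers(x), oracleFlags(x))
  }
})

test_that("video summary computes seeded, reproducible statistics", {
  r <- ssiRecords(0:9, rep(60, 10), rep(30, 10), rep(80, 10), rep(40, 10))
  s <- summarizeVideo(r, nFramesTotal = 100L)
  expect_equal(meanSsi(s), -40.5625)
  expect_equal(sdSsi(s), 0)
  # two-point sample SD
  r2 <- data.frame(frame_index = 0:1, SSI = c(0, 10),
                   outlier = c(FALSE, FALSE))
  s2 <- summarizeVideo(r2, nFramesTotal = 2L)
  expect_equal(meanSsi(s2), 5)
  expect_equal(sdSsi(s2), sqrt(50), tolerance = 1e-6)
  # subsampling is seeded and bit-reproducible
  big <- data.frame(frame_index = 0:2999, SSI = rnorm(3000, -40, 5),
                    outlier = FALSE)
  a <- summarizeVideo(big, 3000L, sampleSize = 1000L, seed = 11L)
  b <- summarizeVideo(big, 3000L, sampleSize = 1000L, seed = 11L)
  expect_identical(meanSsi(a), meanSsi(b))
  expect_identical(sdSsi(a), sdSsi(b))
  expect_equal(a@nSampled, 1000L)
  c2 <- summarizeVideo(big, 3000L, sampleSize = 1000L, seed = 12L)
  expect_false(identical(meanSsi(a), meanSsi(c2)))
})

test_that("video summary applies the >50 labeled-frame QC floor", {
  mk <- function(n) data.frame(frame_index = seq_len(n) - 1L,
                               SSI = rnorm(n, -40, 2), outlier = FALSE)
  set.seed(5)
  expect_false(qcPass(summarizeVideo(mk(40), 1000L)))
  expect_true("TOO_FEW_FRAMES" %in% qcReasons(summarizeVideo(mk(40), 1000L)))
  expect_false(qcPass(summarizeVideo(mk(50), 1000L)))
  expect_true(qcPass(summarizeVideo(mk(51), 1000L)))
  # zero retained records
  empty <- data.frame(frame_index = integer(0), SSI = numeric(0),
                      outlier = logical(0))
  s <- summarizeVideo(empty, 100L)
  expect_false(qcPass(s))
  expect_true("NO_FRAMES" %in% qcReasons(s))
})

test_that("outlier removal cannot inflate the retained count", {
  set.seed(9)
  x <- rnorm(200, -40, 8)
  x[c(3, 50)] <- c(400, -400)
  r <- ssiRecords(seq_along(x) - 1L, rep(60, 200), rep(30, 200),
                  rep(80, 200), rep(40, 200))
  r$SSI <- x
  r$outlier <- flagOutliers(x)
  s <- summarizeVideo(r, 500L)
  expect_lte(nFramesRetained(s), nFramesLabeled(s))
  expect_lte(nFramesLabeled(s), s@nFramesTotal)
})
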