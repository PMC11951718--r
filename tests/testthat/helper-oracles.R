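# Independent brute-force oracles, deliberately written without reusing
# package internals or stats::quantile.

# Quantile by sorting and linear interpolation (the "type 7" rule, done
# by hand).
oracleQuantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Two-stage outlier flags: absolute plausibility window, then Tukey
# fences on the survivors (skipped when fewer than 4 survive). Element-
# wise loop on purpose.
oracleFlags <- function(x, lo = -150, hi = 50, k = 1.5) {
  n <- length(x)
  if (n < 4) return(rep(FALSE, n))
  stage1 <- vapply(x, function(v) v < lo || v > hi, logical(1))
  keep <- x[!stage1]
  flags <- stage1
  if (length(keep) >= 4) {
    q1 <- oracleQuantile(keep, 0.25)
    q3 <- oracleQuantile(keep, 0.75)
    fl <- q1 - k * (q3 - q1)
    fh <- q3 + k * (q3 - q1)
    for (i in seq_len(n))
      if (!flags[i] && (x[i] < fl || x[i] > fh)) flags[i] <- TRUE
  }
  flags
}

# SSI arithmetic done longhand from the four spreads.
oracleSsi <- function(tsO, tsC, itsO, itsC) {
  108.44 * ((tsO - tsC) / tsC) + 31.85 * ((itsO - itsC) / itsC) - 5.49
}

# Principal-axis angle of a point cloud by explicit 2x2 eigen decomposition.
oracleAxisAngle <- function(xs, ys) {
  cx <- mean(xs); cy <- mean(ys)
  m <- cbind(xs - cx, ys - cy)
  ev <- eigen(crossprod(m) / length(xs))
  v <- ev$vectors[, 1]
  atan2(v[2], v[1])
}
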