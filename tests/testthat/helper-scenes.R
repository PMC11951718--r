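# Small, fast synthetic scenes shared across tests. Quarter-ish frame
# size keeps per-frame cost around 0.1 s; blob and body sizes are scaled
# to match (segmentation area limits scale with frame area).

smallScene <- function(tsLeft = 40, itsLeft = 20, tsRight = 50,
                       itsRight = 25, frameSize = c(640, 360),
                       bodySemiAxes = c(90, 36), pawLateralOffset = 60,
                       pawCaudalOffset = 150, blobRadius = 5,
                       jitterSd = 0, noiseSd = 0.03, seed = 1L, ...) {
  sceneSpec(frameSize = frameSize,
            tsLeft = tsLeft, itsLeft = itsLeft,
            tsRight = tsRight, itsRight = itsRight,
            bodySemiAxes = bodySemiAxes,
            pawLateralOffset = pawLateralOffset,
            pawCaudalOffset = pawCaudalOffset,
            blobRadius = blobRadius, noiseSd = noiseSd, jitterSd = jitterSd,
            seed = seed, ...)
}

# A healthy-baseline variant: operated and control spreads identical.
smallBaselineScene <- function(seed = 1L, ...) {
  smallScene(tsLeft = 45, itsLeft = 22, tsRight = 45, itsRight = 22,
             seed = seed, ...)
}
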