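---
title: "Measuring the static sciatic index from under-box video: methods and design"
author: "pawSSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the static sciatic index from under-box video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

After a sciatic nerve crush, a rat progressively loses and (with
successful regeneration) regains the ability to spread the toes of the
affected hind paw. The static sciatic index (SSI) quantifies this at rest
by comparing two distances on each hind paw -- the toe spread TS between
digits 1 and 5, and the intermediate toe spread ITS between digits 2 and
4 -- across the operated (o) and control (c) sides:

$$\mathrm{TSF} = \frac{TS_o - TS_c}{TS_c}, \qquad
  \mathrm{ITSF} = \frac{ITS_o - ITS_c}{ITS_c},$$

$$\mathrm{SSI} = 108.44\,\mathrm{TSF} + 31.85\,\mathrm{ITSF} - 5.49.$$

The weights and intercept are the published calibration of this index and
are treated as constants (`ssiCoefficients()` allows an explicit override
for re-calibration research, nothing else touches them). Both factors are
ratios, so the index is invariant under uniform rescaling of all
distances; the pipeline therefore works entirely in pixels and never
needs camera calibration. The healthy expectation is `SSI(0, 0) = -5.49`,
and severe injury drives the index toward -100.

The practical task is turning a 1-2 minute under-box video (thousands of
frames) into per-frame (TSo, ITSo, TSc, ITSc) tuples, robustly enough
that hundreds of frames contribute to each session's estimate.

## Pipeline stages and their assumptions

**ROI masking.** Analysis is confined to a four-vertex polygon covering
the box floor; pixels outside are zeroed, dimensions are preserved so all
coordinates remain in the original frame system. This is the only
per-video manual input and exists to exclude reflective surroundings,
which otherwise produce bright blobs indistinguishable from paws.

**Segmentation (classical backend).** The shipped backend assumes a
light-coated animal brighter than the background (an `invert` flag serves
the opposite contrast). Per frame: grayscale conversion; a global Otsu
threshold computed from a 256-bin histogram of ROI pixels only;
morphological opening with a disk of radius 1 px to cut speckle;
connected-component labeling. The largest bright component is the body;
the remaining components become digit candidates if their area lies in
[30, 2000] px^2 (defined at 1920x1080 and scaled by frame area for other
resolutions) and their solidity -- component area over convex-hull area,
with pixels treated as unit squares -- is at least 0.7. A component larger
than the digit maximum but smaller than the body (a paw whose digits
merged) is split by assigning its pixels to the nearest of its 3x3-local
intensity maxima (plateau-merged), which works because digit blobs are
brightest at their centers. At most 10 candidates are kept (largest
first). Centroids are intensity-weighted and fractional. If the threshold
floods more than 60% of the ROI the frame has no separable figure and is
rejected (`NO_ANIMAL`), as is any frame whose largest component is below
the body minimum area (5000 px^2 at 1080p equivalent).

The backend sits behind a contract -- image in, `FrameDetection` out -- so
a trained network can replace it (`backend = "cnn"` is the plug-in slot;
no trained model ships with the package, and the classical backend is the
tested implementation).

**Body axis and heading.** The body centroid and principal axis come from
the second-order central moments of the body mask, i.e. the equivalent
ellipse's orientation; the full body length is estimated as four times the
square root of the leading moment eigenvalue. Near-isotropic masks
(eigenvalue ratio > 0.9) give no usable axis and the frame is dropped as
`AMBIGUOUS_HEADING`. The axis leaves a 180-degree ambiguity; it is
resolved by the rule that *hind paws trail the body*: the heading sign is
chosen so the mean digit-candidate position lies behind the centroid.
This needs no snout detection and is robust for the stationary postures
the static index is defined on. When the digit mean projects within a
tolerance (2 px or 2% of body length, whichever is larger) of the
centroid, the frame is flagged ambiguous and dropped rather than guessed.

**Left/right split and digit ordering.** The camera views the ventral
side, so with the heading pointing up the image the animal's left paw
appears on the viewer's right. Candidates are partitioned by the sign of
the 2D cross product of the heading with the centroid-to-candidate
vector (a `flipLR` option serves mirrored rigs). If more than five
candidates land on one side, the five largest survive -- small noise
blobs lose; fewer than five is a per-frame failure (`MISSING_DIGITS`, or
`PAW_NOT_VISIBLE` when a side is empty). Within a paw, digits are ordered
1 to 5 by their unsigned perpendicular distance from the body-axis line
(medial to lateral, the convention of the classical toe-spread
literature), with ties broken by distance to the body centroid, then by
coordinates, keeping the order total and deterministic. TS and ITS are
then plain Euclidean distances between ordered digit centroids, and the
declared operated side maps the two paws onto (o, c).

**Frame QC.** A frame yields a record only with a body, an unambiguous
heading, five digits on each paw, ITS < TS on both paws, and TS within a
sanity band of [0.05, 0.6] times the body length. The band exists to
catch segmentation artifacts (e.g. a reflection merged into a paw
inflating TS); it is deliberately loose and configurable because paw
posture varies. Verdicts are pure functions of their inputs.

**Outlier rejection and aggregation.** Per-frame SSI values pass two
filters: an absolute plausibility window of [-150, +50], generously
bracketing the physiological SSI range (roughly -80 to +10), then Tukey
boxplot fences at 1.5 IQR computed from the surviving values -- the
boxplot convention in which such session distributions are conventionally
presented. Sequences shorter than four values are never flagged, and the
fences are skipped when fewer than four values survive the window.
Quartiles use linear interpolation throughout (the common default;
stated because fence placement depends on it). The per-video summary
(mean, SD with the n-1 denominator, median, quartiles) is computed from a
seeded uniform subsample of at most 1,000 retained records, making
summaries reproducible bit for bit for a given seed while bounding the
cost on long videos. A video passes QC only when more than 50 frames were
labeled; the retention fraction is reported but not enforced beyond that
floor, since real-world retention reflects animal behaviour rather than
software quality.

## The synthetic-scene generator

Every stage is tested against rendered scenes with exact ground truth: a
bright body ellipse (intensity 0.85) on a noisy darker background
(0.12, Gaussian noise sd 0.03), two hind paws of five Gaussian-profile
digit blobs (peak 1.0, radius parameter 9 px at full HD, profile sd =
radius/2) trailing the body, optional per-frame digit jitter, an optional
bright reflective patch, and optional occlusion of one paw -- the main
real-world failure modes. Rendering frame *i* of a spec is a pure
function of (scene seed, *i*), so any frame can be re-rendered in
isolation and whole videos are reproducible.

Digit placement: the five blob centers of a paw form a symmetric fan --
lateral offsets (-ts/2, -its/2, 0, its/2, ts/2) from the paw
center along the axis perpendicular to the heading, with a symmetric
parabolic bow along the heading (depth 0.25 ts). Because the bow is
symmetric, the rendered chords |d1 - d5| and |d2 - d4| equal the
requested ts and its *exactly*, for any its < ts. (A circular-arc
construction with equally spaced digits was considered and rejected: its
chord constraint degenerates exactly at ts = 2 its, which includes the
default test geometry.) Ground truth is recorded after jitter.

What the generator does *not* emulate -- and what passing tests therefore
do not show about real data: fur texture and limb self-occlusion, paws
touching the body outline, non-stationary walking postures, compression
artifacts of consumer cameras, and the behavioural component of
real-world frame retention. The generator validates the geometry and
statistics of the pipeline, not the segmentation difficulty of any
particular animal facility's footage.

## Numerical and design choices

* **Otsu threshold** is computed from a 256-bin histogram by direct
  between-class-variance maximisation over bin edges; ties resolve to the
  first maximum. Computing it over ROI pixels only makes the threshold
  independent of how much dead area the crop leaves.
* **Coordinates** are 0-based pixels, origin top-left, x rightward, y
  downward; angles on screen therefore increase clockwise.
* **Determinism.** The classical backend has no randomness; candidate
  ordering and all tie-breaks are explicit, so identical frames give
  identical detections and re-running a video reproduces its CSV byte for
  byte. The only randomness in the pipeline is the summary subsample,
  which is seeded and restores the caller's RNG state.
* **Quartile method** everywhere (fences and summaries) is linear
  interpolation; SD uses the n-1 denominator (sample statistic over
  frames).
* **Degenerate inputs.** Empty masks error; blank or saturated frames
  reject as `NO_ANIMAL`; coincident digits produce TS = ITS = 0 and are
  rejected by the ITS < TS rule; a zero control spread cannot reach the
  index because spread pairs validate strict positivity.
* **Serialisation** is pinned: the measurements table has columns
  frame_index, TSo, ITSo, TSc, ITSc, TSF, ITSF, SSI, outlier; numbers are
  written with six decimal places in both the XLSX workbook and its CSV
  mirror so downstream scripts can rely on the layout. The XLSX writer is
  self-contained (stored-entry OOXML package with inline strings) and is
  cross-checked against an independent reader in the tests.
* **Video containers.** Multi-page TIFF (effectively lossless at 16-bit,
  deflate) and PNG frame directories are supported natively; MP4 decoding
  and encoding are delegated to an `ffmpeg` executable when one is on the
  PATH. Tests and the acceptance script use the lossless containers and
  in-memory synthetic streams so segmentation tolerances are not
  codec-dependent.

## Problem sizes

The test suite exercises full-HD scenes at 120 frames per video for the
end-to-end statistics and smaller 640x360 scenes elsewhere; the
acceptance script uses 300 frames per full-HD video. Per-frame SSI
statistics stabilise well below these sizes (the standard error of the
mean at SD ~2.7 and 300 frames is ~0.16 SSI units), so these sizes trade
no statistical resolution.

## Known limitations

* The classical backend assumes figure-ground contrast a simple global
  threshold can separate; dark-coated animals on dark backgrounds, or
  strong vignetting, will need either the `invert` flag, tighter crops,
  or a trained segmentation model plugged into the backend contract.
* Heading resolution assumes both hind paws are behind the body centroid;
  extreme curled postures can defeat it (such frames are dropped by QC,
  which is the designed failure mode).
* Digit identity is geometric (medial to lateral), not anatomical; if a
  digit is missing and a noise blob substitutes for it within all
  filters, the spread is mismeasured -- the TS sanity band and the
  outlier fences are the guards.
* The walking-track sciatic functional index (SFI) and paw-length-based
  indices are out of scope; the package measures the static index only.
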