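---
title: "Measuring leaf length and width from reference-sheet photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leaf length and width from reference-sheet photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmetrics)
```

## The measurement problem

A detached leaf is photographed lying on a white rectangular sheet of known
physical size (default 21 cm x 29 cm). The goal is the leaf's **length** --
the Euclidean distance from the leaf tip (apex) to the petiole insertion --
and its **width**, the maximum lamina extent perpendicular to the midrib.
Two things make this harder than counting pixels:

* the camera views the sheet at an angle, so the image is projectively
  distorted and has no fixed pixels-per-centimetre scale; and
* in species such as kiwifruit, the tip and the insertion are frequently
  **concave**: the landmark sits inside a notch (or basal sinus), *below*
  the surrounding lobes, so the silhouette's global vertical extremum is
  the wrong point and overestimates the length.

The pipeline (`measure_image()`) addresses both with a fixed stage order:

1. **Blue channel.** White paper and green lamina separate most strongly in
   the blue channel; the leaf's green/red content is irrelevant to the
   threshold.
2. **3x3 median filter** for impulse noise, with edge replication so the
   histogram is not polluted by artificial border values.
3. **Histogram-valley threshold.** The blue histogram of a valid scene is
   bimodal -- a bright sheet mode at the right end, darker leaf and
   surround to its left. The threshold is the minimum of the smoothed
   histogram between the two rightmost prominent modes; pixels at or below
   it are foreground (ties go to the leaf).
4. **Sheet rectification.** The sheet's four corners are detected in the
   binary image and an exact four-point homography maps them onto a
   rectangle with the sheet's physical aspect ratio, removing perspective
   and fixing the scale.
5. **Crop, swap and clean.** The frame is cropped to the sheet, the leaf
   becomes the foreground, and everything but the largest connected
   component is removed.
6. **Skew correction.** The angle of the midrib from vertical is estimated
   from the basal part of the silhouette and the mask is rotated upright,
   so that width is a horizontal row extent.
7. **Landmarks.** The boundary is traced and each extremity is dispatched
   to a convex (global extremum) or concave (difference-curve peak) path.
8. **Measurement.** Length is the tip-insertion distance (two-point
   distance formula); width is the widest row span; both are converted to
   centimetres by the sheet-derived pixels-per-centimetre.

## The concave landmark search

For a concave extremity, a short boundary segment is selected that spans
both flanking lobes: one endpoint is the band's vertical extremum (the
leaf's top-left or top-right point; on ties the **outermost** pixel, so
that a notch adjacent to the extremum run stays interior to the segment),
and the other is the outermost boundary pixel at the **modal row** of the
extremity band on the opposite side of the lamina midline -- notched
extremities are flat near the top, so the most frequent boundary row marks
the shoulder level. The **difference curve** of the segment records each
pixel's vertical offset from the extremum row; its peak is the deepest
point of the notch, i.e. the landmark.

Classification between concave and convex compares the peak's depth *below
the flanking lobes* (the segment endpoints) against a threshold (default
3 px) and additionally requires the peak to be horizontally interior to
the lobes (at least 20% of the endpoint span away from both). Measuring
depth relative to the lobes rather than the global extremum row means
one-to-two-pixel boundary staircase jitter on a smooth convex apex cannot
fake a notch. Decisions within 1 px of the threshold are flagged in the
run record.

The extremity band is the top (bottom) decile of the leaf's row span. With
the default notch depths this keeps the whole notch inside the band while
holding the search region small.

## Skew estimation from the basal silhouette

The midvein straightens as it approaches the insertion, and the lamina
narrows there, so within the basal band (lowest 20% of leaf rows) the
row-wise horizontal midpoints of the silhouette track the midrib. A least
squares line through those midpoints gives the signed angle from vertical
(positive = top of the midrib leans right). Rows whose span is degenerate
(below 40% of the band's median span -- quantized tip rows and truncation
corners) are excluded; at least 10 usable rows are required.

Two properties of this estimator shape the implementation:

* **It is biased away from upright but exact at upright.** For a tilted
  silhouette, horizontal chords are not perpendicular to the midrib and
  their midpoints lean (for straight basal flanks by a tangent-averaging
  term; for wide curved bases by much more). At the upright pose, symmetry
  makes the midpoint line exactly vertical. `deskew_mask()` therefore
  *iterates* estimate-and-rotate until the estimate vanishes, each pass
  resampling the original mask once by the accumulated angle. The fixed
  point is the true upright pose regardless of the bias profile.
* **Its angular resolution is quantization-limited.** With a basal band of
  h rows, a one-pixel midline shift corresponds to about atan(1/h)
  degrees; at 20 px/cm this is ~0.2 deg for a 15 cm leaf but ~3 deg for a
  4.5 cm leaf. The convergence tolerance (0.2 deg) matches this floor at
  the design resolution: chasing smaller estimates makes the iteration
  wander between poses the data cannot distinguish. Skew-recovery checks
  are therefore run on leaves from the upper half of the size range
  (12-22 cm), where sub-degree recovery is supported by the data; smaller
  leaves de-skew to within a few times their own resolution floor, which
  is harmless for their measurements (a 2 deg residual changes a width by
  under 0.1%).

## Sheet corner detection and rectification

The sheet is the largest bright component. Its convex hull is searched for
the area-maximizing quadrilateral (deterministic local improvement from
the four diagonal extremes), and each side is then refined sub-pixel: the
true edge must pass within one pixel outward of every outermost boundary
pixel centre (the rasterization "tube"). When the tube is wide (an edge
nearly aligned with a pixel axis, showing few staircase steps) its
Chebyshev centre is the minimax estimate; when many steps make the tube
degenerate, a least-squares midline with the intercept clamped into the
tube is used. Adjacent side lines are intersected to give corners at the
sheet's area boundary. The four-point solve onto the target rectangle is
exact, so the detected corners map to the rectangle corners with zero
residual, and the calibration (mean of the width- and height-derived
pixels-per-centimetre, with a 1% cross-check) inherits the corner
accuracy.

A known limitation: an image edge aligned with a pixel axis to within one
staircase step across its whole length carries about +-0.5 px of corner
ambiguity for *any* binary-mask detector -- several distinct lines thread
the constraint tube. This is a measure-zero camera alignment; the
validation suite draws generic poses (every edge tilted at least ~0.35
deg) and area-preserving warps (camera inclination, not zoom -- a zooming
warp changes the true scale, which no rectification can recover).

## The synthetic scene generator

`leaf_shape()` / `leaf_scene()` / `render_scene()` produce ground-truthed
scenes: the exact landmark positions, dimensions, tilt, homography and
leaf mask are known because the geometry is transformed *in vector form*
(tilt, then projective warp) and rasterized once in the final frame.

The lamina is built from analytic half-outlines with the midrib on the
vertical axis:

* a rounded (superellipse-like) or notched apex -- a concave apex has flat
  shoulders with a cosine notch of exactly the specified depth, matching
  the flat-topped morphology the modal-row rule expects;
* rounded side tips (sub-linear taper exponents), because needle-like
  widest points would lose ~2 px of width to median filtering and
  nearest-neighbour resampling -- an artifact of the parameterization, not
  of real laminas;
* an acute base tapering into a narrow blunt neck (straight flanks,
  power-curve tip), or a truncate base whose straight flanks flare into
  two flat shoulders around a cosine sinus. Straight, narrow basal flanks
  are what makes the silhouette-midpoint skew surrogate valid: analysis
  shows broad cordate bases make the row-midpoint fit diverge, which is
  precisely why the original procedure reads the *vein*, not the
  silhouette, near the base. The generator's basal geometry encodes the
  "straight basal midvein" assumption into the silhouette.

Coloration is a vertical green gradient plus low-frequency mottling in the
leaf's own coordinates (so segmentation cannot exploit a flat foreground
value), the sheet has a mild illumination gradient, and Gaussian sensor
noise is added per channel. Before noise, sheet pixels have blue >= ~230
and leaf pixels <= ~115, guaranteeing the bimodal histogram with modes
separated by well over 80 grey levels at noise sd <= 10.

Default study conditions, matching the reported field protocol: 21 x 29 cm
sheet, 20 px/cm rendering, lengths sampled over 4-23 cm (widths 0.7-1.1 x
length, capped so the tilted leaf fits the sheet), each extremity concave
with probability 0.5, notch/sinus depths 2-10% of length, tilt uniform in
+-15 deg, mild perspective (corner displacements ~4% of the sheet width),
noise sd 5. Scenes are deterministic given their seed.

What the generator does **not** emulate -- and what passing tests
therefore do not establish about field photographs: venation and specular
highlights, shadows and uneven illumination beyond a smooth gradient,
optical blur (edges are hard), radial lens distortion (the correction is
planar-projective only), damaged or folded laminas, and multi-leaf or
cluttered scenes.

## Numerical choices and tie-breaks

All tie-breaks are fixed so outputs are bit-reproducible: histogram-valley
ties resolve to the centre of the minimizing run; prominent histogram
maxima closer than 20 grey levels merge into the taller (sampling noise
can split a mode into equal twin peaks that prominence cannot demote);
extremum-row ties to the outermost column; modal-row ties to the row
nearer the extremum; difference-curve ties to the pixel nearest the
segment's horizontal midpoint; convex-landmark row ties to the column
nearest the boundary's column centroid; widest-row ties to the smallest
row. Masks are warped with nearest-neighbour sampling (preserving
binarity), grayscale and RGB bilinearly. Boundary tracing is
Moore-neighbour with Jacob's stopping criterion plus visited-state cycle
detection, which terminates correctly on diagonally pinched masks where
the classic criterion alone can loop.

Validation problem sizes (chosen to exercise the method across its range
while keeping the default test run a few minutes long): 30 mixed scenes
for end-to-end recovery, 50 sheets for rectification, 50 scenes for skew,
10 double-notched leaves for concave landmarks, 100 simulated histograms
plus 6 scenes for thresholding, 10 high-tilt scenes for the
skew-motivation comparison.

## A worked example

```{r example, eval = FALSE}
shape <- leaf_shape(12, 9.5, apex = "concave", base = "convex",
                    notch_depth_cm = 0.8, seed = 42)
scene <- leaf_scene(shape, tilt_deg = 8, noise_sd = 5, seed = 42)
rendered <- render_scene(scene)
run <- measure_image(rendered$image)
run
#> leaf_run [<array>]: ok
#>   length 12.00 cm, width 9.50 cm (tip concave, base convex)
```

The run record carries per-stage status (the chosen threshold, the
detected sheet extent, the de-skew angle and residual, the landmark
labels), which is what you need when a computed value disagrees with a
ruler.

## Known limitations

* Width is an inclusive pixel span on the de-skewed mask; after two
  nearest-neighbour resamplings it is typically accurate to ~2 px
  (0.1 cm at the default resolution), which dominates the error budget
  for small leaves.
* Notches narrower than ~3 px or shallower than the dispatch threshold
  are (by design) treated as convex; the resulting length error is
  bounded by the notch depth.
* The basal skew surrogate assumes a narrowing, near-symmetric base; it
  is not meant for strongly asymmetric or broadly cordate laminas.
* Sheets photographed with an edge exactly aligned to the sensor axes sit
  at the binary corner-detection information floor (~0.5 px).
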