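---
title: "Curating clinical breast-ultrasound image datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating clinical breast-ultrasound image datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buscurate)
```

## The problem

Clinical breast ultrasound (BUS) archives are messy in ways DICOM headers do
not record: frames captured in Color/Power Doppler or elastography rather than
plain B-mode, near-black frames from machine malfunction or annotation-only
captures, side-by-side dual-view composites, sonographer-placed measurement
calipers burnt into the pixels, and free-text labels (laterality, clock-face
position, transducer orientation, distance from the nipple, procedure notes).
Left in a training corpus, these artifacts teach models shortcuts — a lesion
detector that finds calipers instead of lesions, or a classifier that
associates the mere presence of text with malignancy. buscurate implements a
modular screening pipeline: *filtering* (invalid and non-B-mode frames),
*cleaning* (dual-view detection, caliper detection, scan-area cropping), and
*knowledge extraction* (OCR plus regular-expression parsing of the burnt-in
labels), plus a synthetic phantom generator so every detector can be validated
end-to-end without clinical data.

## Filtering

**Invalid frames.** A frame is invalid when more than 75% of the scan area is
black, where black means a grayscale value strictly below 5 (8-bit scale).
Both cutoffs are strict inequalities and are exposed in `filter_params()`.
Color input is first converted by the standard luma weighting
(0.299 R + 0.587 G + 0.114 B); whether thresholds should apply to luma or to
a single extracted channel is not dictated by any standard, so luma is the
default and the conversion point is fixed in one function (`to_grayscale()`).

**Non-B-mode frames.** A four-step decision: (1) a grayscale frame (exact
channel equality by default; `grayscale_tol` absorbs JPEG chroma noise) is
B-mode outright; (2) HSV masks are built for the blood-flow palette (orange,
green, yellow, red, blue — red's hue range wraps) and a green/white indicator
mask; (3) a rectangle fragment or image-spanning line in the green/white mask
(the overlay graphics of elastography and Doppler ROIs) marks the frame
non-B-mode; (4) otherwise the frame is non-B-mode when flow-colored pixels
exceed 0.5% of the scan area. The HSV ranges are vendor-dependent and ship as
editable defaults (OpenCV-style units, hue 0–179). Three numerical choices
deserve note:

* The 0.5% denominator is the **stage-1 crop box** (the scan area), not the
  full frame, so black borders cannot dilute the fraction. When cropping
  degenerates the full frame is used.
* The fraction is computed on the **undilated** in-range mask. Dilation
  (disc radius 2 by default) exists to reconnect fragments of thin overlay
  graphics before contour analysis; applied before counting it would inflate
  isolated chroma-noise pixels roughly thirteen-fold and make the 0.5%
  cutoff meaningless.
* The rectangle test ignores components smaller than `min_rect_px` (40 px) in
  either dimension: rendered text glyphs are themselves small axis-aligned
  shapes, while genuine indicator overlays are software-scale graphics. The
  "image-spanning line" rule requires a gap-tolerant run covering 80% of the
  image height or width (gaps ≤ 5 px), since overlay lines span most but not
  all of the frame.

A consequence of the spanning-line rule worth knowing: a single unbroken line
of burnt-in text wide enough to cross 80% of the frame can satisfy it. This
is rare at realistic annotation lengths but is the main false-positive route
for the mode classifier on the synthetic suite.

## Cleaning

**Dual-view composites** are two views stored side by side with a sharp
vertical boundary at the midline. The test: frames dominated by teal/green
(elastography) or narrower than 0.75× their height are excluded; a Canny edge
map (hysteresis thresholds 50/150 on 8-bit input, Gaussian σ = 1) is computed;
the frame is dual-view when the edge count in the single midline column
`m = floor(width/2)` exceeds 100 and exceeds by more than 10 the counts at
columns `m ± 10`. A band instead of a single column would be more forgiving
of off-center splits; the single column is kept as the literal reading and
the margin/slack are configurable. The in-house Canny keeps ties in
non-maximum suppression (a pixel survives when its gradient magnitude is ≥
both neighbors along the gradient direction), so a symmetric step edge
retains candidates in both adjacent columns rather than arbitrarily dropping
the midline one.

**Calipers.** The contour method: (1) black-mask the outer 15% of each
dimension *per side* — burnt-in text and software overlays cluster near the
frame edges; (2) apply a 3×3 Laplacian edge kernel (the classic FIND-EDGES
contract: high response where local intensity changes, negatives clipped), a
3×3 maximum filter, binarization, and a disc-2 dilation; (3) take external
contours and return every one whose bounding box is between 10 and 70 px
**inclusive in both height and width**. Two implementation decisions:

* **Binarization threshold** (`edge_threshold`, default 120). Speckle texture
  produces moderate nonzero edge responses everywhere, so binarizing at zero
  merges the whole scan area into one giant component and no caliper can ever
  be isolated; high-contrast caliper marks saturate the clipped response at
  255. On the generator's smoothed speckle (marginal sd 30, grain σ = 3) the
  99.99th percentile of tissue edge response after the maximum filter is
  ≈ 75, so 120 sits between the regimes with margin on both sides. It is a
  config key because real tissue contrast varies.
* **Frame-artifact suppression.** The border mask itself creates an
  artificial high-contrast frame at its boundary; edge responses within the
  border band plus the filters' reach (kernel radius + max filter + dilation)
  are zeroed. Without this the Hough extension below would find the frame's
  horizontal and vertical lines intersecting at the corners on every image.
* Dilation decides component membership (the fragments of one cross merge),
  but each component's box is measured on the *undilated* edge support, so
  the 10–70 px bounds apply to the artifact's own extent rather than to its
  dilation halo. Marks smaller than about 8 px are therefore rejected by the
  lower bound, as intended.

**Hough extension** (`detect_calipers_hough()`). Some datasets join calipers
with dotted lines spanning the lesion. Under the contour method the dots and
markers merge into one component larger than 70 px and the scan is missed —
the acceptance suite reproduces this collapse and its repair. The extension
runs a Hough transform over the same edge image, extracts supporting segments
with gap bridging (minimum length 15 px, maximum gap 4 px — enough to bridge
a 3-px dot gap), and reports a caliper when two segments are non-parallel
(angle difference > 5°) and their supporting lines intersect inside both
segments' extents padded by 3 px. It ships **off by default**: it is the
adapt-to-your-dataset step, enabled per run (`calipers_hough` stage or
`--enable-hough-calipers`), mirroring how the base method is the
out-of-the-box behavior.

**Scan-area cropping.** Stage 1 thresholds the grayscale frame at
`mode + 10` (the mode of a mostly-black frame is the background value),
opens the mask with disc-3 erosion and dilation — which strips burnt-in text
strokes — and takes the tight bounding box of the largest 8-connected
component. A frame with nothing above threshold (uniform or all-black) raises
a typed degenerate-input condition which the pipeline records as invalid.
Rectangular scan areas *fill* their box; the test is fill ratio ≥ 0.95,
tolerating anti-aliasing and small nicks. Non-rectangular areas (trapezoid,
convex fan, shadow-eroded) are refined in stage 2: the box rows are split
into three equal bands (integer floor at the band edges); each band
contributes its leftmost and rightmost non-mode column; the refined
`x_left`/`x_right` are the medians (middle value of three, no interpolation)
of those extremes, and the symmetric rule over three vertical bands refines
the heights. Width and height are refined independently from the same stage-1
box. "Non-mode" is judged against the global image mode by default. A band
with no non-mode pixel contributes the corresponding stage-1 edge. Cropping
is idempotent in the meaningful case: re-cropping a cropped non-rectangular
frame (which retains background corners) returns the full sub-image to
within ±1 px of band flooring. Re-cropping a *borderless* all-tissue crop is
ill-posed — there is no background to find — and is documented as a
degenerate input rather than patched around.

## Knowledge extraction

OCR is an interface, not a dependency: `run_ocr()` dispatches on the backend
object, and any engine can be plugged in by implementing a method that
returns `(text, box, confidence)` rows. The package ships the deterministic
**stub backend**, which replays a phantom's ground-truth strings. This
removes the OCR engine from the loop, so the grammar layer is tested for
exact (100%) recovery — a failure there is a parsing bug, not an OCR error.
No real engine is bundled; requesting one raises an error that points to the
stub and to the backend contract. Detections below `min_confidence` (0.3,
permissive because the grammars reject garbage anyway) are dropped; strings
are uppercased and whitespace-normalized.

The grammars live in `inst/extdata/vocabulary.yaml` (regex lists per field,
editable and documented in place) and cover: laterality (LEFT/LT, RIGHT/RT,
bare L/R before BREAST/AX…), transducer orientation (RAD, ARAD with
ANTI-RAD/ANTIRAD aliases tested first so they never degrade to RAD, TRANS/TRV,
LONG, SAG, OBL), clock-face position (`H:MM` with hour 1–12, `H O'CLOCK`
dialects; quadrant notation such as LOQ is deliberately rejected), distance
from the nipple (a number + CM + a from-nipple marker: `FN`, `CMFN`,
`FROM NIPPLE`), axilla (AXILLA/AXILLARY/AX at word boundaries), lesion
measurements (any number–CM group *not* claimed by distance; `A x B CM`
yields both), and procedural terms (biopsy, FNA, aspiration, clip, marker,
coil, wire…). Disambiguation is by excision: distance matches are removed
from the string before measurement matching, so a number is consumed by
exactly one field. Across detections, seeing both LEFT and RIGHT yields
`CONFLICT` rather than a first-match winner — such frames (often mislabeled
or dual-view) deserve review, not a silent guess.

## Evaluation

Each binary task is scored by sensitivity, specificity and F1 from a standard
confusion matrix; undefined ratios (empty denominator) are `NA`, never 0.
Text-field tasks follow the strict convention that a true positive requires
the field to be recognized *and* classified correctly: a wrong value on an
annotated scan is a false negative, a value extracted where none exists is a
false positive, so cells always sum to the number of scored scans. Reported
tables round half away from zero at 3 decimals (`round3()`); raw values are
retained in machine output. The published per-task confusion counts for the
internal (n = 430) and external case-study (n = 780) datasets ship as data
functions so the table arithmetic is reproducible; recomputation agrees with
the printed statistics in 39 of 42 cells, and the three discrepant cells
(orientation F1, axilla F1, caliper sensitivity on the internal set) differ
from their own printed counts by 0.001–0.002 — the package reports the values
computed from the counts.

## The synthetic phantom generator

Phantoms exist to give every detector a labeled, regenerable test population;
physical realism is a non-goal. A phantom is a black canvas with a speckled
scan area (rectangular, trapezoidal, convex-fan, or irregular with a
shadow-eroded lower boundary), optionally carrying calipers (crosses, X's,
digit marks, 4–100 px), dotted spanning lines (dash 4 px, gap 3 px),
scattered Doppler-palette pixels in a box, green indicator overlays
(complete/partial rectangles or a near-full-height line), burnt-in text in a
bundled 5×7 bitmap font (no system-font dependency), side-by-side dual views
split by a two-column dark separator at the midline, or a near-black invalid
frame (≥ 80% of pixels below 5).

Speckle is a clipped Gaussian field, mean 90 and sd 30 on the 8-bit scale,
smoothed to a spatial grain of σ = 3 px and rescaled to keep the marginal sd:
echo texture is locally correlated, and an uncorrelated field would saturate
any local edge detector everywhere, making caliper detection impossible for
*any* method rather than testing this one. Rendering is bit-deterministic
given the spec (including its seed); `generate_suite()` stratifies over eight
artifact classes and derives per-image seeds from one master seed, so a
manifest row plus the package version reconstructs the exact image.

What passing the suite does and does not show: it demonstrates that each
detector implements its stated decision rule correctly and robustly against
speckle, placement, and size variation under the generator's conditions. It
does **not** demonstrate transfer to any vendor's real rendering of overlays,
fonts, or palettes — the published case study's lesson is precisely that new
data distributions need re-validation and possibly re-parameterization, which
is why every threshold discussed above is a config key.

On the suite, the caliper task is scored over the B-mode single-view
population (plain, text-annotated, and cross-caliper phantoms): in the
pipeline's intended flow, non-B-mode and dual-view frames have already been
filtered or set aside by the time calipers are sought, and overlay graphics
partially protruding into the central region would otherwise be counted
against a detector that is never meant to see them. Dotted-line phantoms are
scored separately as the mechanism study (contour-method collapse vs Hough
recovery).

## Problem sizes and runtime

The acceptance suite uses 50 phantoms per class (400 images, canvases around
420×560) for detector recovery, the same population for the dotted-line
mechanism and the stub-OCR round-trip, 100 random small images for the
brute-force oracle equivalences, and 16 shape phantoms for the crop
invariants. These sizes give two-sided binomial noise well below the 0.95
acceptance margins while keeping a full run in a few minutes on one CPU.

## Limitations

* No caliper removal/inpainting: boxes are returned for caller-side cropping.
* Dual-view frames are flagged, not split into two records.
* English vocabulary only, extensible via the YAML file.
* DICOM support covers uncompressed little-endian transfer syntaxes with
  MONOCHROME1/2, RGB and YBR_FULL photometric interpretations; compressed
  pixel data is rejected with a format error. Frames stored deeper than
  8 bits are min–max rescaled per frame so the 8-bit thresholds apply.
* The real-OCR path is an interface; recognition accuracy of any concrete
  engine is outside the package's test surface.
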