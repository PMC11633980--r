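# buscurate

Curation and cleaning of clinical breast-ultrasound (BUS) image datasets for
AI development, in R.

Clinical BUS archives mix plain B-mode tissue frames with material that
poisons model training and skews evaluation: Doppler/elastography captures,
near-black invalid frames, dual-view composites, sonographer-placed
measurement calipers burnt into the pixels, and free-text labels rasterized
onto the image. A lesion-segmentation model trained on caliper-annotated
scans can learn to find calipers instead of lesions; text presence can leak
outcome information. buscurate screens a directory of scans (PNG, JPEG, TIFF,
or uncompressed DICOM) and reports, per image:

* **Filtering** — invalid frames (strictly more than 75% of the scan area
  below grayscale 5) and non-B-mode frames, via a four-step test: grayscale
  frames pass; HSV masks for the blood-flow palette and for green/white
  indicator overlays are built; indicator rectangles or image-spanning lines
  flag the frame; otherwise flow-colored pixels over 0.5% of the scan area
  flag it.
* **Cleaning** — dual-view composites (Canny edge count in the midline column
  `m` must exceed 100 and exceed the counts at `m ± 10` by more than 10);
  lesion calipers via border masking (outer 15% per side), a Laplacian edge
  filter + maximum filter + dilation, and contours whose boxes fall in
  10–70 px in both dimensions; an optional Hough-line extension for calipers
  joined by dotted spanning lines (two non-parallel segments whose lines
  intersect within both extents); and a two-stage scan-area crop —
  threshold at mode + 10, opening, largest connected component, then for
  non-rectangular areas a thirds-band refinement taking the median of
  per-band extreme non-background coordinates.
* **Knowledge extraction** — OCR (pluggable backend; a deterministic
  ground-truth stub ships for testing) followed by regex grammars for the
  ACR BI-RADS labeling fields: laterality, clock-face location, transducer
  orientation, distance from the nipple in cm, plus axilla, lesion
  measurements, and procedural annotations.

A synthetic phantom generator renders every artifact class with
machine-readable ground truth, and an evaluation module scores any detector
against a manifest with sensitivity/specificity/F1 — so the whole pipeline is
testable without any clinical data.

## Worked example

```r
library(buscurate)

spec <- phantom_spec(
  calipers = tibble::tibble(cx = c(210, 330), cy = c(190, 260),
                            style = c("CROSS", "X"), size = 21L),
  text_items = tibble::tibble(text = "RT BREAST 10:30 2.5 CM FN RAD",
                              x = 18L, y = 10L),
  seed = 7
)
ph <- render_phantom(spec)
ph$image
#> <scan_image> 420x560, 1 channel, source: phantom-00000007

flags <- process_image(ph$image, bus_config(), truth = ph$truth)
flags[, c("is_invalid", "is_non_b_mode", "is_dual_view", "has_calipers",
          "shape_class", "crop_x_left")]
#> # A tibble: 1 × 6
#>   is_invalid is_non_b_mode is_dual_view has_calipers shape_class crop_x_left
#>   <lgl>      <lgl>         <lgl>        <lgl>        <chr>             <int>
#> 1 FALSE      FALSE         FALSE        TRUE         RECTANGULAR          50
```

The frame is a valid, B-mode, single-view scan; its rectangular scan area was
cropped to the box starting at column 50, and the two calipers were located
(boxes in 0-based, half-open pixel coordinates, so each ~23 px box brackets
one 21-px marker):

```r
flags$caliper_boxes[[1]]
#> # A tibble: 2 × 6
#>   x_left y_top x_right y_bottom     w     h
#>    <int> <int>   <int>    <int> <int> <int>
#> 1    199   179     222      202    23    23
#> 2    318   249     343      272    25    23
```

The burnt-in annotation parses into structured BI-RADS fields (right breast,
10:30 position, 2.5 cm from the nipple, radial transducer orientation):

```r
tidy(flags$fields[[1]])
#> # A tibble: 1 × 10
#>   laterality orientation clock_hour clock_minute distance_cm axilla ...
#> 1 RIGHT      RAD                 10           30         2.5 FALSE  ...
```

Scoring works from confusion counts; for example, the counts of the improved
Hough-based caliper detector on the external case-study dataset give

```r
cm <- confusion_matrix(tp = 117, fp = 50, tn = 603, fn = 10)
round(100 * sensitivity(cm), 1); round(100 * specificity(cm), 1)
#> [1] 92.1
#> [1] 92.3
```

i.e. 92.1% sensitivity and 92.3% specificity.

Batch use mirrors the same functions: `process_directory()` writes a per-image
CSV/JSON-lines report, `generate_suite()` writes a labeled phantom suite, and
`score_manifest()` compares any prediction table to a ground-truth manifest.
A thin command-line wrapper with `process` / `synthesize` / `evaluate`
subcommands is installed at `inst/cli/buscurate.R`.

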