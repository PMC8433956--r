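---
title: "Measuring wound area from photographs: method, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wound area from photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundsizer)
```

## The problem

Chronic-wound care needs a repeatable, contact-free estimate of lesion
area so that healing can be tracked over time. `woundsizer` implements a
deterministic image-processing pipeline that segments a dark lesion on a
lighter skin background in a single photograph, sums the segmented
contour areas in pixels, and converts that pixel area to cm² from the
photograph's physical-resolution (DPI) metadata. It also implements the
companion calibration arithmetic for comparing two devices that measure
the same wounds (per-image differences, mean absolute percentage error,
multiplicative adjustment).

## The pipeline

`run_pipeline()` executes a fixed stage sequence; each intermediate is
retained (labels a–i):

1. **a — grayscale.** BT.601 luma, `0.299R + 0.587G + 0.114B`.
2. **b — box blur.** 19 × 19 windowed mean, borders by symmetric
   reflection. Suppresses sensor noise and skin texture before
   thresholding.
3. **c — Otsu threshold + inversion.** The threshold maximizes the
   between-class variance of the 256-bin histogram (ties broken toward
   the smallest threshold); pixels above it map to white. Because the
   wound is darker than skin, the binarized image is then inverted so
   the lesion is foreground (white).
4. **d — contour filter.** All contours are traced (outer boundaries of
   8-connected foreground regions and their holes) and foreground
   regions whose outer-contour area is below 50 px² are erased.
5. **e/f — morphological closing.** Dilation then erosion with an
   11 × 11 elliptical structuring element joins fragments of the lesion
   while approximately preserving area.
6. **g — Canny edges** of the closed mask (Sobel gradients,
   non-maximum suppression, hysteresis at 100/200). On a binary mask
   the step-edge gradient dwarfs any mid-range threshold pair, so the
   thresholds are insensitive here.
7. **h — edge dilation.** The thin edge ring is dilated with the same
   11 × 11 ellipse to merge nearby fragments.
8. **i — final contours.** Contours of the dilated edge image are
   traced; those below 50 px² are discarded; of the rest, only contours
   with at least the **mean** contour area are kept, and their shoelace
   polygon areas are summed.

The summed pixel area is converted with `measure_wound()`:
`value_cm = value_px × 2.54 / DPI` per axis, image width and height
rounded to 2 decimals *before* multiplying into the frame area in cm²,
and the wound area reported as the wound pixel fraction of that frame
area, to 4 decimals. That rounding order is deliberate — it is the
reporting convention of the measurement tables the package reproduces
(e.g. a 706 px, 300 DPI height is 5.98 cm; a 749,772 px frame is
8.99 × 5.98 = 53.7602 cm²; a 54,746.5 px wound is 3.9254 cm²). When a
stated frame pixel area and height are supplied without a width, the
width is derived as `total_area_px / height_px`, which keeps every
downstream number consistent with the stated frame area.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `blur_kernel` | 19 | px | noise suppression before Otsu |
| `morph_kernel` | 11 | px | closing ellipse; sets the gap size that gets bridged |
| `min_contour_area` | 50 | px² | speck rejection (strictly-below cutoff) |
| `canny_low`, `canny_high` | 100, 200 | gradient units | hysteresis; insensitive on binary masks |
| `edge_dilate_kernel` | 11 | px | post-Canny merge radius |
| `min_class_separation` | 20 | gray levels | "no wound" guard (below) |
| `dpi_override` | — | dots/inch | used only when the file has no resolution metadata |

All kernels are odd so the operators are centred and unbiased in
position.

### The no-wound guard

Otsu's method always returns *some* threshold. On a lesion-free
photograph the 19 × 19 blur flattens sensor noise to a near-constant
image, and the resulting split separates the two class means by only a
gray level or two — segmenting it would promote noise to "wound". The
pipeline therefore reports **no wound detected** (zero areas, not an
error) whenever the class means of the blurred image are closer than
`min_class_separation` (default 20). The default sits two orders of
magnitude of contrast between blurred noise (≈1–2 levels) and the
several-tens-of-levels contrast a lesion has against skin, so it does
not interact with normal operation.

## Numerical and representational choices

* **Rounding** is half-away-from-zero throughout the reporting path
  (`round_half_away()`); base R's half-to-even cannot reproduce the
  published tables.
* **Border policy**: reflection for the blur; background (zero) padding
  for morphology, so erosion removes a border band from an all-white
  mask. A consequence is that the erosion/dilation duality
  `erode = invert ∘ dilate ∘ invert` holds exactly only beyond one
  structuring-element radius from the border; tests check it there.
* **Elliptical footprint**: cell (di, dj) belongs to the k × k ellipse
  iff `(di/r)² + (dj/r)² ≤ 1` with `r = (k−1)/2`, so the footprint is
  reproducible across platforms.
* **Contour areas** are shoelace polygon areas over the full traced
  vertex sequence (Moore-neighbour border following, 8-connected
  foreground, 4-connected background, raster-scan discovery order). The
  traced boundary of a filled n × n square has area (n−1)²: polygon
  areas run through pixel centres and undercount pixel counts by about
  the half-perimeter. A reported area like 54,746.5 px² (non-integer)
  is only possible under this convention, which is why it was adopted.
* **Hole contours** stay in the contour set; their areas enter the mean
  filter and the final sum. For a ring-shaped final region the interior
  hole falls below the mean area and is dropped, so in practice the
  outer boundary alone is measured.
* **Degenerate inputs**: constant images raise a degenerate-histogram
  error at the operator level; the pipeline converts that (and the
  low-contrast case) into a structured no-wound result.
* **Missing DPI is a hard error.** Resolution metadata is read from the
  PNG `pHYs` chunk, the JPEG JFIF density, or TIFF tags 282/283/296.
  Uploads and messaging apps routinely strip this metadata; silently
  assuming a default would silently mis-scale every area, so the
  package refuses unless an explicit `dpi_override` is given. EXIF
  fields (including orientation) are not interpreted. PNG stores
  integer pixels-per-metre, so 300 DPI round-trips as 299.9994; DPI
  comparisons therefore use a 0.1% tolerance. The TIFF writer is a
  minimal uncompressed implementation carrying the resolution tags,
  written because the available TIFF writer cannot store them; JPEG
  density is patched into the standard JFIF APP0 segment (integer DPI).

## The synthetic validation data

No clinical photographs ship with the package. `synth_wound_spec()` /
`generate_wound()` emulate the relevant features of a wound photograph:
a 1024 × 706 px frame at 300 DPI, a skin-tone background
(RGB 205/160/140, luma ≈ 171), dark-red elliptical or smoothed-blob
lesions (default RGB 120/32/28, luma ≈ 58 — a contrast of ~115 gray
levels), additive Gaussian sensor noise (σ = 8 per channel, clipped),
optional small dark distractor specks (below the 50 px² cutoff) and an
optional linear illumination ramp. Noise comes from R's
Mersenne-Twister with inversion normals under an explicit seed, and
rasterization is integer-based, so fixtures are bit-stable across runs
and platforms. The ground truth (pixel mask, pixel count, traced
contour area, cm² equivalent) is the exact rasterized lesion before
noise.

What the generator does **not** model: photorealistic skin texture,
specular glare, camera-distance variation, shadows, perspective. A
passing synthetic suite therefore demonstrates correctness of the
*algorithmic chain*, not clinical accuracy on real photographs.

`make_fixture_suite()` writes a reproducible suite cycling through
single-lesion, two-lesion, distractor and low-contrast scenarios; the
low-contrast case (luma contrast < 20) is flagged `expected_failure` in
the manifest because it falls under the no-wound guard by construction.

## Known limitations: the edge-band bias

The final area is taken from the contours of the *dilated Canny edges*
(stages g–i), exactly as the stage sequence prescribes. Geometrically
this measures the outer boundary of an edge band that extends roughly
`edge_dilate_kernel/2 + 1` ≈ 6 px beyond the true lesion boundary, so
the method systematically **overestimates**: for an ellipse with
semi-axes (a, b) the measured area is close to π(a+6)(b+6) against a
truth of πab — about +9% for a 59,000 px² near-circular lesion, growing
to about +40% at 3,600 px². The package's validation suite measures
this bias directly (it is positive for every fixture and shrinks
monotonically with lesion size), and the per-stage log records both the
closed-mask (stage f) and final (stage i) areas so users can see the
two numbers side by side. Practical consequences: areas of small
lesions are best compared longitudinally (the bias is stable for a
given size) rather than absolutely, and reducing `edge_dilate_kernel`
reduces the bias at the cost of less aggressive fragment merging.

Also inherited from the method: all detected regions are summed into a
single area (no per-wound breakdown), and nothing corrects for
camera-to-skin distance — the DPI metadata is trusted as the sole scale
reference.

## Cross-device calibration

`compare_measurements()` takes paired areas (reference device vs test
device) and computes per-image differences (`round2(test − ref)` cm²,
`round1(100·(test − ref)/ref)` %) and the mean absolute percentage
error, MAE = mean |percent difference| (unrounded internally, reported
to 1 decimal). `adjust_measurements()` applies the multiplicative
calibration `round2(test × (1 + MAE))` and recomputes the differences.
On the shipped ten-pair device data the MAE is 36.1% and adjusting by
it shrinks the mean absolute difference to about 21% — a coarse
single-factor calibration, deliberately free of any fitted model.

```{r calibration}
cal <- compare_measurements(device_comparison())
glance(cal)
head(adjust_measurements(device_comparison(), cal$mae_fraction), 3)
```

## A worked run

```{r pipeline}
g <- generate_wound(synth_wound_spec(
  width_px = 320, height_px = 240,
  lesions = list(list(shape = "ellipse", center = c(160, 120),
                      semi_axes = c(60, 40))),
  seed = 5))
res <- run_pipeline(list(pixels = g$pixels, meta = g$meta))
res
tidy(res)
g$truth$true_contour_area_px   # ground truth for comparison
```

## Problem sizes used in the test suite

Operator properties are exercised on small random images (8–64 px a
side, hundreds of cases) against brute-force oracles; end-to-end
recovery uses twenty full-frame 1024 × 706 fixtures spanning traced
lesion areas from ≈3,600 to ≈59,000 px² (the closing kernel imposes a
minor-axis floor of 3 × 11 px, which puts the smallest realizable
fixture near 3,600 px²), plus two-lesion and distractor scenarios.
These sizes keep the whole suite within a few minutes on one CPU while
covering the size range over which the edge-band bias varies most.
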