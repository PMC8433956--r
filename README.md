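# woundsizer

Measures the area of a skin wound, in cm², from a single photograph.

Clinicians tracking chronic wounds need a contact-free, repeatable area
estimate. `woundsizer` implements a deterministic segmentation pipeline
for photographs of dark lesions on lighter skin, plus the calibration
arithmetic for comparing two devices that measure the same wounds. It
is aimed at researchers and tool builders who need the full method —
every intermediate image, every parameter — rather than a black box.

## The method

For an RGB photograph *I* with physical resolution *DPI*:

1. grayscale: `Y = 0.299 R + 0.587 G + 0.114 B`
2. box blur, 19 × 19 window (borders reflected)
3. Otsu threshold *t\** = argmax over t of ω₀(t)·ω₁(t)·(μ₀(t) − μ₁(t))²,
   then inversion so the dark wound becomes white
4. contour tracing (Moore border following, 8-connected); regions with
   contour area < 50 px² removed
5. morphological closing with an 11 × 11 elliptical structuring element
6. Canny edge detection on the closed mask, then dilation of the edges
   with the same ellipse
7. final contour pass: drop areas < 50 px², keep contours with at least
   the mean area, sum their shoelace polygon areas → `A_px`
8. metric conversion (per axis): `value_cm = value_px × 2.54 / DPI`;
   the wound area is the wound's pixel fraction of the frame area in
   cm²:
   `A_cm² = A_px / (W_px·H_px) × (W_cm × H_cm)`

Cross-device calibration: for paired areas (reference, test) the
per-image difference and percent difference are computed, the mean
absolute percentage error `MAE = mean |Δ%|` summarizes the
disagreement, and `test × (1 + MAE)` is the adjusted series.

DPI metadata is read from PNG `pHYs`, JPEG JFIF density, or TIFF
resolution tags; a file without resolution metadata is a hard error
unless an explicit `dpi` override is given, because a guessed DPI
silently rescales every area.

## A worked example

No clinical images ship with the package; the built-in generator makes
photographs with exact ground truth:

```r
library(woundsizer)

g <- generate_wound(synth_wound_spec(
  width_px = 320, height_px = 240,
  lesions = list(list(shape = "ellipse", center = c(160, 120),
                      semi_axes = c(60, 40))),
  seed = 5))
res <- run_pipeline(list(pixels = g$pixels, meta = g$meta))
res
#> <wound_pipeline>
#>   image: 320 x 240 px at 300 x 300 DPI
#>   wound area: 9361.0 px^2 = 0.6705 cm^2 (1 contours kept)
g$truth$true_contour_area_px
#> [1] 7384
```

The measured 9,361 px² exceeds the true traced-contour area 7,384 px²:
the final area is the outer boundary of the dilated Canny edge band,
which sits ~6 px outside the true lesion boundary. This positive bias
is intrinsic to the stage sequence, shrinks with lesion size, and is
discussed with measurements in the methods vignette
(`vignettes/wound-area-measurement.Rmd`).

The conversion arithmetic on its own, for a 706 px-tall, 749,772 px
frame at 300 DPI with a 54,746.5 px² wound:

```r
measure_wound(54746.5, 749772, 706, 300)[, 5:8]
#>   width_cm height_cm total_area_cm2 wound_area_cm2
#> 1     8.99      5.98        53.7602         3.9254
```

And the device calibration on the shipped ten-pair comparison data:

```r
cal <- compare_measurements(device_comparison())
glance(cal)
#>       n mae_pct mae_fraction
#> 1    10    36.1        0.361
adjust_measurements(device_comparison(), 0.347)   # published factor
```

A command-line front end covering batch measurement, comparison and
fixture generation is installed at
`system.file("cli", "woundsizer.R", package = "woundsizer")`:

```sh
Rscript woundsizer.R measure --dpi 300 photo1.png photo2.jpg
Rscript woundsizer.R compare --adjust-auto pairs.csv
Rscript woundsizer.R synth --out fixtures/ --n 4 --seed 1
```

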