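# vesselcalibre

Fully automated detection and calibre measurement of blood vessels in
retinal images.

Retinal vessel diameters carry clinical signal — narrowing, widening
and calibre variability are associated with hypertension, diabetes and
cardiovascular risk — but computer-assisted measurement tools require a
user to draw each cross-section by hand, which limits throughput and
introduces observer bias. `vesselcalibre` measures a diameter at every
point along every detected vessel segment in a fundus photograph or
fluorescein angiogram, with no manual input, in seconds per image.

## Method

The pipeline has two parts:

**Segmentation by wavelet thresholding.** The isotropic undecimated
wavelet transform (à trous/starlet scheme) decomposes the image by
repeated lowpass filtering with zero-upsampled cubic B-spline kernels
h = [1,4,6,4,1]/16; wavelet planes are differences of successive
scaling planes, *w*<sub>j</sub> = *c*<sub>j−1</sub> − *c*<sub>j</sub>,
and reconstruction is pure addition. Summing the levels with the best
vessel contrast (levels 2–3 for ~565-px fundus images) and marking the
lowest 20% of coefficients inside the field of view (highest for
angiograms) yields a binary mask, cleaned by removing small objects
and filling small holes (each 0.05% of the FOV area by default).

**Centreline extraction and sub-pixel edge location.** The mask is
thinned to a skeleton (distance-ordered homotopic thinning), branch
pixels are removed to split the tree into measurable segments, spurs
are pruned and unmeasurably short segments dropped using a diameter
estimate from the distance transform. A least-squares parametric cubic
spline (centripetal parameterisation, ~10 px between breaks) smooths
each centreline and supplies perpendicular directions; intensity
profiles interpolated along the perpendiculars form a straightened
vessel image. After anisotropic Gaussian smoothing with
σ<sub>∥</sub> = 2√w along the vessel and σ<sub>⊥</sub> = 0.1√w across
it (w an automatic width estimate), each vessel edge is localised to
sub-pixel accuracy as a zero-crossing of the second derivative,
crossings are linked into trails along the vessel, trails far from the
predicted edges (e.g. from the central light reflex) are rejected, and
the diameter is the Euclidean distance between the left and right edge
points. For a Gaussian cross-section of scale σ the noise-free measured
diameter converges to 2√(σ² + σ<sub>⊥</sub>²).

A synthetic phantom generator (`phantom_suite()`, `render_phantom()`)
provides vessel images with exact ground truth — known centrelines,
widths, optional central light reflex and noise — so every stage is
testable without any external image database.

## Worked example

Measure a phantom containing seven rectangle-section vessels of true
width 9 px:

```r
library(vesselcalibre)

ph  <- render_phantom(phantom_suite()$rect_w9)
res <- measure_image(ph$image)
m   <- subset(res$measurements, valid)

cat("segments:", length(res$chains), "\n")
cat("profiles measured:", nrow(res$measurements), " valid:", nrow(m), "\n")
cat("mean diameter (px):", round(mean(m$diameter), 3), "\n")
head(m[, c("segment_id", "profile_index", "centre_row", "centre_col", "diameter")], 3)
```

```
segments: 7
profiles measured: 1645  valid: 1645
mean diameter (px): 9.006
  segment_id profile_index centre_row centre_col diameter
1          1             1   18.00978   10.99815 8.977978
2          1             2   17.99923   11.99809 8.978596
3          1             3   17.99320   12.99807 8.979783
```

Every one of the 1645 perpendicular profiles yields a valid sub-pixel
measurement; the mean recovered diameter is 9.006 px against a true
width of 9 px. Each row gives the centreline point the profile passes
through and the distance between the two detected edge points.

The same pipeline runs from the shell on image files
(PNG/TIFF/JPEG in; PNG mask, CSV tables and a JSON report out):

```sh
vesselcalibre run fundus.png --levels 2,3 --threshold 20 --out results/
vesselcalibre phantom gauss4 --out phantoms/
vesselcalibre eval pred.png truth.png fov.png
```

Segmentation accuracy against a manually segmented reference is
computed with `evaluate_segmentation()` (TPR, FPR and accuracy inside
the FOV).

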