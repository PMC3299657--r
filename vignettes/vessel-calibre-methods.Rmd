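---
title: "Measuring retinal vessel calibre: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel calibre: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vesselcalibre` detects blood vessels in retinal images — fundus
photographs, where vessels are dark on a bright background, and
fluorescein angiograms, where they are bright — and measures a diameter
at every point along every detected vessel segment, with no user
interaction. This vignette explains the model behind each stage, the
parameters that matter, what the synthetic phantoms do and do not
emulate, and the numerical decisions taken where the design was open.

## The pipeline at a glance

1. **Segmentation.** The image is decomposed with the isotropic
   undecimated wavelet transform (IUWT); the wavelet levels with the
   best vessel contrast are summed and thresholded at a percentile of
   the field-of-view (FOV) coefficients; small objects are removed and
   small holes filled.
2. **Centrelines.** The binary mask is thinned to a skeleton; branch
   pixels are removed to divide the vascular tree into segments; spurs
   and unmeasurably short segments are pruned, using a diameter
   estimate from the distance transform.
3. **Geometry.** A least-squares parametric cubic spline smooths each
   centreline and supplies tangents, hence perpendicular directions;
   intensity profiles sampled along the perpendiculars form a
   "straightened" vessel image.
4. **Edges.** Each edge is located to sub-pixel accuracy as a
   zero-crossing of the second derivative across the smoothed profile
   stack, linked along the vessel into trails; the diameter is the
   Euclidean distance between the left and right edge points.

## Segmentation by wavelet thresholding

The IUWT (the *à trous* or starlet scheme) repeatedly lowpass-filters
the image with the cubic B-spline kernel $h = [1,4,6,4,1]/16$, upsampled
at iteration $j$ by inserting $2^{j-1}-1$ zeros between taps. Scaling
planes $c_j$ are produced by separable filtering of $c_{j-1}$ (with
$c_0$ the image), and wavelet planes are plain differences,
$w_j = c_{j-1} - c_j$, so the image is recovered exactly by addition:
$c_0 = c_J + \sum_{j\le J} w_j$. Wavelet planes have zero mean, and
features of spatial scale comparable to the filter footprint appear
with the best contrast on the corresponding level. For ~565-px fundus
images, levels 2–3 suit typical vessel widths; wider vessels or higher
resolutions call for higher levels — this is the one parameter that
routinely changes between image types.

Thresholding marks the lowest `threshold_percent` (default 20%) of
summed coefficients inside the FOV for fundus images, or the highest
for angiograms. Because the true vessel fraction of a fundus FOV is
typically 10–15%, a 20% threshold deliberately oversegments; the
misclassified pixels cluster into small isolated objects that
small-object removal (default `0.05%` of the FOV pixel count) deletes,
while small holes inside vessels are filled (same default). Remaining
false detections are handled later by the centreline-length filter.

Numerical decisions:

* **Quantile ties.** The threshold value is the $k$-th smallest FOV
  coefficient with $k = \mathrm{round}(p/100 \cdot n)$, and *all*
  pixels equal to it are included. The selected count can exceed $k$
  when ties exist; determinism was preferred over exactness of count.
  A perfectly constant coefficient image therefore selects the whole
  FOV (with a warning) — degenerate, but reproducible; the skeleton of
  a full-FOV mask is subsequently discarded by the length filter, so a
  featureless image yields no measurements rather than arbitrary ones.
* **Connectivity.** Objects are 8-connected, holes 4-connected (the
  standard duality); the image border never bounds a hole.
* **FOV.** When no mask is supplied, the FOV is the largest connected
  component of `image > fov_threshold` (default 20 on the 0–255 scale,
  best applied to the red channel of a colour image), eroded by a
  square structuring element of side `2*fov_erosion_radius + 1`
  (default radius 1). Erosion treats everything outside the image as
  background, so the border is always eroded.
* **Boundary handling.** All filtering uses mirror (half-sample
  symmetric) extension, which avoids the dark-border artefacts that a
  zero extension would inject into FOV-edge coefficients, and makes
  composed separable filtering exactly equal to convolution with the
  composed kernel (the property the test-suite oracle checks).
* **Level clamping.** If the upsampled filter footprint at some level
  would exceed twice the smaller image extent, deeper levels are
  dropped with a warning; such scales are meaningless for the image.

## Centreline extraction

Thinning uses the Guo–Hall two-subiteration deletion conditions applied
in *distance-ordered* fashion: pixels are considered for deletion in
increasing order of their Euclidean distance to the background
(quarter-pixel layers). Plain iterative thinning can let the skeleton
drift by a pixel or two where the mask boundary is stepped — visible at
segment ends; ordering deletions by the distance transform keeps the
skeleton on the distance ridge, i.e. the medial axis, while preserving
homotopy (deletion conditions are unchanged, so component and hole
counts never change).

Skeleton pixels with three or more 8-neighbours are branch pixels and
are removed, splitting the tree into simple paths and loops. Diameters
are not well defined at branches, and measurements across a bifurcation
are not comparable anyway. Chains shorter than `spur_length` pixels
(default 10) are deleted; where such a deletion leaves a removed branch
cluster adjacent to exactly two surviving chains — the signature of a
thinning spur — the cluster is bridged by a shortest pixel path and the
two chains merged, so spurs do not fragment their parent vessel. A
Euclidean distance transform of the mask then gives each chain a coarse
diameter estimate (twice the maximum transform value along the chain),
and chains with fewer pixels than their estimated diameter are
discarded as unmeasurable.

Tracing starts at the lexicographically smallest end pixel for
determinism; isolated loops (e.g. a vessel forming a closed ring in the
mask) are cut at their lexicographically smallest pixel and processed
as open chains flagged `is_closed`.

## Centreline refinement and profiles

Discrete pixel chains are poor sources of orientation, so each chain is
fitted with a least-squares parametric cubic spline: each coordinate is
a piecewise cubic in the centripetal parameter
$t_{i+1} = t_i + \lVert p_{i+1}-p_i \rVert^{1/2}$, which damps the
overshoot chord-length parameterisation produces at tight bends. The
chain is divided into `max(1, floor(n / break_spacing))` pieces of
equal parameter span (default `break_spacing` 10 px; `floor` was chosen
where rounding was open, so short chains never get more pieces than
their points can constrain); chains too short for even one constrained
piece fall back to a single cubic, and chains of fewer than four points
to a lower-order polynomial.

The spline is resampled at approximately 1-px arc-length steps. Cubic
arc length has no closed form, so it is approximated by dense parameter
evaluation (10 times the chain resolution) with cumulative chord
lengths. Normals are tangents rotated by +90°, with signs propagated
along the vessel so the two sides of the profile stack stay consistent.

At each sample, `profile_length` points at 1-px spacing along the
normal are interpolated — bilinearly from the grayscale image, by
nearest neighbour from the binary masks. `profile_length` is set to
twice the largest diameter estimate in the image, so profiles stretch
beyond even the widest vessel with room for filtering. Two binary
stacks accompany the intensities: `own_vessel` (the run of segmented
pixels connected to the centre column within each profile — resolving
the connected-region rule per profile keeps it robust and fast) and
`excluded` (other vessels, pixels outside the FOV, and samples falling
outside the image, which carry `NA` intensity and are excluded from all
averaging).

## Sub-pixel edge identification

An edge is defined as a local extremum of the intensity gradient across
the vessel, located to sub-pixel accuracy as a zero-crossing of the
second derivative. Four steps per segment:

1. **Provisional width** $w_0$: the median of the per-profile sums of
   `own_vessel` (even counts average the two central values).
2. **Predicted edge columns**: the profiles are averaged column-wise
   (excluded samples omitted) and the extremal central-difference
   gradients located within $w_0$ columns of the centre — the most
   negative gradient on the left and most positive on the right for a
   dark vessel, swapped for bright. Their separation is the refined
   width $w$, which is largely independent of the segmentation
   threshold — the property that makes the whole measurement robust to
   the binarisation stage.
3. **Smoothing and differentiation**: the stack is smoothed with an
   anisotropic Gaussian, $\sigma_\parallel = 2\sqrt{w}$ down the stack
   (along the vessel) and $\sigma_\perp = 0.1\sqrt{w}$ across it, so
   wider vessels receive more smoothing and blur is oriented along the
   vessel rather than across its edges. Because the filter acts on the
   straightened stack, it is effectively oriented parallel to the
   vessel at every point. Invalid samples are handled by normalised
   (mask-weighted) convolution. The second derivative across the
   vessel is the stencil $[1,-2,1]$ applied along each profile.
4. **Trail linking**: per-profile sign changes of the second derivative
   are located by linear interpolation, classified by direction (for a
   dark vessel the lumen is a dip, hence convex, so its interior second
   derivative is positive: the left edge is a $-\!\to\!+$ crossing and
   the right edge $+\!\to\!-$; exact zeros count as positive, a
   deterministic convention), and candidates inside excluded regions
   are dropped. Candidates are linked into 8-connected trails per side;
   trails that never come within $w/3$ of the predicted edge column are
   removed — this is what rejects the central light reflex, whose
   crossings sit near the vessel middle — and the trail spanning the
   most profiles survives (ties broken by smaller mean distance to the
   predicted column). A profile yields a valid measurement only when
   both surviving trails cross it; nothing is interpolated across
   invalid profiles — no measurement is preferable to a fabricated one.
   The refined width $w$ (not the provisional one) feeds the $w/3$
   test, since step 2 precedes step 4 and is the better estimate.

For a vessel with an exact Gaussian cross-section of scale $\sigma$,
the zero-crossings of the smoothed second derivative sit at the
inflection points of a Gaussian of variance $\sigma^2+\sigma_\perp^2$,
so the noise-free measured diameter converges to
$2\sqrt{\sigma^2+\sigma_\perp^2}$ — the closed form the acceptance
checks use. The discrete $[1,-2,1]$ stencil biases this by under 1% at
$\sigma = 4$ px, within the 2% tolerance asserted.

## The phantom generator

`phantom_spec()` / `render_phantom()` produce synthetic vessel images
with exact ground truth: straight, circular-arc (including full-circle)
or polyline centrelines; Gaussian or blurred-rectangle cross-sections;
an optional central light reflex (a narrow Gaussian ridge of opposite
contrast along the centreline); a flat or radially bowed background;
and additive white Gaussian noise under a fixed seed. Intensities are
analytic — exact point-to-segment and point-to-arc distances feed the
profile functions, and the blurred rectangle uses the closed-form
Gaussian-convolved box — so rendering error does not contaminate
accuracy measurements. Poisson noise is not modelled: the images the
method targets are not photon-count calibrated.

`phantom_suite()` freezes the fixtures used throughout the tests. Two
design rules matter:

* **Vessel fraction.** Each image carries enough vessels that the true
  vessel fraction of the FOV sits near the 10–15% regime of real
  fundus photographs, the operating point the default 20% threshold
  assumes. A sterile image with a single thin vessel would force the
  percentile quota to be filled by meaningless background structure —
  a mismatch of conditions, not an algorithm property.
* **Segment ends.** Straight vessels end in round caps inside the
  image, and curved vessels are closed circles, because a vessel cut
  flat by the image border has a medial axis with 45° corner branches:
  a skeleton tip at such a cut genuinely leaves the vessel axis. The
  reported true centreline extends through each cap to the limit of
  the rendered support, which is where a medial-axis skeleton of the
  capped vessel can end.

Ground truth reports the vessel mask (half-width $\sigma$ for Gaussian
sections — the inflection edges — and half the width for rectangles),
dense centrelines at 0.25-px spacing, true widths, and the analytic
expected diameter. `match_chains()` implements the usual evaluation
protocol: a detected chain is compared against the vessel whose true
centreline it follows, and chains matching no vessel are reported as
spurious rather than silently mixed into accuracy statistics.

What the phantoms do *not* emulate: the optic disc and macula,
branching trees, pathology (exudates, haemorrhages), vignetting and
non-white sensor noise, and the intensity statistics of real fundus
cameras. Passing tests demonstrate correctness of the mechanics and
closed-form accuracy in controlled conditions, not clinical
performance; segmentation accuracy on real data should be evaluated
against manually segmented references with `evaluate_segmentation()`.

A note on noise: the edge detector's robustness rests on the contrast
between the smoothed second-derivative signal and noise. Blurred
step edges (rectangle sections, and real vessel walls) keep a strong
second-derivative peak and measure reliably down to contrast-to-noise
5; pure Gaussian cross-sections have much softer curvature at the
inflection and degrade sooner. The noisy fixtures therefore pair white
noise with rectangle sections for quantitative spread checks, and the
Gaussian noise fixtures exist to exercise, not to certify, the soft
limit.

## Problem sizes and runtime

All phantoms are 256×256 with vessel families of 3–9 segments; the
full test suite (≈980 assertions, including every end-to-end pipeline
run) completes in about half a minute on one CPU, and the acceptance
script in under a minute. These sizes were chosen because every
quantity the package asserts — reconstruction error, centreline
deviation, diameter bias and spread — is already stable at this scale;
larger images change runtimes, not conclusions.

## Known limitations

* Diameters are undefined at branch points by construction; segments
  shorter than their own width are discarded, so very short vessel
  stubs are never measured.
* Measurement near the FOV boundary depends on profiles that may leave
  the FOV; such samples are excluded and the affected profiles are
  reported invalid rather than extrapolated.
* The light-reflex defence assumes the reflex is narrower than about a
  third of the vessel width; an extreme reflex approaching the vessel
  width would defeat the $w/3$ trail test.
* Wavelet level choice remains a per-resolution user decision; very
  wide vessels analysed with too-fine levels produce bimodal
  coefficient profiles whose thresholded mask can split into two
  parallel strips.
* The tie-inclusive percentile threshold can select substantially more
  than the requested fraction on images with large perfectly-uniform
  regions (synthetic data); natural images are unaffected.
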