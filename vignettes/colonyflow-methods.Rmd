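---
title: "Methods: colony extraction and collective motion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony extraction and collective motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyflow)
```

## The problem

Human epidermal keratinocyte stem cells are expanded for transplantation in
co-culture with growth-arrested 3T3 fibroblast feeders. Colonies founded by
cells with high proliferative potential show high collective locomotion,
while "clonal conversion" — the irreversible loss of stemness — manifests as
slow colonies. A noninvasive, automated quality-control readout therefore
needs two things: (i) find the colony in a phase-contrast field that also
contains feeder cells, and (ii) measure how fast the cells inside it move.
`colonyflow` implements both, plus the evaluation and screening statistics
around them and a synthetic-scene generator that provides ground truth for
every stage.

## Colony extraction

Extraction pools two per-cell landmark channels and smooths them into a
colony-membership likelihood.

**Nucleolus channel.** In phase contrast the nucleolus is a dark spot and
the nucleus a dark ring around it. `detect_nucleoli()` adaptively binarizes
the frame (dark polarity), labels connected components, keeps components
with area in `[nucleolus_min_px, nucleolus_max_px]` = `[12, 72]` px, and
accepts a component's rounded centroid as a landmark only if (a) the
centroid pixel lies in the component itself and (b) the component is
enclosed by a second dark region — operationally: no 4-connected background
path from the component reaches the image border without crossing other
foreground. Ring-less dark debris (feeder fragments, noise) fails (b);
crescents whose centroid falls outside themselves fail (a). The published
size rule reads "regions of ≥12 pixels or ≤72 pixels"; a literal OR keeps
every region, so it is implemented as the inclusive range `[12, 72]` and
exposed in the configuration.

**Boundary channel.** Colony cells are outlined by a bright mesh of
cell-cell boundaries that feeders lack. `extract_boundary_mask()` binarizes
with bright polarity, applies a 3×3 morphological opening then closing
(element size is not specified in the source method; 3×3 with one iteration
each is the minimal choice and is what "eliminate small spots or
protrusions" needs), and removes regions of `boundary_min_region_px` = 250
px or less. `zhang_suen_thin()` reduces the mesh to 1-px curves with the
classic two-subiteration scheme, followed by a pruning pass that deletes
topology-preserving corners of residual 2×2 blocks (a known Zhang–Suen
artifact that would otherwise create spurious junctions). Branch points are
skeleton pixels with crossing number

$$CN = \tfrac12 \sum_{i=1}^{8} |P_i - P_{i+1}|, \qquad P_9 = P_1,$$

equal to exactly 3; the neighbors are traversed clockwise from the top-left
(any fixed cyclic order gives the same value, fixing one makes tests
deterministic). CN = 4 crossings are not branch points by default
(`include_crossings` adds them).

**Density surface.** Nucleoli and branch points together form the sample
points of an isotropic 2-D Gaussian kernel density estimate with bandwidth
`kde_bandwidth` = 151 px,

$$f(x) = \frac{1}{n\,2\pi h^2} \sum_i \exp\!\Big(-\frac{\lVert x - x_i\rVert^2}{2h^2}\Big),$$

the 2-D generalization (proper bivariate normalizer) of the 1-D textbook
form. The surface is computed by separable convolution of a landmark
impulse image with a truncated Gaussian and must agree with the direct sum
— the reference path kept in the package as `method = "direct"`.

Numerical choices worth stating:

* **Truncation at 6h, not 4h.** The kernel tail at 4 bandwidths is still
  `exp(-8) ≈ 3.4e-4` of the peak, which is visible at the 1e-6 relative
  agreement we require between the convolution and direct paths; at 6h the
  tail is `exp(-18) ≈ 1.5e-8`. Configurable via `kde_truncate`.
* **Zero-padded borders.** Reflecting the impulse image would add mirrored
  phantom landmark mass near the borders and break the equality with the
  direct sum, so the convolution is zero-padded. Density near borders is
  genuinely lower — exactly as the direct sum says it is.
* **Relative threshold at 0.5 of the maximum.** The source method says only
  "a certain threshold". A relative threshold makes the normalizer
  irrelevant; we default to the half-maximum level set because a Gaussian-
  smoothed indicator crosses half its plateau value exactly at the
  indicator's boundary (the FWHM argument), so the extracted outline tracks
  the true colony edge for any bandwidth. Lower fractions (e.g. 0.2) push
  the contour outward by roughly `h·Φ⁻¹(1-frac)` — over a hundred pixels at
  h = 151 — and systematically over-segment. An absolute-threshold mode is
  available.

The super-threshold pixels are labeled and the largest 8-connected region
is the colony (ties broken toward the earliest raster pixel). Occasional
feeder aggregates that are continuous with the colony are a known failure
mode of the method itself; no corrective step is added.

## Motion analysis

`dense_flow()` estimates per-pixel displacement between consecutive frames.
The original pipeline used OpenCV's DeepFlow with default parameters; the
algorithm's internals are not part of the method's contribution, so the
backend is pluggable behind a contract — for a rigid integer translation of
a textured scene the median recovered vector must be within 0.5 px per
component. Two backends ship:

* `"lk"` — a self-contained pyramidal Lucas–Kanade dense flow
  (coarse-to-fine Gaussian pyramid, 3 warping iterations per level, 15-px
  windowed least squares, Tikhonov-regularized 2×2 solve). Sub-pixel values
  are kept as floats; rounding before averaging would bias small motions
  toward zero, which is exactly the regime of a metabolic-inhibitor screen.
* `"block"` — exhaustive integer block matching (9×9 blocks, ±5 px search,
  candidates scanned in order of increasing magnitude so an untranslated
  scene yields an exactly zero field). It is the deterministic testing
  oracle.

`colony_speed()` averages `sqrt(u² + v²)` over the mask of the *earlier*
frame of each pair (the causal choice; the source method does not say which
frame's region it used) and converts to µm/min with
`pixel_size_um / interval_min`. The pixel size depends on the objective and
camera and is never guessed: without it speeds are reported in px/frame.
The statistical unit for all group comparisons is the per-colony mean
speed; pixelwise samples are exported for violin plots only, which avoids
pseudo-replication.

## Screening statistics

Two conditions are compared with the unpaired two-tailed Mann–Whitney U
test (`stats::wilcox.test`), exact for both groups ≤ 10 without ties — so a
5-vs-5 screen with complete separation bottoms out at
p = 2/C(10,5) = 0.0079 — and a midrank normal approximation with a recorded
tie note otherwise. Three or more conditions use the tie-corrected
Kruskal–Wallis test followed by Dunn's z tests against the designated
control. The multiple-comparison adjustment (Bonferroni over the number of
comparisons, the common companion of Dunn's test; the source does not name
one) is stated in every output record. All-constant input is returned as
H = 0, p = 1 rather than the NaN the raw tie-corrected formula produces.

Segmentation is scored per pixel against a manual mask: undetected =
FN/total, over-detected = FP/total, accurate = (TP+TN)/total, which sum to
1 by construction.

## The synthetic world

`generate_scene()` renders what the pipeline consumes, not photorealism:
dark nucleolus discs (radius 3 px, ~29 px area — inside the 12–72 window)
inside dark nuclear annuli (radii 7–9.5 px), a bright ~3-px-wide mesh along
the edges of the nearest-seed partition of the colony polygon, elongated
dark feeder ellipses and ring-less dark decoy spots outside it, a mild
horizontal illumination gradient (so only adaptive thresholding works), a
static pixel-scale texture field (the granularity optical flow locks onto,
baked into the scene so it moves with it), and fresh Gaussian read noise
per frame. Defaults — 1040×1388 frames, colony radius 280 px, 24-px cell
spacing, 0.25 contrast steps, noise SD 0.015 — are one fixed, realistic
operating point for a 1.4-megapixel monochrome camera; they are stated
here once and not tuned per test.

Motion is applied to the pre-noise scene with `apply_displacement()`
(backward bilinear sampling), and frame t+1 is defined as the warp of frame
t, so warping a clean frame by the ground-truth field reproduces the next
clean frame exactly — the generator's consistency invariant. Because noise
is regenerated per frame, flow estimators must track structure, not noise.

What a green test does *not* establish: robustness to real phase-contrast
halos, debris, mitotic rounding, focus drift, or colonies merging with
feeder aggregates; the generator has none of these. It establishes that
every formula and rule is implemented as stated and that the pipeline's
stages compose correctly end to end.

## Parameters that matter

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `binarize_window` | 41 | px | adaptive-threshold neighborhood |
| `binarize_offset` | 0.03 | intensity | deviation from local mean required |
| `nucleolus_min_px`/`max_px` | 12 / 72 | px | nucleolus area window |
| `boundary_min_region_px` | 250 | px | boundary fragments removed at ≤ this |
| `kde_bandwidth` | 151 | px | Gaussian KDE bandwidth |
| `kde_threshold_frac` | 0.5 | — | fraction of density max (FWHM rule) |
| `kde_truncate` | 6 | bandwidths | kernel truncation radius |
| `flow_backend` | `"lk"` | — | dense flow implementation |
| `pixel_size_um` | — | µm/px | objective-dependent; user-supplied |
| `interval_min` | 5 | min | frame interval |

The local-mean weighting for adaptive binarization is Gaussian with
σ = window/6 (a box mean is available); the source cites an
adaptive-thresholding scheme without naming the weights, and the offset
constant (3% of the intensity range) is likewise a stated default, required
to keep flat background out of the foreground.

## Conventions and limitations

Coordinates are 1-based `(row, col)` with row 1 at the top — the package
follows R's native array indexing rather than a 0-based convention.
Intensities are floats in `[0, 1]` internally with 8-bit I/O at the
boundary. Supported raster formats are PNG, PGM/PPM and CSV matrices;
multi-page TIFF is not read (no TIFF decoder among the package's
dependencies) — export time series as numbered single-frame files.
Centroid rounding breaks `.5` ties toward the smaller index for
determinism. Optical-flow speeds are known to run lower than manual
single-cell tracking on the same recordings; no correction is applied, so
compare speeds only within one method.
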