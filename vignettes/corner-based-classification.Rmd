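---
title: "Corner-based classification of brain slices: methods and design notes"
author: "CornerDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corner-based classification of brain slices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CornerDx)
```

# The method

CornerDx classifies 2-D grayscale brain slices (CT or MRI) into "Normal"
and "Abnormal" by comparing *corner sets* rather than raw intensities.
The premise is clinical: radiologists attend to the morphology of
hypodense and hyperdense regions, and the clearest such structures
(ventricles, lesions, the brain outline) concentrate the diagnostic
information. The pipeline therefore (1) normalizes each slice, (2)
converts it to a *multilayer texture image* (MTI) in which texture
significance is explicit, (3) represents the slice by Harris corners
carrying *importance values*, (4) matches corner sets across slices
under mobility constraints, and (5) classifies by a similarity-weighted
K-nearest-neighbour vote.

## Normalization

Raw slices consist of background, skull and the intracranial portion;
only the last is kept. The skull/tissue interface is the strongest edge
structure, so the intracranial mask is recovered from a Canny-style edge
map: the edge component enclosing the largest interior is selected, with
a descent rule that moves from the outer skull contour to the inner one
when the nested contour encloses a comparably large region (at least
half the area; the skull band is thin). When no closed contour encloses
a plausible region — a broken contour, or an already skull-stripped
image — the mask falls back to the filled largest above-background
component; the fallback also replaces a contour-derived mask smaller
than half the visible foreground, which signals a broken contour.

The mask's orientation is estimated from its second central moments and
the image rotated so the principal axis is vertical. Near-circular masks
(axis ratio < 1.05) have no meaningful orientation and are left alone.
The image is cropped to the mask bounding box, resized bilinearly to a
common (Row, Column) grid — either given, or the round-half-up mean of
the cropped sizes across the set, which is how the study sizes
(285×260 CT, 175×141 MRI) arise — and intensities are divided by the
bit-depth maximum (255 or 65535), *not* the per-image maximum, so CT and
MRI land on one \[0,1\] scale.

## Multilayer texture images

A single Canny edge map is binary: it cannot say which textures are
*clearer* than others. The MTI stacks Canny layers obtained from a
descending schedule of hysteresis double thresholds derived from the
64-bin histogram of gradient magnitudes (Gaussian smoothing σ = 1.4,
3×3 Sobel). For each pixel fraction R in (0.8, 0.7, ..., 0), the bin
index s is the smallest whose ascending cumulative count reaches
R × (pixel count); the layer thresholds are then highTh = s/64 and
lowTh = 0.3 × highTh, as fractions of the maximum magnitude M. Because R
decreases, highTh is non-increasing: the first layer keeps only the
sharpest ~20% tail of the gradient distribution, later layers admit
progressively fainter texture. A pixel first claimed by layer i gets MTI
value 1/i; unclaimed pixels are 0 (background). Identical consecutive
threshold pairs are skipped — under first-layer priority they cannot
claim new pixels.

Two design points deserve note:

* **Ascending cumulation.** One could imagine cumulating the histogram
  from the high-gradient end. We cumulate ascending: highTh = s/Bn with
  Bn = 64 is exactly the classical 64-bin Canny threshold-selection
  heuristic ("the high threshold sits at the R-quantile of gradient
  magnitude"), and only this reading makes the R = 0.8 layer the
  *strictest*, so that the schedule descends from the clearest textures
  as the layering requires.
* **The terminal R = 0 layer** is included (s = 1 there, trivially
  satisfying the cumulative rule), giving N = 9 layers under the default
  schedule; it is configurable off.

All thresholds are fractions of the per-image maximum magnitude, which
makes the MTI invariant under global intensity rescaling — the mechanism
behind the method's robustness to the very different intensity ranges of
8-bit CT and 16-bit MRI. The test suite asserts this invariance exactly
for power-of-two factors; other factors can flip a pixel at a bin
boundary through floating-point rounding.

## Corners with importance values

Harris corners are detected *on the MTI value grid*, not the grayscale
image: corner strength then reflects texture significance, and each
corner inherits the MTI value at its pixel as its importance. The
response uses the classical constant k = 0.04 and a Gaussian structure
tensor window (σ = 1.0); these are conventional choices, exposed as
arguments. The response is normalized by its maximum positive value so
that a threshold θ is comparable across images — the θ search grids
(0.01–0.1 in steps of 0.01) only make sense on a normalized response.
A pixel is a corner iff its normalized response is ≥ θ, it is a local
maximum within a 1-px Chebyshev radius (ties broken row-major), and its
MTI value is positive; response peaks that drift onto background pixels
are discarded rather than snapped, since a corner without importance has
no defined mobility. Because the Harris response scales like the fourth
power of the local MTI amplitude, corners on late, faint layers fall
far below the θ grid: the importance weighting itself prunes noise
corners.

## Mobility-constrained matching

Corners of similar brains occupy similar, but not identical, positions;
the positional slack (mobility) of a corner is the reciprocal of its
importance — a layer-i corner may move i pixels. Two corners from
different images form a candidate pair when their Euclidean distance is
at most the sum of their mobilities. The candidate list is possibly
one-to-many; the final matching is the one-to-one subset of maximum
cardinality and, among those, minimum total distance. This is solved
exactly as an assignment problem: a square cost matrix with non-candidate
cells at BIG = 1 + (sum of all candidate distances), solved by a
Hungarian (shortest-augmenting-path) solver in compiled code. Since every
real edge costs less than BIG, cardinality strictly dominates cost, which
fixes the priority between the two optimality criteria (the two can
conflict; we let cardinality win, as the assignment reduction implies).
Equal-cost optima are resolved deterministically toward lower corner
indices through an infinitesimal perturbation (~1e-9), far below any
meaningful distance difference; reported totals use unperturbed
distances.

## Similarity and classification

For two corner sequences C, C' with final matching CM,

    SIM = W(|C|, |C'|) × Σ_{pairs} MD(dis),   MD(d) = 1 / max(d, ε)

with ε = 0.5 px so a coincident pair contributes a finite 2. The weight
W depends only on the count difference d = ||C| − |C'|| (matched pairs
cancel). The printed piecewise form — 0 when d = 0, 1/log d otherwise —
is singular at d = 1 and makes an image maximally *dissimilar* to
itself at d = 0, which contradicts the surrounding reasoning that few
unmatched corners should mean high similarity; we read the zero branch
as a typographical inversion but do not guess the intended formula.
Instead two modes are exposed: `as_printed` (the literal form, with the
d = 1 singularity capped at 1/log 2) for fidelity experiments, and
`guarded` (default), which assigns the cap 1/log 2 to d ∈ {0, 1} and
1/log d beyond — non-increasing in d and maximal when counts agree. The
logarithm base is unstated in the source formulation; we default to the
natural log (configurable); W is invariant to this choice only up to a
constant factor, which KNN ranking ignores. The similarity sum runs over
matched pairs only; unmatched corners influence SIM solely through W.

Classification is similarity-KNN: the K most similar training images
vote (similarity ties break toward the smaller training index, vote ties
toward the single most similar neighbour). The corner-response threshold
θ and K are selected by stratified k-fold cross-validation over the
study grids θ ∈ {0.01, ..., 0.1}, K ∈ {3, 5, ..., 21} with 5 folds;
the accuracy-maximizing cell is chosen, ties toward smaller K then
smaller θ. Fold assignment is a seeded stratified shuffle (default
seed 17); the fold-construction details are our own, as none are
prescribed. "Normal" is the positive class for the
precision/recall/F1 utilities.

# The synthetic phantom generator

No clinical images ship with the package (the original evaluation sets
are a private hospital CT collection and a restricted-access MRI set),
so a seeded phantom generator makes every stage testable. A phantom is
an 8-bit 192×192 slice: a bright elliptical skull ring (intensity 235,
thickness 5–8 px) on zero background, noisy mid-intensity tissue (115),
and two dark (45) mirrored crescent ventricles near the centre; per
image, the geometry is jittered (rotation ±15°, axes ×0.92–1.0, centre
±2 px). "Abnormal" phantoms add one round lesion (radius 9–14 px,
contrast ±60, hypo- or hyperdense, random side) *and* asymmetric
enlargement (×1.4–1.7) of one ventricle — the mass-effect signature that
distinguishes infarction/hemorrhage slices from normals around the
ventricles. Tissue noise is a spatially *correlated* Gaussian field
(smoothed white noise rescaled to marginal sd 8): reconstructed CT/MRI
noise is correlated, and iid pixel noise would litter the faint texture
layers with spurious corners unrelated to anatomy.

What the phantoms do *not* emulate: partial-volume effects, bias
fields, gyral/sulcal texture, realistic lesion shapes, scanner-specific
noise spectra. Passing the end-to-end check therefore demonstrates that
the pipeline recovers a geometrically consistent class signal through
normalization, texture layering, matching and voting — not clinical
performance.

# Numerical choices and degenerate inputs

* Bin boundaries: gradient bins are ((j−1)M/64, jM/64\] with zero
  magnitudes in bin 1; a cumulative count numerically equal to R×total
  (within 1e-6) selects the smaller bin.
* Flat images: M = 0 gives an all-zero MTI and an empty corner set —
  valid, not an error; an entirely zero slice raises "no foreground" at
  normalization.
* Non-maximum suppression uses the 4-sector quantized gradient
  direction; plateau ties keep both pixels at the edge-thinning stage
  and break row-major at the corner stage.
* Rotation and resizing are bilinear with zero fill; rotated masks use
  nearest-neighbour.
* Corner coordinates are 1-based (row, col), the R convention,
  consistently through matching, similarity and the CSV interfaces.

# Problem sizes used by the checks

The shipped checks run entirely on generated data: the worked 12-vs-9
matching example; 200 random bipartite instances (≤ 8+8 corners)
against an exhaustive-enumeration oracle; 50 random corner-set pairs
against the definition-level candidate filter; 100 random 64-bin
histograms for the schedule rule; 20 toy images for MTI invariants; and
the end-to-end study: 40+40 phantoms, 5-fold stratified CV over the full
θ × K grid, plus a 20-phantom held-out set. With the shipped defaults
(seed 17) the selected classifier reaches 0.925 mean CV accuracy and
0.85 held-out accuracy; these numbers are recomputed, not stored, by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

# Known limitations

* The skull-extraction heuristic assumes a closed, high-contrast skull
  ring or a clean foreground silhouette; pathological contrast or heavy
  artefacts can defeat both routes.
* Principal-axis orientation is only defined up to 180°; a slice scanned
  upside-down stays upside-down.
* The similarity is not a metric (no triangle inequality) and depends on
  corner *counts*, so acquisition differences that change corner counts
  systematically (e.g. different noise levels between cohorts) bias W.
* All pairwise matchings are computed per θ during cross-validation;
  cost grows quadratically in the training-set size.
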