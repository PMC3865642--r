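---
title: "Feature-based contour propagation: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based contour propagation: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Delineating a tumor and the organs at risk (lungs, spinal cord) on every
slice of a thoracic CT volume is a major time cost in radiotherapy planning,
and fully automatic single-slice segmentation fails precisely where it
matters — low-contrast regions such as the hilus pulmonis, where the lung
root meets the mediastinum. `contourprop` implements a middle ground: a
physician delineates **one** slice, and the package carries that contour
through the rest of the stack by registering each slice to its neighbor,
then snapping the carried contour onto local image evidence.

Each propagation step treats the already-delineated slice as the *template*
and its neighbor as the *target*, and runs four stages:

1. **Keypoint detection** on both slices (box-filter Hessian pyramid,
   SURF-style);
2. **Description and matching** (64-dimensional GDLOH descriptors, a
   correlation-aware distance, a ±5 px spatial gate, mutual nearest
   neighbors);
3. **Thin-plate-spline (TPS) warping** fitted to the matched pairs, which
   pushes the contour onto the target slice;
4. **Band-constrained active-contour (snake) refinement** of the pushed
   contour against the target's gradients.

Steps recurse outward from the seed slice in both directions, each step
starting from the previous step's *refined* contour. Agreement is scored by
Jaccard similarity (intersection over union of the rasterized regions) and
by maximum and mean Hausdorff distance between the contours.

## Coordinate convention

All coordinates are `(x, y)` with `x` the column and `y` the row, 0-based;
pixel `(c, r)` occupies `[c, c+1) × [r, r+1)` with center `(c+0.5, r+0.5)`.
Rasterization includes a pixel iff its center lies inside the closed polygon
under the even-odd rule. This convention is a package decision — nothing in
the underlying method fixes one — and it is applied uniformly to detection,
warping, refinement, and scoring, which is all that matters for
consistency.

## Detection and description

The detector locates maxima of the box-filter approximation of the Hessian
determinant, `det H ≈ Dxx·Dyy − (0.9·Dxy)²`, computed on an integral image
at filter sizes 9, 15, 21, … organized in 3 octaves of 4 levels. Maxima are
taken over 3×3×3 scale-space neighborhoods, refined to sub-pixel and
sub-scale position by a quadratic fit, and assigned the orientation of the
dominant Haar-wavelet response over a sliding π/3 window in a 6σ disk. The
detector is deliberately behind a plain function interface
(`detect_keypoints()`): the pipeline depends on its contract (scale- and
orientation-tagged points with strengths), not on the specific kernel.

The GDLOH descriptor samples a 20σ window, rotated to the keypoint
orientation, on a 20×20 grid; each sample contributes horizontal and
vertical Haar responses rotated into the keypoint frame and
Gaussian-weighted (σ = 3.3 in grid units). Sixteen subregions each yield
the four sums `(Σdx, Σdy, Σ|dx|, Σ|dy|)` — 64 values, normalized to unit
length. Two subregion geometries exist because the descriptor's usual
diagram and its 16×4 = 64 arithmetic suggest different layouts: the default
is the 4×4 square grid (which makes the arithmetic exact); a concentric
4-ring × 4-sector variant is available via `layout = "concentric"`.

Matching uses the distance

```
D(P, Q) = (Σ P_i² + Σ Q_i²) · Σ (P_i − Q_i)² / (2 · Σ P_i Q_i)
```

which scales the squared Euclidean distance by the inverse normalized
correlation of the two vectors. Because `Σ P_i Q_i` can be zero or negative
(the signed sums may disagree), such pairs are declared *incomparable* and
excluded rather than given a signed distance that would corrupt
nearest-neighbor ordering. Candidates are restricted **before** the search
to a 10×10 px axis-aligned window (±5 px per axis) around the source
keypoint — adjacent CT slices move by a few pixels, so distant candidates
are noise — and only mutual nearest neighbors are kept, guaranteeing the
one-to-one correspondences a landmark-based fit needs. Descriptors are
unit-normalized before the distance; both the gate-first order and the
normalization are package decisions where the method description is silent.

## The thin-plate spline

With `n ≥ 3` non-collinear control points `P_i` (template) matched to `Q_i`
(target), the map per output coordinate is

```
f(p) = a1 + a_u x + a_v y + Σ_i w_i U(|P_i − p|),   U(r) = r² log r²
```

with `U(0) = 0` by its limit. The weights solve the bordered system
`L (W | a)ᵀ = (V | 0)ᵀ` where `L = [[K, P], [Pᵀ, 0]]`, `K_ij = U(r_ij)`,
`P = [1 x y]`. The zero block is 3×3, the only shape compatible with `P`
being n×3. The side conditions `ΣW = ΣWx = ΣWy = 0` fall out of the border
and make the radial part free of affine leakage; consequently any affine
motion is reproduced with `W = 0` exactly, and with `λ = 0` the fit
interpolates (`f(P_i) = Q_i` to solver precision). `λ > 0` replaces `K`
with `K + λI` for noisy matches (default 0).

Numerical care: duplicate source points (< 1e-6 px apart) are merged with
averaged targets; genuine degeneracy is detected by a condition estimate of
the system built from *unit-scaled* coordinates (TPS interpolation is
scale-equivariant given the side conditions, while the raw system's
condition number grows with the coordinate extent even for perfectly
healthy landmark sets — about 1e13 for points spread over a 256 px frame).
When that scale-free estimate exceeds 1e12, a light automatic
`λ = 1e-6 · mean|K|` is applied with a warning; the off-diagonal mean is
used as the magnitude scale because `K`'s diagonal is identically zero.

Contours are pushed forward vertex-by-vertex (the model maps template to
target coordinates, so no field inversion is needed), clamped to the image,
and resampled to uniform 2 px arc-length spacing — resampling keeps the
snake's continuity term meaningful and makes results independent of the
seed contour's vertex density.

## The band-constrained snake

Refinement minimizes the discrete energy

```
E = Σ_i  α·E_cont(v_i) + β·E_curv(v_i) + γ·E_image(v_i)
E_cont = |d̄ − ‖v_i − v_{i−1}‖|,  E_curv = ‖v_{i−1} − 2v_i + v_{i+1}‖²,
E_image = −‖∇I‖(v_i)
```

with `∇I` the Sobel gradient of the Gaussian-smoothed (σ = 1 px) slice.
Defaults `α = 0.15, β = 0.2, γ = 0.85` are the centers of the empirically
optimized ranges for lung CT. The optimizer is the greedy Williams–Shah
scheme: sweep the vertices in order, score each candidate in a
`(2·window+1)²` grid (window 1 by default), move to the minimizer. Each
term is min-max normalized over the candidate window before weighting —
the three terms are otherwise incommensurate (pixels, pixels², intensity
gradient).

Two design choices deserve explanation:

* **The band is anchored to the initial contour**, not re-centered each
  iteration: every vertex must stay within `band` px (Euclidean, to the
  initial polyline) at all times. Anchoring bounds the *total* drift, which
  is the band's purpose — the registered contour is trusted up to a few
  pixels, and the snake must not be able to walk away from it one iteration
  at a time. The default half-width 5 px (midpoint of the recommended 3–9
  px for 512 px slices) scales proportionally with image width, floored at
  3 px.
* **Monotone energy by construction.** Window-local normalization alone
  does not guarantee that a sweep decreases any global objective, so every
  proposed move is additionally checked against a fixed-normalization
  energy (mean spacing frozen at the initial resampled contour, gradient
  term normalized over the whole slice) over the three affected vertices,
  and rejected if it would increase it. The recorded per-sweep energy trace
  is therefore non-increasing, which also gives a clean convergence
  criterion alongside the moved-vertex fraction (stop below 5%, or at 100
  sweeps).

Ties among candidate minima go to the candidate nearest the current
position, then lexicographically by offset — with the fixed sweep order
this makes refinement fully deterministic.

## Propagation policy

`propagate_volume()` recurses outward from the seed in both directions, at
most 20 slices each way by default (beyond that the prior-knowledge value
of the seed has decayed too far), warning when the slice thickness exceeds
3 mm. Each step requires at least `min_matches = 30` matched pairs; on a
shortfall the step retries once with the detector threshold halved, and if
it still fails the direction halts with a warning — a silent identity copy
would fabricate a contour with no registration evidence behind it. All
structures sharing the seed slice are propagated through the *same* TPS
model per slice pair, fitted once from all matches; feature matching is
structure-agnostic. The refined (post-snake) contour feeds the next step:
refinement is the mechanism that stops registration error from
accumulating, so each step should start from the best available contour.
Keypoints of the shared slice are computed once and reused across steps.

## Metrics

Jaccard similarity is computed on rasterized masks (two empty masks score 1
with a warning, a degenerate case that only arises in synthetic tests).
Hausdorff distances are computed between contours densely resampled at 0.5
px — making values independent of vertex density — with `hd_max` the
classical symmetric maximum and `hd_mean` the average of the two directed
mean distances (average symmetric surface distance; "mean Hausdorff" has no
single standard definition, and this is the common reading). Plain 100%
maxima are reported, not percentile variants. Distances are in pixels, with
mm columns added when the volume carries spacing metadata.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds lung-CT-like stacks with exact ground truth:
two dark elliptical lung fields on a smooth bright background, bright
vascular-like blob chains inside the lungs plus a smaller share of
mediastinal vessels between them, a bright cord disk seated in a darker
vertebral-body ellipse (in real CT the spinal canal's bone is what anchors
registration near the cord), and a tumor blob in the right lung. Each next
slice is the previous one warped by a fresh smooth random TPS field on a
jittered 5×5 grid — rescaled exactly to a 4 px sup-norm bound by linearity
of the TPS in its targets — plus independent Gaussian noise (sd 0.01 on a
[0, 1] intensity scale). Contours are pushed forward through the exact
field; images are pulled back through its fixed-point inverse (5
iterations), so image and truth stay consistent to sub-pixel level.

Defaults (256 px, 21 slices, 4 px max displacement, texture density 8
blobs per 10⁴ px) are the package's reference study conditions: 21 slices
exercise the full ±10-slice recursion from a middle seed at a size where
the suite runs in minutes, and at 512 px the same texture defaults yield
well over 30 detectable keypoints per slice, matching the control-point
count the method needs. The deformation magnitude (≤ 4 px between
neighbors) corresponds to thin-slice CT of a quietly breathing patient.

What passing on the phantom does **not** show: robustness to the texture
statistics of real parenchyma (the phantom's blobs are cleaner and more
repeatable than real vasculature), to out-of-plane motion (structures
appearing/disappearing between slices), to pathology that changes topology,
or to CT artifacts. Clinical use would require validation on real scans;
the phantom validates the machinery, not the clinic.

## Problem sizes used by the test suite

Unit tests run on 64–128 px frames; the end-to-end tests use the reference
conditions (256 px, 21 slices) for both the deformed-recovery and
identity-stack checks, and a 128 px, 5-slice stack for byte-level
determinism. These sizes were chosen so the whole suite completes in a few
minutes while still exercising the full recursion depth.

## Known limitations

* Purely 2D: no use of 3D context, no respiratory-phase modeling.
* The TPS is global per slice pair; strongly localized deformation beyond
  the control-point density is smoothed over.
* Small structures (a cord-sized disk of radius < 5 px) lose Jaccard
  quickly under even sub-pixel drift; Hausdorff numbers are the more
  informative metric at that scale.
* DICOM series input is not supported; convert to NIfTI or image
  directories first. RTSTRUCT export is out of scope.
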