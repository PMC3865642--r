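# contourprop

Semi-automatic structure delineation for volumetric grayscale image stacks
(lung CT being the motivating case): a physician delineates **one** slice,
and `contourprop` propagates that contour through the rest of the stack by
feature-based deformable registration, refining each propagated contour
with a band-constrained active contour. It is aimed at radiotherapy
treatment-planning workflows, where slice-by-slice manual delineation of
the tumor and organs at risk (lungs, spinal cord) is the bottleneck and
fully automatic methods fail in low-contrast regions such as the hilus
pulmonis.

## Method

Each step registers the already-delineated slice (*template*) to its
neighbor (*target*):

1. **Detect** scale-invariant keypoints on both slices — maxima of the
   box-filter Hessian determinant `Dxx·Dyy − (0.9·Dxy)²` over a 3-octave
   integral-image pyramid, with sub-pixel refinement and Haar-wavelet
   orientation assignment.
2. **Describe and match** with 64-dimensional GDLOH descriptors (16
   subregions × 4 Haar-response sums over an oriented 20σ window). For
   descriptors *P*, *Q* the matching distance is

   D(P,Q) = (Σ Pᵢ² + Σ Qᵢ²) · Σ (Pᵢ − Qᵢ)² ⁄ (2 Σ PᵢQᵢ),

   searched within a ±5 px spatial gate and filtered to mutual nearest
   neighbors.
3. **Warp** with a thin-plate spline fitted to the matched pairs:
   f(p) = a₁ + aᵤx + aᵥy + Σ wᵢ U(|Pᵢ − p|), U(r) = r² log r², solved via
   the bordered system L(W | a)ᵀ = (V | 0)ᵀ (exact interpolation at λ = 0).
   The contour is pushed through the fitted map; a dense displacement
   vector field is available via `tps_to_dvf()`.
4. **Refine** with a greedy snake minimizing
   α·E_cont + β·E_curv + γ·E_image (defaults 0.15 / 0.2 / 0.85), with every
   vertex hard-constrained to a band (default 5 px at 512-px width) around
   the propagated contour.

Steps recurse outward from the seed slice in both directions (20 slices
each way at most), each step starting from the previous refined contour.
Agreement against reference contours is scored by Jaccard similarity and
maximum / mean Hausdorff distance. A synthetic lung-CT-like phantom
generator with exact ground truth makes the whole pipeline testable without
clinical data.

## Worked example

```r
library(contourprop)

# synthetic 21-slice stack with known truth (256 px, <= 4 px/step deformation)
stack <- generate_phantom(phantom_spec(seed = 42))
#> <phantom_stack> 21 slices of 256 x 256, structures: lung_L, lung_R, cord, tumor

# the "manually delineated" seed: ground-truth contours of the middle slice
seeds <- Filter(function(ct) ct$slice_index == 10, stack$truth)
seeds[[1]]
#> <contour> 'lung_L' on slice 10, 64 vertices, area 10100 px^2

# propagate bidirectionally, then score against ground truth
result <- propagate_volume(stack$volume, seeds)
#> <propagation_result> seed slice 10, contours on 21 slices (0..20)
report <- evaluate_contours(result$contours, stack$truth, c(256, 256))
report
#> <metrics_report> 84 (slice, structure) pairs
#>  structure  n   js_mean      js_sd hd_max_mean hd_max_sd hd_mean_mean
#>       cord 21 0.8092591 0.08056701   2.3527558 1.2503085    0.8546584
#>     lung_L 21 0.9773929 0.01153696   2.5438685 1.1870330    0.6510764
#>     lung_R 21 0.9700322 0.01209749   4.4429667 1.9450582    0.7746780
#>      tumor 21 0.9393198 0.02783091   0.9796145 0.4699592    0.4342873
```

Reading the numbers: `js_mean` is the average intersection-over-union
between propagated and true regions across all 21 slices (1 = perfect);
the lungs stay above 0.97 ten slices from the seed, the small tumor at
0.94, and the cord — a disk of only ~9 px radius, where a single pixel of
drift costs several points of overlap — at 0.81. `hd_max_mean` / 
`hd_mean_mean` are the average maximum and average mean contour-to-contour
distances in pixels: propagated contours stay within a few pixels of truth
everywhere, and well under one pixel on average for the compact
structures.

Per-slice contour JSONs and a diagnostics CSV (keypoint and match counts,
TPS residuals per step) can be written with `save_propagation()`. A thin
CLI wraps the same functions:

```sh
exec/contourprop phantom --size 256 --slices 21 --max-disp 4 --seed 42 --out stack/
exec/contourprop propagate --volume stack/volume.nii.gz \
    --seed-contour stack/truth_s010_lung_L.json --out out/
exec/contourprop eval --pred out/ --truth stack/ --shape 256x256 --out report.csv
```

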