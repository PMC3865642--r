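Package: contourprop
Title: Feature-Based Contour Propagation for Volumetric Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates a single manually delineated planar contour through a
    volumetric grayscale image stack by feature-based deformable registration.
    Scale-invariant keypoints are detected on adjacent slices with a box-filter
    Hessian (SURF-style) detector, described with a 64-dimensional
    gradient-distance-location-orientation histogram (GDLOH), and matched under
    a spatial gate with a correlation-aware descriptor distance. Matched point
    pairs drive a thin-plate-spline warp that carries the contour to the next
    slice, where a band-constrained greedy active contour refines it against
    image gradients. Includes Jaccard and Hausdorff agreement metrics, a
    synthetic lung-CT-like phantom generator with known ground truth, and
    readers and writers for NIfTI volumes, slice-image directories, and a
    plain-JSON contour format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
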