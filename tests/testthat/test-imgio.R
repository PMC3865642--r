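test_that("volume construction validates shapes and thickness", {
  s <- matrix(runif(64 * 64), 64)
  v <- volume(list(s, s, s), slice_thickness = 2.5)
  expect_s3_class(v, "volume")
  expect_equal(length(v$slices), 3L)
  expect_equal(v$slices[[3]]$index, 2L)
  expect_error(volume(list(s, matrix(0.5, 32, 32))), "inconsistent slice shapes")
  expect_error(volume(list(s), slice_thickness = 0), "thickness")
  expect_error(image_slice(matrix(1, 8, 8)), "at least 16 x 16")
  expect_error(image_slice(matrix(c(1, NA), 16, 16)), "non-finite")
})

test_that("NIfTI volume round-trip is bit-identical with spacing metadata", {
  set.seed(1)
  v <- volume(lapply(1:4, function(i) matrix(runif(64 * 48), 48, 64)),
              slice_thickness = 2.5, pixel_spacing = 0.97)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  save_volume(v, path, "nifti")
  v2 <- load_volume(path, "nifti")
  expect_identical(v2$slices[[2]]$pixels, v$slices[[2]]$pixels)
  expect_equal(v2$slice_thickness, 2.5, tolerance = 1e-6)
  expect_equal(v2$pixel_spacing, 0.97, tolerance = 1e-6)
})

test_that("slice directories load ordered and reject DICOM", {
  dir <- withr::local_tempdir()
  set.seed(2)
  v <- volume(lapply(1:5, function(i) matrix(runif(64 * 64), 64)))
  save_volume(v, dir, "slice_dir")
  v2 <- load_volume(dir, "slice_dir")
  expect_equal(length(v2$slices), 5L)
  expect_equal(dim(v2$slices[[1]]$pixels), c(64L, 64L))
  # PNG quantizes but preserves ordering of intensities
  expect_gt(cor(as.vector(v2$slices[[3]]$pixels),
                as.vector(v$slices[[3]]$pixels)), 0.999)
  expect_error(load_volume(dir, "dicom_dir"), "not supported")
  expect_error(load_volume(tempfile(), "nifti"), "no such file")
})

test_that("contour JSON round-trip preserves vertices exactly", {
  set.seed(3)
  ct <- contour(matrix(runif(200, 0, 511), 100), slice_index = 7L,
                label = "lung_L")
  path <- withr::local_tempfile(fileext = ".json")
  save_contour(ct, path)
  ct2 <- load_contour(path)
  expect_identical(ct2$vertices, ct$vertices)
  expect_identical(ct2$slice_index, 7L)
  expect_identical(ct2$label, "lung_L")
})

test_that("contours reject too few vertices and out-of-bounds attachment", {
  expect_error(contour(matrix(c(0, 0, 1, 1), 2)), "n >= 3")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "x", slice_index = 0,
                            vertices = matrix(c(0, 0, 1, 1), 2)), path)
  expect_error(load_contour(path), "n >= 3")
  ct <- contour(rbind(c(10, 10), c(90, 10), c(50, 90)))
  expect_error(validate_contour_bounds(ct, c(64, 64)), "outside image bounds")
  expect_error(rasterize_contour(ct, c(64, 64)), "outside image bounds")
})

test_that("rasterization matches brute-force point-in-polygon", {
  sq <- contour(rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20)))
  expect_equal(sum(rasterize_contour(sq, c(64, 64))), 100L)
  tri <- contour(rbind(c(0, 0), c(4, 0), c(0, 4)))
  m <- rasterize_contour(tri, c(16, 16))
  expect_identical(m, oracle_rasterize(tri$vertices, c(16, 16)))
  set.seed(4)
  for (i in 1:50) {
    v <- random_polygon(sample(3:9, 1), runif(1, 8, 24), runif(1, 8, 24),
                        1.5, 7.5)
    ct <- contour(v)
    expect_identical(rasterize_contour(ct, c(32, 32)),
                     oracle_rasterize(v, c(32, 32)))
  }
})

test_that("rasterized area of a convex lattice polygon is near shoelace area", {
  set.seed(5)
  for (i in 1:10) {
    pts <- matrix(sample(4:28, 16, replace = TRUE), ncol = 2)
    hull <- pts[chull(pts), , drop = FALSE]
    if (nrow(hull) < 3) next
    ct <- contour(hull)
    area <- abs(polygon_area(hull))
    per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ])^2)))
    expect_lt(abs(sum(rasterize_contour(ct, c(32, 32))) - area), per + 1e-9)
  }
})

test_that("degenerate polygons rasterize empty with a warning", {
  ct <- contour(rbind(c(5, 5), c(5, 5), c(5, 5)))
  expect_warning(m <- rasterize_contour(ct, c(16, 16)), "degenerate")
  expect_equal(sum(m), 0L)
})
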