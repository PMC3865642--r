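test_that("config invariants are enforced", {
  expect_error(propagation_config(max_distance = 0), "max_distance")
  expect_error(propagation_config(min_matches = 2), "min_matches")
})

test_that("a step between identical slices returns an almost unchanged contour", {
  ts <- textured_slice()
  ct <- circle_contour(77, 123, 20, 48, 0L, "lung_L")  # inside the left lung
  st <- propagate_step(ts$img, ts$img, ct, propagation_config())
  m_in <- rasterize_contour(ct, c(256, 256))
  expect_gte(jaccard(rasterize_contour(st$refined, c(256, 256)), m_in), 0.98)
  expect_lt(st$diagnostics$tps_residual, 1e-6)
  expect_equal(st$refined$slice_index, 1L)
})

test_that("a step recovers a pure translation of the whole slice", {
  ts <- textured_slice()
  img2 <- matrix(0.5, 256, 256)
  img2[4:256, 3:256] <- ts$img[1:253, 1:254]   # (x + 2, y + 3)
  ct <- circle_contour(77, 123, 20, 48, 0L, "lung_L")
  st <- propagate_step(ts$img, img2, ct, propagation_config())
  v <- st$initial$vertices
  rms <- sqrt(mean((sqrt((v[, 1] - 79)^2 + (v[, 2] - 126)^2) - 20)^2))
  expect_lt(rms, 1)
})

test_that("a featureless target fails the step with a diagnostic condition", {
  ts <- textured_slice()
  ct <- circle_contour(77, 123, 20, 48, 0L, "lung_L")
  err <- tryCatch(
    propagate_step(ts$img, matrix(0.5, 256, 256), ct, propagation_config()),
    contourprop_step_failure = function(e) e)
  expect_s3_class(err, "contourprop_step_failure")
  expect_equal(err$n_matches, 0L)
  expect_match(conditionMessage(err), "min_matches")
})

test_that("a single-slice volume returns only the seed contour", {
  ph <- small_phantom()
  v1 <- volume(list(ph$volume$slices[[1]]$pixels))
  seed <- seed_contours(ph, 0L)[[1]]
  pr <- propagate_volume(v1, seed, propagation_config(min_matches = 10))
  expect_length(pr$contours, 1L)
  expect_identical(pr$contours[[1]], seed)
})

test_that("bad seed indices and thick slices are flagged", {
  ph <- small_phantom()
  seed <- seed_contours(ph, 0L)[[1]]
  expect_error(propagate_volume(ph$volume,
                                { s <- seed; s$slice_index <- 99L; s }),
               "outside volume")
  thick <- volume(lapply(ph$volume$slices, `[[`, "pixels"),
                  slice_thickness = 4)
  expect_warning(
    propagate_volume(thick, seed_contours(ph, 0L),
                     propagation_config(max_distance = 1, min_matches = 10)),
    "3 mm")
})

test_that("propagation covers the stack contiguously and keeps the seed intact", {
  ph <- small_phantom()
  seeds <- seed_contours(ph, 2L)
  pr <- propagate_volume(ph$volume, seeds,
                         propagation_config(min_matches = 10))
  slices <- sort(unique(vapply(pr$contours, function(ct) ct$slice_index, 0L)))
  expect_identical(slices, 0:4)
  at_seed <- Filter(function(ct) ct$slice_index == 2L, pr$contours)
  expect_identical(at_seed, seeds)
  # every structure present on every slice
  keys <- vapply(pr$contours, function(ct)
    paste0(ct$slice_index, "|", ct$label), "")
  expect_equal(length(unique(keys)), 5L * length(seeds))
  expect_true(all(!pr$diagnostics$retried))
  # diagnostics cover each step once
  expect_equal(nrow(pr$diagnostics), 4L)
})

test_that("propagated contours track the deformed truth on the small phantom", {
  ph <- small_phantom()
  seeds <- seed_contours(ph, 2L)
  pr <- propagate_volume(ph$volume, seeds,
                         propagation_config(min_matches = 10))
  rep <- evaluate_contours(pr$contours, ph$truth, c(128, 128))
  expect_gte(mean(rep$per_key$js), 0.85)
  # no structure is ever lost, even the 4-px-radius cord on this small frame
  expect_true(all(rep$per_key$js > 0.5))
})

test_that("results serialize to per-slice contour JSONs plus diagnostics", {
  ph <- small_phantom()
  pr <- propagate_volume(ph$volume, seed_contours(ph, 2L),
                         propagation_config(min_matches = 10))
  dir <- withr::local_tempdir()
  save_propagation(pr, dir)
  files <- list.files(dir, pattern = "^contour_.*json$")
  expect_equal(length(files), length(pr$contours))
  expect_true(file.exists(file.path(dir, "diagnostics.csv")))
  ct <- load_contour(file.path(dir, files[1]))
  expect_s3_class(ct, "contour")
})
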