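# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small deformed phantom used by several propagation tests
small_phantom <- function() cached("small_phantom", function()
  generate_phantom(phantom_spec(size = 128L, n_slices = 5L, max_disp = 3,
                                seed = 3L)))

# a single textured 256 px slice plus its keypoints and descriptors
textured_slice <- function() cached("textured_slice", function() {
  ph <- generate_phantom(phantom_spec(size = 256L, n_slices = 1L, seed = 11L))
  img <- ph$volume$slices[[1]]$pixels
  kps <- detect_keypoints(img)
  list(img = img, kps = kps, desc = compute_descriptors(img, kps),
       truth = ph$truth)
})

seed_contours <- function(ph, slice)
  Filter(function(ct) ct$slice_index == slice, ph$truth)

# synthetic disk image with a sharp edge at radius r
disk_image <- function(size, cx, cy, r, lo = 0.2, hi = 0.8) {
  xs <- seq_len(size) - 0.5
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size)
  ifelse(sqrt((X - cx)^2 + (Y - cy)^2) <= r, lo, hi)
}
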