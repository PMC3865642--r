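test_that("detector finds nothing on a constant image and rejects tiny ones", {
  expect_equal(nrow(detect_keypoints(matrix(0.5, 64, 64))), 0L)
  expect_error(detect_keypoints(matrix(runif(24 * 24), 24)), "too small")
})

test_that("a Gaussian blob is detected at its center", {
  xs <- seq_len(64) - 0.5
  X <- matrix(xs, 64, 64, byrow = TRUE); Y <- matrix(xs, 64, 64)
  blob <- exp(-((X - 32)^2 + (Y - 32)^2) / (2 * 4^2))
  kps <- detect_keypoints(blob, hessian_threshold = 1e-5)
  expect_gte(nrow(kps), 1L)
  d <- sqrt((kps$x - 32)^2 + (kps$y - 32)^2)
  expect_lt(min(d), 2)
  # strongest response is the blob center
  expect_lt(d[1], 2)
})

test_that("keypoint locations are equivariant under integer translation", {
  ts <- textured_slice()
  img <- ts$img[1:128, 1:128]
  kps <- detect_keypoints(img)
  for (sh in list(c(2L, 5L), c(8L, 3L))) {
    img2 <- matrix(median(img), 128, 128)
    img2[(1 + sh[2]):128, (1 + sh[1]):128] <-
      img[1:(128 - sh[2]), 1:(128 - sh[1])]
    kps2 <- detect_keypoints(img2)
    # interior keypoints must reappear shifted by the same vector (+/- 1 px)
    interior <- kps[kps$x > 20 & kps$x < 100 & kps$y > 20 & kps$y < 100, ]
    hits <- vapply(seq_len(nrow(interior)), function(i) {
      d <- sqrt((kps2$x - interior$x[i] - sh[1])^2 +
                (kps2$y - interior$y[i] - sh[2])^2)
      min(d) <= 1
    }, logical(1))
    expect_gt(mean(hits), 0.9)
  }
})

test_that("descriptors are 64-dim unit vectors, degenerate on flat patches", {
  ts <- textured_slice()
  expect_equal(ncol(ts$desc), 64L)
  nrm <- sqrt(rowSums(ts$desc^2))
  expect_true(all(abs(nrm - 1) < 1e-9 | nrm == 0))
  flat <- matrix(0.5, 64, 64)
  kp <- data.frame(x = 32, y = 32, sigma = 2, theta = 0, response = 1)
  d <- compute_gdloh(flat, kp)
  expect_length(d, 64L)
  expect_true(all(d == 0))
  expect_true(isTRUE(attr(d, "degenerate")))
})

test_that("descriptor is stable under 90-degree patch rotation", {
  set.seed(4)
  img <- matrix(runif(96 * 96), 96)
  img <- 0.5 * img + 0.5 * disk_image(96, 40, 52, 17)
  rot <- t(img)[, 96:1]    # rotate: (x, y) -> (y, 95 - x)
  kp <- data.frame(x = 48, y = 48, sigma = 3, theta = 0.7, response = 1)
  kp_rot <- data.frame(x = 48, y = 48, sigma = 3, theta = 0.7 + pi / 2,
                       response = 1)
  d0 <- compute_gdloh(img, kp)
  d1 <- compute_gdloh(rot, kp_rot)
  expect_lt(sqrt(sum((d0 - d1)^2)), 0.1)
})

test_that("concentric descriptor layout also yields 64-dim unit vectors", {
  ts <- textured_slice()
  kp <- ts$kps[1:5, ]
  d <- compute_descriptors(ts$img, kp, layout = "concentric")
  expect_equal(dim(d), c(5L, 64L))
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
})

test_that("descriptor distance matches the literal formula and is symmetric", {
  expect_equal(descriptor_distance(c(1, 1), c(2, 2)), 2.5)
  expect_equal(descriptor_distance(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_true(is.na(descriptor_distance(c(1, 0), c(0, 1))))
  set.seed(7)
  for (i in 1:100) {
    p <- runif(64); q <- runif(64)
    d <- descriptor_distance(p, q)
    expect_equal(d, oracle_descriptor_distance(p, q), tolerance = 1e-10)
    expect_identical(d, descriptor_distance(q, p))
  }
})

test_that("matching a slice against itself is the identity with zero distance", {
  ts <- textured_slice()
  mm <- match_features(ts$kps, ts$desc, ts$kps, ts$desc)
  expect_equal(nrow(mm), nrow(ts$kps))
  expect_identical(mm$src_idx, mm$dst_idx)
  expect_true(all(mm$distance < 1e-10))
})

test_that("matching respects the gate, is one-to-one, and sorted by distance", {
  ts <- textured_slice()
  kps <- ts$kps; desc <- ts$desc
  far <- kps; far$x <- far$x + 300; far$y <- far$y + 300
  expect_equal(nrow(match_features(kps, desc, far, desc)), 0L)
  img2 <- matrix(0.5, 256, 256)
  img2[4:256, 3:256] <- ts$img[1:253, 1:254]
  kps2 <- detect_keypoints(img2)
  desc2 <- compute_descriptors(img2, kps2)
  mm <- match_features(kps, desc, kps2, desc2)
  expect_false(any(duplicated(mm$dst_idx)))
  expect_false(any(duplicated(mm$src_idx)))
  expect_true(all(abs(mm$src_x - mm$dst_x) <= 5 &
                  abs(mm$src_y - mm$dst_y) <= 5))
  expect_true(!is.unsorted(mm$distance))
  mm1 <- match_features(kps, desc, kps2, desc2, mutual = FALSE)
  expect_false(any(duplicated(mm1$dst_idx)))
  expect_gte(nrow(mm1), nrow(mm))
})

test_that("matching recovers a known integer translation", {
  ts <- textured_slice()
  img2 <- matrix(0.5, 256, 256)
  img2[4:256, 3:256] <- ts$img[1:253, 1:254]   # shift by (x + 2, y + 3)
  kps2 <- detect_keypoints(img2)
  desc2 <- compute_descriptors(img2, kps2)
  mm <- match_features(ts$kps, ts$desc, kps2, desc2)
  expect_gte(nrow(mm), 30L)
  good <- abs(mm$dst_x - mm$src_x - 2) <= 1 & abs(mm$dst_y - mm$src_y - 3) <= 1
  expect_gte(mean(good), 0.9)
})
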