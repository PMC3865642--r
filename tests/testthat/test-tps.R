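dist_to_true_circle <- function(v, cx, cy, r)
  abs(sqrt((v[, 1] - cx)^2 + (v[, 2] - cy)^2) - r)

test_that("the radial basis takes its defining values", {
  expect_equal(tps_basis(0), 0)
  expect_equal(tps_basis(1), 0)
  expect_equal(tps_basis(sqrt(exp(1))), exp(1))
  expect_equal(tps_basis(c(0, 1, 2)), c(0, 0, 4 * log(4)))
  expect_error(tps_basis(-1), "r >= 0")
})

test_that("identity and translation are reproduced with zero bending", {
  set.seed(10)
  src <- matrix(runif(12, 0, 100), 6)
  m_id <- fit_tps(src, src)
  expect_lt(max(abs(c(m_id$weights_x, m_id$weights_y))), 1e-8)
  expect_equal(unname(m_id$affine_x), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(unname(m_id$affine_y), c(0, 0, 1), tolerance = 1e-8)
  m_tr <- fit_tps(src, src + rep(c(3, -2), each = 6))
  expect_lt(max(abs(c(m_tr$weights_x, m_tr$weights_y))), 1e-8)
  pts <- matrix(runif(40, 0, 100), 20)
  expect_equal(apply_tps(m_tr, pts), pts + rep(c(3, -2), each = 20),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("general affine maps are reproduced exactly", {
  set.seed(11)
  A <- matrix(c(1.2, -0.3, 0.25, 0.9), 2)
  b <- c(4, -7)
  src <- matrix(runif(20, 0, 100), 10)
  dst <- t(A %*% t(src) + b)
  m <- fit_tps(src, dst)
  expect_lt(max(abs(c(m$weights_x, m$weights_y))), 1e-6)
  pts <- matrix(runif(200, 0, 100), 100)
  expect_equal(apply_tps(m, pts), t(A %*% t(pts) + b),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the exact fit interpolates its control points", {
  set.seed(12)
  for (rep in 1:5) {
    src <- matrix(runif(20, 0, 100), 10)
    dst <- src + matrix(runif(20, -8, 8), 10)
    m <- fit_tps(src, dst)
    expect_lt(max(abs(apply_tps(m, src) - dst)), 1e-6)
    # side conditions of the bordered system
    expect_lt(abs(sum(m$weights_x)), 1e-8 * sum(abs(m$weights_x)) + 1e-8)
    expect_lt(abs(sum(m$weights_x * src[, 1])),
              1e-8 * sum(abs(m$weights_x)) * 100 + 1e-6)
    expect_lt(abs(sum(m$weights_y * src[, 2])),
              1e-8 * sum(abs(m$weights_y)) * 100 + 1e-6)
  }
})

test_that("the bordered solve equals a dense brute-force solve", {
  set.seed(13)
  for (n in c(5, 12, 20)) {
    src <- matrix(runif(2 * n, 0, 50), n)
    dst <- src + matrix(runif(2 * n, -5, 5), n)
    m <- fit_tps(src, dst)
    coef <- oracle_tps_solve(src, dst)
    got <- cbind(c(m$weights_x, m$affine_x), c(m$weights_y, m$affine_y))
    expect_equal(got, coef, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate control-point sets are rejected or merged", {
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(fit_tps(line, line + 1), "collinear")
  expect_error(fit_tps(matrix(1, 2, 2), matrix(1, 2, 2)), "at least 3")
  # exact duplicates collapse to one control point with averaged target
  src <- rbind(c(0, 0), c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  dst <- rbind(c(1, 0), c(3, 0), c(10, 0), c(0, 10), c(10, 10))
  m <- fit_tps(src, dst)
  expect_equal(nrow(m$control_points), 4L)
  expect_equal(unname(apply_tps(m, rbind(c(0, 0)))[1, ]), c(2, 0),
               tolerance = 1e-6)
})

test_that("displacement fields reflect the fitted map", {
  set.seed(14)
  src <- matrix(runif(16, 10, 50), 8)
  m_id <- fit_tps(src, src)
  f <- tps_to_dvf(m_id, c(24, 32))
  expect_equal(dim(f$dx), c(24L, 32L))
  expect_lt(max(abs(c(f$dx, f$dy))), 1e-6)
  m_tr <- fit_tps(src, src + rep(c(3, -2), each = 8))
  f2 <- tps_to_dvf(m_tr, c(24, 32))
  expect_equal(range(f2$dx), c(3, 3), tolerance = 1e-6)
  expect_equal(range(f2$dy), c(-2, -2), tolerance = 1e-6)
  dst <- src + matrix(runif(16, -3, 3), 8)
  m <- fit_tps(src, dst)
  f3 <- tps_to_dvf(m, c(64, 64))
  at <- cbind(round(src[, 2]) + 1, round(src[, 1]) + 1)  # (row, col) of (x, y)
  moved <- apply_tps(m, src) - src
  # field interpolates the control displacements on the integer grid
  expect_lt(max(abs(f3$dx[at] - moved[, 1])), 0.8)
})

test_that("contours propagate through the map with resampling and clamping", {
  set.seed(15)
  src <- matrix(runif(16, 0, 64), 8)
  ct <- circle_contour(32, 32, 10)
  m_id <- fit_tps(src, src)
  out <- propagate_contour(m_id, ct, c(64, 64))
  d <- dist_to_true_circle(out$vertices, 32, 32, 10)
  expect_lt(max(d), 0.05)
  expect_equal(out$slice_index, ct$slice_index + 1L)
  m_tr <- fit_tps(src, src + rep(c(3, -2), each = 8))
  out2 <- propagate_contour(m_tr, ct, c(64, 64))
  expect_lt(max(dist_to_true_circle(out2$vertices, 35, 30, 10)), 0.05)
  # pushing the contour across the border clamps with a warning
  m_far <- fit_tps(src, src + rep(c(30, 0), each = 8))
  expect_warning(out3 <- propagate_contour(m_far, ct, c(64, 64)), "clamped")
  expect_true(all(out3$vertices[, 1] <= 64))
})

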