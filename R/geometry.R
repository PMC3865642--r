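# Shared low-level geometry and image-sampling helpers.

#' Resample a closed polyline to uniform arc-length spacing
#'
#' @param vertices n x 2 matrix of (x, y) vertices of a closed polyline.
#' @param spacing Target spacing in pixels; the vertex count is
#'   `max(3, round(perimeter / spacing))` so the result is exactly uniform.
#' @param n_out Optional explicit vertex count, overriding `spacing`.
#' @return m x 2 matrix of uniformly spaced vertices starting at the first
#'   input vertex.
#' @export
resample_closed <- function(vertices, spacing = 2, n_out = NULL) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(seq_len(n)[-1L], 1L)
  seg <- sqrt((v[j, 1L] - v[, 1L])^2 + (v[j, 2L] - v[, 2L])^2)
  per <- sum(seg)
  if (per <= 0) stop("cannot resample a zero-length polyline", call. = FALSE)
  m <- if (is.null(n_out)) max(3L, as.integer(round(per / spacing))) else
    max(3L, as.integer(n_out))
  s_target <- (seq_len(m) - 1L) * per / m
  cum <- c(0, cumsum(seg))          # arc length at each vertex, closed at per
  idx <- findInterval(s_target, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  t_loc <- (s_target - cum[idx]) / seg[idx]
  t_loc[!is.finite(t_loc)] <- 0
  cbind(v[idx, 1L] + t_loc * (v[j[idx], 1L] - v[idx, 1L]),
        v[idx, 2L] + t_loc * (v[j[idx], 2L] - v[idx, 2L]))
}

# Minimum Euclidean distance from each point to a closed polyline.
# pts: m x 2, poly: n x 2 (closed implicitly). Returns length-m vector.
dist_to_closed_polyline <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  n <- nrow(poly)
  j <- c(seq_len(n)[-1L], 1L)
  ax <- poly[, 1L]; ay <- poly[, 2L]
  bx <- poly[j, 1L]; by <- poly[j, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1
  # t = clamp(((p - a) . (b - a)) / |b - a|^2, 0, 1), outer over points x segs
  px <- pts[, 1L]; py <- pts[, 2L]
  tmat <- (outer(px, dx) + outer(py, dy) -
             rep(ax * dx + ay * dy, each = length(px))) /
    rep(len2, each = length(px))
  tmat[tmat < 0] <- 0; tmat[tmat > 1] <- 1
  cx <- rep(ax, each = length(px)) + tmat * rep(dx, each = length(px))
  cy <- rep(ay, each = length(px)) + tmat * rep(dy, each = length(px))
  d2 <- (cx - px)^2 + (cy - py)^2
  dim(d2) <- c(length(px), n)
  sqrt(apply(d2, 1L, min))
}

# Bilinear interpolation of an image at continuous (x, y) package coordinates
# (pixel centers at c + 0.5, r + 0.5). Out-of-range positions are clamped to
# the border (constant extension).
bilinear_sample <- function(img, x, y) {
  x <- as.vector(x); y <- as.vector(y)
  nr <- nrow(img); nc <- ncol(img)
  cx <- pmin(pmax(x - 0.5, 0), nc - 1)   # continuous col index of left center
  cy <- pmin(pmax(y - 0.5, 0), nr - 1)
  c0 <- pmin(floor(cx), nc - 2); c0[c0 < 0] <- 0
  r0 <- pmin(floor(cy), nr - 2); r0[r0 < 0] <- 0
  fx <- cx - c0; fy <- cy - r0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

# Summed-area table with a zero top row/left column:
# ii[r + 1, c + 1] = sum(img[1:r, 1:c]).
integral_image <- function(img) {
  ii <- matrix(0, nrow(img) + 1L, ncol(img) + 1L)
  cs <- apply(img, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, 1L)
  ii[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  ii
}

# Sum of img over rows r0..r1, cols c0..c1 (1-based, inclusive), vectorized
# over parallel index vectors. Indices must be within the image.
rect_sum <- function(ii, r0, r1, c0, c1) {
  ii[cbind(r1 + 1L, c1 + 1L)] - ii[cbind(r0, c1 + 1L)] -
    ii[cbind(r1 + 1L, c0)] + ii[cbind(r0, c0)]
}

# Reflect-pad an image by `pad` pixels on every side.
reflect_pad <- function(img, pad) {
  nr <- nrow(img); nc <- ncol(img)
  ridx <- reflect_index(seq_len(nr + 2L * pad) - pad, nr)
  cidx <- reflect_index(seq_len(nc + 2L * pad) - pad, nc)
  img[ridx, cidx, drop = FALSE]
}

# Reflect 1-based indices into 1..n (mirror about the half-sample border).
reflect_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  i[i >= n] <- 2L * n - 1L - i[i >= n]
  i + 1L
}

# Sobel gradient magnitude of a Gaussian-smoothed image.
gradient_magnitude <- function(img, smooth_sigma = 1) {
  if (smooth_sigma > 0) img <- gaussian_blur(img, smooth_sigma)
  nr <- nrow(img); nc <- ncol(img)
  p <- reflect_pad(img, 1L)
  # shifted views of the padded image; center pixel at offset (0, 0)
  sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc),
                           drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Separable Gaussian blur with reflected borders.
gaussian_blur <- function(img, sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- reflect_pad(img, half)
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc + 2L * half)
  for (i in seq_along(k))                       # vertical pass
    tmp <- tmp + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))                       # horizontal pass
    out <- out + k[i] * tmp[, i:(i + nc - 1L), drop = FALSE]
  out
}
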