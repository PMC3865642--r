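# Independent brute-force oracles, deliberately written with naive loops and
# none of the package's internals.

# even-odd point-in-polygon by ray casting (crossings strictly to the right)
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1]))
    for (c in seq_len(shape[2]))
      mask[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5,
                                            vertices[, 1], vertices[, 2])
  mask
}

# literal term-by-term evaluation of the correlation-aware distance
oracle_descriptor_distance <- function(p, q) {
  sp2 <- 0; sq2 <- 0; spq <- 0; sdiff <- 0
  for (i in seq_along(p)) {
    sp2 <- sp2 + p[i]^2
    sq2 <- sq2 + q[i]^2
    spq <- spq + p[i] * q[i]
    sdiff <- sdiff + (p[i] - q[i])^2
  }
  (sp2 + sq2) * sdiff / (2 * spq)
}

# dense solve of the full bordered TPS system by explicit matrix inversion
oracle_tps_solve <- function(src, dst) {
  n <- nrow(src)
  U <- function(r) ifelse(r > 0, r^2 * log(r^2), 0)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- U(sqrt(sum((src[i, ] - src[j, ])^2)))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Y <- rbind(dst, matrix(0, 3, 2))
  solve(L) %*% Y
}

oracle_jaccard <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i] || b[i]) uni <- uni + 1
  }
  inter / uni
}

# all-pairs directed Hausdorff on raw point sets
oracle_hausdorff <- function(pa, pb) {
  d <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa)))
    for (j in seq_len(nrow(pb)))
      d[i, j] <- sqrt(sum((pa[i, ] - pb[j, ])^2))
  dab <- apply(d, 1, min)
  dba <- apply(d, 2, min)
  c(hd_max = max(max(dab), max(dba)), hd_mean = (mean(dab) + mean(dba)) / 2)
}

# simple random star-shaped polygon (non-self-intersecting by construction)
random_polygon <- function(n, cx, cy, rmin, rmax) {
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, rmin, rmax)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

circle_contour <- function(cx, cy, r, n = 64, slice_index = 0L,
                           label = "structure") {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(cx + r * cos(t), cy + r * sin(t)), slice_index, label)
}
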