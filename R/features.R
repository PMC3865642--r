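# Scale-invariant keypoint detection (box-filter Hessian pyramid on integral
# images), 64-dimensional GDLOH description, and spatially gated matching.

#' Detect scale-invariant keypoints on a slice
#'
#' Keypoints are local maxima of a box-filter approximation of the Hessian
#' determinant across a scale pyramid (integral-image SURF-style filters,
#' filter sizes 9, 15, 21, ... grouped in octaves), refined to sub-pixel and
#' sub-scale position by a 3D quadratic fit, and assigned an orientation from
#' the dominant Haar-wavelet response direction in a circular neighborhood of
#' radius 6 sigma.
#'
#' @param slice An [image_slice()] or a numeric matrix (at least 32 x 32).
#' @param hessian_threshold Minimum normalized Hessian-determinant response.
#'   The default is calibrated so that a textured 512 x 512 phantom slice
#'   yields at least 30 keypoints.
#' @param n_octaves Number of octaves in the filter pyramid (default 3).
#' @param max_keypoints Optional cap; strongest responses kept.
#' @return A data.frame with columns `x`, `y` (pixel coordinates, 0-based,
#'   pixel centers at half-integers), `sigma` (scale in px), `theta`
#'   (orientation, radians in `[0, 2*pi)`), and `response`, sorted by
#'   descending response.
#' @export
detect_keypoints <- function(slice, hessian_threshold = 2e-4, n_octaves = 3L,
                             max_keypoints = Inf) {
  img <- slice_pixels(slice)
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 32L || nc < 32L)
    stop("image too small for the filter pyramid (need >= 32 x 32)",
         call. = FALSE)
  ii <- integral_image(img)

  octaves <- lapply(seq_len(n_octaves), function(o)
    (3L * 2L^o + 3L) + (0:3) * 6L * 2L^(o - 1L))
  sizes <- sort(unique(unlist(octaves)))
  sizes <- sizes[sizes <= min(nr, nc) - 2L]
  maps <- lapply(sizes, function(L) hessian_det_map(ii, nr, nc, L))
  names(maps) <- as.character(sizes)

  out <- list()
  for (o in seq_len(n_octaves)) {
    lv <- octaves[[o]]
    if (!all(as.character(lv) %in% names(maps))) next
    for (j in 2:3) {
      m <- maps[[as.character(lv[j])]]
      lo <- maps[[as.character(lv[j - 1L])]]
      hi <- maps[[as.character(lv[j + 1L])]]
      cand <- which(m > hessian_threshold &
                    m == neighborhood_max(m) &
                    m >= neighborhood_max(lo) &
                    m > neighborhood_max(hi), arr.ind = TRUE)
      if (!nrow(cand)) next
      sig <- 1.2 * lv[j] / 9
      sig_lo <- 1.2 * lv[j - 1L] / 9
      sig_hi <- 1.2 * lv[j + 1L] / 9
      ref <- refine_extrema(m, lo, hi, cand, sig, sig_lo, sig_hi)
      out[[length(out) + 1L]] <- ref
    }
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), sigma = numeric(),
                      theta = numeric(), response = numeric()))
  kps <- do.call(rbind, out)
  kps <- kps[kps$x >= 0 & kps$x <= nc & kps$y >= 0 & kps$y <= nr, , drop = FALSE]
  kps <- kps[order(-kps$response), , drop = FALSE]
  if (is.finite(max_keypoints) && nrow(kps) > max_keypoints)
    kps <- kps[seq_len(max_keypoints), , drop = FALSE]
  rownames(kps) <- NULL
  kps$theta <- assign_orientations(img, kps)
  kps[, c("x", "y", "sigma", "theta", "response")]
}

slice_pixels <- function(slice) {
  if (inherits(slice, "image_slice")) slice$pixels else as.matrix(slice)
}

# Normalized box-filter Hessian determinant for filter size L; -Inf where the
# full L x L window does not fit.
hessian_det_map <- function(ii, nr, nc, L) {
  half <- (L - 1L) %/% 2L
  l <- L %/% 3L
  rv <- (half + 1L):(nr - half)
  cv <- (half + 1L):(nc - half)
  box <- function(dr0, dr1, dc0, dc1)
    ii[rv + dr1 + 1L, cv + dc1 + 1L, drop = FALSE] -
    ii[rv + dr0, cv + dc1 + 1L, drop = FALSE] -
    ii[rv + dr1 + 1L, cv + dc0, drop = FALSE] +
    ii[rv + dr0, cv + dc0, drop = FALSE]
  w <- l - 1L
  dyy <- box(-half, -half + l - 1L, -w, w) -
    2 * box(-half + l, -half + 2L * l - 1L, -w, w) +
    box(-half + 2L * l, half, -w, w)
  dxx <- box(-w, w, -half, -half + l - 1L) -
    2 * box(-w, w, -half + l, -half + 2L * l - 1L) +
    box(-w, w, -half + 2L * l, half)
  dxy <- box(-l, -1L, -l, -1L) + box(1L, l, 1L, l) -
    box(-l, -1L, 1L, l) - box(1L, l, -l, -1L)
  inv <- 1 / (L * L)
  det <- (dxx * inv) * (dyy * inv) - (0.9 * dxy * inv)^2
  out <- matrix(-Inf, nr, nc)
  out[rv, cv] <- det
  out
}

# 3x3 neighborhood maximum (including the center), -Inf padded borders.
neighborhood_max <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- pmax(out, p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  out
}

# Quadratic sub-pixel / sub-scale refinement of detected extrema.
refine_extrema <- function(m, lo, hi, cand, sig, sig_lo, sig_hi) {
  n <- nrow(cand)
  xs <- ys <- ss <- rs <- numeric(n)
  for (k in seq_len(n)) {
    r <- cand[k, 1L]; c <- cand[k, 2L]
    v <- m[r, c]
    off <- c(0, 0, 0)
    if (r > 1L && r < nrow(m) && c > 1L && c < ncol(m) &&
        all(is.finite(c(m[(r - 1L):(r + 1L), (c - 1L):(c + 1L)],
                        lo[r, c], hi[r, c])))) {
      g <- c((m[r, c + 1L] - m[r, c - 1L]) / 2,
             (m[r + 1L, c] - m[r - 1L, c]) / 2,
             (hi[r, c] - lo[r, c]) / 2)
      hxx <- m[r, c + 1L] - 2 * v + m[r, c - 1L]
      hyy <- m[r + 1L, c] - 2 * v + m[r - 1L, c]
      hss <- hi[r, c] - 2 * v + lo[r, c]
      hxy <- (m[r + 1L, c + 1L] - m[r + 1L, c - 1L] -
              m[r - 1L, c + 1L] + m[r - 1L, c - 1L]) / 4
      H <- matrix(c(hxx, hxy, 0, hxy, hyy, 0, 0, 0, hss), 3L, 3L)
      sol <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol)) && max(abs(sol)) <= 1)
        off <- sol
    }
    xs[k] <- (c - 1L) + 0.5 + off[1L]
    ys[k] <- (r - 1L) + 0.5 + off[2L]
    ss[k] <- sig + off[3L] * (sig_hi - sig_lo) / 2
    rs[k] <- v
  }
  data.frame(x = xs, y = ys, sigma = pmax(ss, 0.8), theta = 0, response = rs)
}

# Dominant Haar-response orientation per keypoint (sliding pi/3 window).
assign_orientations <- function(img, kps) {
  if (!nrow(kps)) return(numeric())
  off <- expand.grid(i = -6:6, j = -6:6)
  off <- off[off$i^2 + off$j^2 <= 36, ]
  wts <- exp(-(off$i^2 + off$j^2) / (2 * 2.5^2))
  win <- seq(0, 2 * pi, length.out = 43L)[-43L]
  pad <- as.integer(ceiling(8 * max(kps$sigma))) + 2L
  pimg <- reflect_pad(img, pad)
  pii <- integral_image(pimg)
  theta <- numeric(nrow(kps))
  for (k in seq_len(nrow(kps))) {
    sg <- kps$sigma[k]
    s <- max(1L, as.integer(round(2 * sg)))
    cc <- as.integer(round(kps$x[k] + off$i * sg)) + 1L + pad
    rr <- as.integer(round(kps$y[k] + off$j * sg)) + 1L + pad
    dx <- rect_sum(pii, rr - s, rr + s - 1L, cc, cc + s - 1L) -
          rect_sum(pii, rr - s, rr + s - 1L, cc - s, cc - 1L)
    dy <- rect_sum(pii, rr, rr + s - 1L, cc - s, cc + s - 1L) -
          rect_sum(pii, rr - s, rr - 1L, cc - s, cc + s - 1L)
    dx <- dx * wts; dy <- dy * wts
    ang <- atan2(dy, dx) %% (2 * pi)
    best <- 0; best_len <- -1
    for (a in win) {
      d <- (ang - a) %% (2 * pi)
      inwin <- d < pi / 3                        # window [a, a + pi/3)
      sx <- sum(dx[inwin]); sy <- sum(dy[inwin])
      len <- sx * sx + sy * sy
      if (len > best_len) { best_len <- len; best <- atan2(sy, sx) }
    }
    theta[k] <- best %% (2 * pi)
  }
  theta
}

#' Compute the 64-dimensional GDLOH descriptor of a keypoint
#'
#' A 20-sigma window oriented along the keypoint's `theta` is sampled on a
#' 20 x 20 grid; at every sample the horizontal and vertical Haar-wavelet
#' responses (size 2 sigma) are taken, rotated into the keypoint frame, and
#' Gaussian-weighted. Sixteen subregions each contribute the four sums
#' (sum dx, sum dy, sum |dx|, sum |dy|), giving 64 values, normalized to unit
#' length when the raw norm is positive. Borders are handled by reflection
#' padding, so the computation never fails near an edge.
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param kp A one-row keypoint data.frame (columns `x`, `y`, `sigma`,
#'   `theta`) as returned by [detect_keypoints()].
#' @param layout `"grid4x4"` (default; 4 x 4 square subregions) or
#'   `"concentric"` (4 radial rings x 4 angular sectors over a 10-sigma
#'   radius).
#' @return Numeric length-64 vector; all zeros with attribute
#'   `degenerate = TRUE` when the keypoint sits on a constant patch.
#' @export
compute_gdloh <- function(slice, kp, layout = c("grid4x4", "concentric")) {
  layout <- match.arg(layout)
  d <- compute_descriptors(slice, kp[1, , drop = FALSE], layout = layout)
  v <- d[1L, ]
  if (sum(v * v) == 0) attr(v, "degenerate") <- TRUE
  v
}

#' Compute GDLOH descriptors for a set of keypoints
#'
#' Batch form of [compute_gdloh()]; the image is reflect-padded once.
#'
#' @inheritParams compute_gdloh
#' @param kps Keypoint data.frame from [detect_keypoints()].
#' @return n x 64 numeric matrix (one row per keypoint).
#' @export
compute_descriptors <- function(slice, kps, layout = c("grid4x4", "concentric")) {
  layout <- match.arg(layout)
  img <- slice_pixels(slice)
  n <- nrow(kps)
  D <- matrix(0, n, 64L)
  if (!n) return(D)
  pad <- as.integer(ceiling(16 * max(kps$sigma))) + 2L
  pii <- integral_image(reflect_pad(img, pad))
  grid <- expand.grid(u = seq(-9.5, 9.5, by = 1), v = seq(-9.5, 9.5, by = 1))
  gw <- exp(-(grid$u^2 + grid$v^2) / (2 * 3.3^2))
  for (k in seq_len(n)) {
    sg <- kps$sigma[k]; th <- kps$theta[k]
    ct <- cos(th); st <- sin(th)
    px <- kps$x[k] + sg * (grid$u * ct - grid$v * st)
    py <- kps$y[k] + sg * (grid$u * st + grid$v * ct)
    s <- max(1L, as.integer(round(sg)))
    cc <- as.integer(round(px)) + 1L + pad
    rr <- as.integer(round(py)) + 1L + pad
    dx <- rect_sum(pii, rr - s, rr + s - 1L, cc, cc + s - 1L) -
          rect_sum(pii, rr - s, rr + s - 1L, cc - s, cc - 1L)
    dy <- rect_sum(pii, rr, rr + s - 1L, cc - s, cc + s - 1L) -
          rect_sum(pii, rr - s, rr - 1L, cc - s, cc + s - 1L)
    du <- (dx * ct + dy * st) * gw
    dv <- (-dx * st + dy * ct) * gw
    if (layout == "grid4x4") {
      bin <- (pmin(pmax(ceiling((grid$v + 10) / 5), 1L), 4L) - 1L) * 4L +
        pmin(pmax(ceiling((grid$u + 10) / 5), 1L), 4L)
      keep <- rep(TRUE, nrow(grid))
    } else {
      rho <- sqrt(grid$u^2 + grid$v^2)
      keep <- rho <= 10
      ring <- pmin(pmax(ceiling(rho / 2.5), 1L), 4L)
      sect <- (floor(((atan2(grid$v, grid$u)) %% (2 * pi)) / (pi / 2)) %% 4) + 1L
      bin <- (ring - 1L) * 4L + sect
    }
    b <- bin[keep]
    vec <- c(rbind(vapply(split(du[keep], factor(b, levels = 1:16)), sum, 0),
                   vapply(split(dv[keep], factor(b, levels = 1:16)), sum, 0),
                   vapply(split(abs(du[keep]), factor(b, levels = 1:16)), sum, 0),
                   vapply(split(abs(dv[keep]), factor(b, levels = 1:16)), sum, 0)))
    nrm <- sqrt(sum(vec * vec))
    D[k, ] <- if (nrm > 0) vec / nrm else 0
  }
  D
}

#' Correlation-aware descriptor distance
#'
#' For descriptors P and Q the distance is
#' `(sum(P^2) + sum(Q^2)) * sum((P - Q)^2) / (2 * sum(P * Q))`,
#' which augments the squared Euclidean distance with a factor sensitive to
#' the interrelationship of the two vectors. It is symmetric, zero for
#' identical nonzero vectors, and undefined when the cross term
#' `sum(P * Q)` is not positive: such pairs are declared incomparable and
#' reported as `NA` (never an error), to preserve nearest-neighbor semantics.
#'
#' @param p,q Numeric vectors of equal length (64 in the pipeline).
#' @param eps Positivity floor for the cross term (default `1e-12`).
#' @return Non-negative scalar, or `NA_real_` for an incomparable pair.
#' @export
descriptor_distance <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q))
    stop("descriptors must have equal length", call. = FALSE)
  cross <- sum(p * q)
  if (!is.finite(cross) || cross <= eps) return(NA_real_)
  (sum(p * p) + sum(q * q)) * sum((p - q)^2) / (2 * cross)
}

#' Match keypoints between two slices under a spatial gate
#'
#' For every source keypoint, candidate targets are those within an
#' axis-aligned `gate x gate` pixel window centered on the source location
#' (default 10, i.e. +/- 5 px per axis). The nearest candidate by
#' [descriptor_distance()] is selected; with `mutual = TRUE` (default) only
#' mutual nearest neighbors are kept, enforcing one-to-one correspondences.
#' Ties are broken toward the smaller spatial displacement, then the smaller
#' target index.
#'
#' @param src_kps,dst_kps Keypoint data.frames ([detect_keypoints()]).
#' @param src_desc,dst_desc Parallel descriptor matrices
#'   ([compute_descriptors()]).
#' @param gate Full width of the spatial window in pixels.
#' @param mutual Keep only mutual nearest neighbors (default `TRUE`).
#' @return A data.frame with one row per match: `src_idx`, `dst_idx`,
#'   `src_x`, `src_y`, `dst_x`, `dst_y`, `distance`, sorted by ascending
#'   distance. Zero rows when nothing matches.
#' @export
match_features <- function(src_kps, src_desc, dst_kps, dst_desc,
                           gate = 10, mutual = TRUE) {
  empty <- data.frame(src_idx = integer(), dst_idx = integer(),
                      src_x = numeric(), src_y = numeric(),
                      dst_x = numeric(), dst_y = numeric(),
                      distance = numeric())
  n <- nrow(src_kps); m <- nrow(dst_kps)
  if (!n || !m) return(empty)
  stopifnot(nrow(src_desc) == n, nrow(dst_desc) == m)
  half <- gate / 2
  dxm <- outer(src_kps$x, dst_kps$x, "-")
  dym <- outer(src_kps$y, dst_kps$y, "-")
  in_gate <- abs(dxm) <= half & abs(dym) <= half
  if (!any(in_gate)) return(empty)
  np <- rowSums(src_desc^2)
  nq <- rowSums(dst_desc^2)
  cross <- src_desc %*% t(dst_desc)
  sums <- outer(np, nq, "+")
  D <- sums * (sums - 2 * cross) / (2 * cross)
  D[!in_gate | cross <= 1e-12] <- NA
  disp2 <- dxm^2 + dym^2

  pick_nn <- function(Dm, sp2, margin) {
    # nearest neighbor along `margin` (1 = per src row, 2 = per dst col)
    apply_idx <- if (margin == 1L) seq_len(nrow(Dm)) else seq_len(ncol(Dm))
    vapply(apply_idx, function(i) {
      dvec <- if (margin == 1L) Dm[i, ] else Dm[, i]
      svec <- if (margin == 1L) sp2[i, ] else sp2[, i]
      ok <- which(!is.na(dvec))
      if (!length(ok)) return(NA_integer_)
      dmin <- min(dvec[ok])
      cands <- ok[dvec[ok] == dmin]
      if (length(cands) > 1L) cands <- cands[svec[cands] == min(svec[cands])]
      cands[1L]
    }, integer(1))
  }
  nn_fwd <- pick_nn(D, disp2, 1L)
  keep <- which(!is.na(nn_fwd))
  if (mutual) {
    nn_bwd <- pick_nn(D, disp2, 2L)
    keep <- keep[nn_bwd[nn_fwd[keep]] == keep]
  } else {
    # enforce one-to-one: smallest distance claims a contested target
    dsts <- nn_fwd[keep]
    dvals <- D[cbind(keep, dsts)]
    ord <- order(dvals, keep)
    seen <- logical(m); sel <- logical(length(keep))
    for (t in ord) {
      if (!seen[dsts[t]]) { seen[dsts[t]] <- TRUE; sel[t] <- TRUE }
    }
    keep <- keep[sel]
  }
  if (!length(keep)) return(empty)
  res <- data.frame(src_idx = keep, dst_idx = nn_fwd[keep],
                    src_x = src_kps$x[keep], src_y = src_kps$y[keep],
                    dst_x = dst_kps$x[nn_fwd[keep]],
                    dst_y = dst_kps$y[nn_fwd[keep]],
                    distance = D[cbind(keep, nn_fwd[keep])])
  res <- res[order(res$distance, res$src_idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}
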