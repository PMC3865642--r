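# Thin-plate-spline landmark warping: bordered-system fit, point mapping,
# dense displacement fields, and contour push-forward.

#' Thin-plate-spline radial basis
#'
#' `U(r) = r^2 * log(r^2)` (natural log), with the limit value `U(0) = 0`.
#'
#' @param r Non-negative distance (vectorized).
#' @return `U(r)`.
#' @export
tps_basis <- function(r) {
  if (any(r < 0)) stop("tps_basis needs r >= 0", call. = FALSE)
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos]^2)
  dim(out) <- dim(r)
  out
}

#' Fit a thin-plate-spline mapping from matched landmarks
#'
#' Solves the bordered linear system `L %*% (W | a)^T = (V | 0)^T` once per
#' output coordinate, where `L` stacks the radial-basis kernel `K` (with
#' `U(r) = r^2 log r^2`) over the affine border `P = [1 x y]`. With
#' `regularization = 0` the fitted map interpolates every control point
#' exactly; with `lambda > 0` the kernel becomes `K + lambda * I`
#' (approximating spline for noisy matches). Duplicate source points (closer
#' than 1e-6 px) are merged with their targets averaged. A near-singular
#' system (condition estimate above 1e12) triggers automatic light
#' regularization with a warning.
#'
#' @param src n x 2 matrix of source (template-slice) control points, n >= 3,
#'   not collinear.
#' @param dst n x 2 matrix of matched target-slice points.
#' @param regularization Smoothing parameter lambda (default 0, pure
#'   interpolation).
#' @return An object of class `tps_model` with elements `control_points`,
#'   `weights_x`, `weights_y`, `affine_x`, `affine_y` (each affine triple is
#'   `(a1, a_u, a_v)`), and `lambda`.
#' @export
fit_tps <- function(src, dst, regularization = 0) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!identical(dim(src), dim(dst)))
    stop("src and dst must be parallel n x 2 matrices", call. = FALSE)
  merged <- merge_duplicate_points(src, dst)
  src <- merged$src; dst <- merged$dst
  n <- nrow(src)
  if (n < 3L)
    stop("TPS fit needs at least 3 distinct control points, got ", n,
         call. = FALSE)
  ctr <- sweep(src, 2L, colMeans(src))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1))
    stop("control points are collinear; TPS system is singular ",
         "(points span a line through (", round(mean(src[, 1]), 2), ", ",
         round(mean(src[, 2]), 2), "))", call. = FALSE)

  K <- tps_basis(as.matrix(stats::dist(src)))
  lambda <- regularization
  P <- cbind(1, src)
  build_L <- function(lam) rbind(cbind(K + diag(lam, n), P),
                                 cbind(t(P), matrix(0, 3L, 3L)))
  L <- build_L(lambda)
  # degeneracy is judged scale-free: TPS interpolation is equivariant under
  # coordinate scaling, while kappa of the raw bordered system grows with
  # the coordinate extent even for well-spread landmarks
  ext <- max(diff(range(src[, 1L])), diff(range(src[, 2L])), 1)
  scl <- src / ext
  Kn <- tps_basis(as.matrix(stats::dist(scl)))
  Ln <- rbind(cbind(Kn, cbind(1, scl)),
              cbind(t(cbind(1, scl)), matrix(0, 3L, 3L)))
  if (lambda == 0 && kappa(Ln, exact = FALSE) > 1e12) {
    lambda <- 1e-6 * mean(abs(K[upper.tri(K)]))
    warning("near-singular TPS system; applying automatic regularization ",
            "lambda = ", signif(lambda, 3))
    L <- build_L(lambda)
  }
  Y <- rbind(dst, matrix(0, 3L, 2L))
  coef <- tryCatch(solve(L, Y), error = function(e)
    stop("TPS fit failed (singular system; check for duplicate or collinear ",
         "control points): ", conditionMessage(e), call. = FALSE))
  structure(list(control_points = src,
                 weights_x = coef[seq_len(n), 1L],
                 weights_y = coef[seq_len(n), 2L],
                 affine_x = coef[n + 1:3, 1L],
                 affine_y = coef[n + 1:3, 2L],
                 lambda = lambda),
            class = "tps_model")
}

merge_duplicate_points <- function(src, dst, tol = 1e-6) {
  n <- nrow(src)
  if (n < 2L) return(list(src = src, dst = dst))
  key <- paste(round(src[, 1L] / tol), round(src[, 2L] / tol))
  grp <- match(key, unique(key))
  src2 <- apply(src, 2L, function(col) tapply(col, grp, mean))
  dst2 <- apply(dst, 2L, function(col) tapply(col, grp, mean))
  list(src = matrix(src2, ncol = 2L), dst = matrix(dst2, ncol = 2L))
}

#' @export
print.tps_model <- function(x, ...) {
  cat("<tps_model> ", nrow(x$control_points), " control points, lambda = ",
      x$lambda, "\n", sep = "")
  invisible(x)
}

#' Apply a fitted TPS mapping to points
#'
#' Each point is mapped by `f(p) = a1 + a_u x + a_v y + sum_i w_i U(|P_i - p|)`
#' per output coordinate.
#'
#' @param model A `tps_model` from [fit_tps()].
#' @param points m x 2 matrix of (x, y) points.
#' @return m x 2 matrix of mapped points.
#' @export
apply_tps <- function(model, points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must be an m x 2 matrix", call. = FALSE)
  cp <- model$control_points
  d <- sqrt(outer(pts[, 1L], cp[, 1L], "-")^2 +
            outer(pts[, 2L], cp[, 2L], "-")^2)
  U <- tps_basis(d)
  fx <- model$affine_x[1L] + model$affine_x[2L] * pts[, 1L] +
    model$affine_x[3L] * pts[, 2L] + drop(U %*% model$weights_x)
  fy <- model$affine_y[1L] + model$affine_y[2L] * pts[, 1L] +
    model$affine_y[3L] * pts[, 2L] + drop(U %*% model$weights_y)
  cbind(fx, fy)
}

#' Evaluate a TPS model as a dense displacement field
#'
#' The deformation vector field over a slice: `dx(c, r) = f_x(c, r) - c` and
#' `dy(c, r) = f_y(c, r) - r` at every pixel, evaluated in row chunks to
#' bound memory.
#'
#' @param model A `tps_model`.
#' @param shape `c(rows, cols)`.
#' @return List of class `displacement_field` with `dx`, `dy` (rows x cols
#'   matrices, pixel units).
#' @export
tps_to_dvf <- function(model, shape) {
  rows <- as.integer(shape[1L]); cols <- as.integer(shape[2L])
  dx <- matrix(0, rows, cols); dy <- matrix(0, rows, cols)
  xs <- seq_len(cols) - 1L
  chunk <- max(1L, as.integer(2e6 / max(nrow(model$control_points) * cols, 1L)))
  r0 <- 1L
  while (r0 <= rows) {
    r1 <- min(rows, r0 + chunk - 1L)
    ys <- (r0:r1) - 1L
    pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = cols))
    f <- apply_tps(model, pts)
    dx[r0:r1, ] <- matrix(f[, 1L] - pts[, 1L], length(ys), cols)
    dy[r0:r1, ] <- matrix(f[, 2L] - pts[, 2L], length(ys), cols)
    r0 <- r1 + 1L
  }
  structure(list(dx = dx, dy = dy), class = "displacement_field")
}

#' Push a contour through a TPS mapping
#'
#' Vertices are mapped with [apply_tps()], clamped to the image bounds (with
#' a warning when clamping occurs), and resampled to uniform arc-length
#' spacing.
#'
#' @param model A `tps_model` mapping template to target coordinates.
#' @param contour A [contour()] on the template slice.
#' @param shape `c(rows, cols)` of the target slice, for bounds clamping.
#' @param spacing Resampling spacing in pixels (default 2).
#' @param target_index Slice index to stamp on the result (default: source
#'   index + 1).
#' @return The propagated [contour()].
#' @export
propagate_contour <- function(model, contour, shape, spacing = 2,
                              target_index = contour$slice_index + 1L) {
  mapped <- apply_tps(model, contour$vertices)
  clamped <- cbind(pmin(pmax(mapped[, 1L], 0), shape[2L]),
                   pmin(pmax(mapped[, 2L], 0), shape[1L]))
  if (any(clamped != mapped))
    warning("propagated contour '", contour$label,
            "' extended outside image bounds; vertices clamped")
  if (abs(polygon_area(clamped)) < 4)
    stop("propagated contour '", contour$label, "' is degenerate (area < 4 px^2)",
         call. = FALSE)
  contour(resample_closed(clamped, spacing = spacing),
          slice_index = target_index, label = contour$label)
}
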