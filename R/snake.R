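# Band-constrained greedy active contour refinement.

#' Snake configuration
#'
#' Weighted energy `alpha * E_cont + beta * E_curv + gamma * E_image` is
#' minimized greedily per vertex, with motion restricted to a band around the
#' initial contour. Defaults follow the optimized weight ranges for lung CT
#' (alpha 0.15, beta 0.2, gamma 0.85) and a band half-width of 5 px on a
#' 512-wide slice (the recommended 3-9 px range), scaled proportionally with
#' image width when `band = NULL`.
#'
#' @param alpha,beta,gamma Energy weights, each in `[0, 1]`.
#' @param band Band half-width in pixels (`NULL`: `5 * width / 512`, at
#'   least 3).
#' @param window Per-step search half-width in pixels (candidate grid
#'   `(2 * window + 1)^2`); must not exceed the band.
#' @param max_iter Maximum greedy sweeps.
#' @param move_frac_stop Stop when the fraction of vertices that moved in a
#'   sweep falls below this value.
#' @param smooth_sigma Gaussian smoothing (px) applied before the Sobel
#'   gradient used as image energy.
#' @param resample_spacing Uniform vertex spacing (px) imposed on the initial
#'   contour before refinement.
#' @return A list of class `snake_config`.
#' @export
snake_config <- function(alpha = 0.15, beta = 0.2, gamma = 0.85,
                         band = NULL, window = 1L, max_iter = 100L,
                         move_frac_stop = 0.05, smooth_sigma = 1,
                         resample_spacing = 2) {
  for (w in c(alpha, beta, gamma))
    if (w < 0 || w > 1) stop("snake weights must lie in [0, 1]", call. = FALSE)
  if (!is.null(band) && band < 1) stop("band must be >= 1", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (move_frac_stop <= 0 || move_frac_stop >= 1)
    stop("move_frac_stop must lie in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, band = band,
                 window = as.integer(window), max_iter = as.integer(max_iter),
                 move_frac_stop = move_frac_stop, smooth_sigma = smooth_sigma,
                 resample_spacing = resample_spacing),
            class = "snake_config")
}

default_band <- function(cfg, width) {
  if (!is.null(cfg$band)) return(cfg$band)
  max(3, round(5 * width / 512))
}

#' Raw snake energy terms for one candidate vertex position
#'
#' Returns the unnormalized terms of the contour energy at a candidate
#' position for vertex `i`: `E_cont = |dbar - |candidate - v[i-1]||` with
#' `dbar` the current mean vertex spacing, `E_curv = |v[i-1] - 2 candidate +
#' v[i+1]|^2`, and `E_image = -|grad I|` (Sobel magnitude of the smoothed
#' slice, bilinearly sampled). Inside [refine_contour()] each term is
#' min-max normalized over the candidate window before weighting.
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param vertices Current n x 2 vertex matrix (closed).
#' @param i Vertex index (1-based).
#' @param candidate Length-2 candidate `(x, y)` position.
#' @param grad Optional precomputed gradient-magnitude matrix.
#' @param smooth_sigma Smoothing used when `grad` is not supplied.
#' @return Named numeric vector `c(E_cont, E_curv, E_image)`.
#' @export
energy_terms <- function(slice, vertices, i, candidate, grad = NULL,
                         smooth_sigma = 1) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  ip <- if (i == 1L) n else i - 1L
  in_ <- if (i == n) 1L else i + 1L
  dbar <- mean(sqrt(rowSums(diff(v)^2)))   # mean consecutive vertex spacing
  e_cont <- abs(dbar - sqrt(sum((candidate - v[ip, ])^2)))
  e_curv <- sum((v[ip, ] - 2 * candidate + v[in_, ])^2)
  if (is.null(grad))
    grad <- gradient_magnitude(slice_pixels(slice), smooth_sigma)
  e_img <- -bilinear_sample(grad, candidate[1L], candidate[2L])
  c(E_cont = e_cont, E_curv = e_curv, E_image = e_img)
}

#' Refine a contour with the band-constrained greedy snake
#'
#' The initial contour is resampled to uniform spacing; each sweep visits the
#' vertices in order and moves each to the weighted-energy minimizer over the
#' `(2 * window + 1)^2` candidate grid intersected with the band around the
#' *initial* contour (hard constraint: no refined vertex ever strays more
#' than `band` px from the initial polyline). Each energy term is min-max
#' normalized over the candidate window before weighting; a move is accepted
#' only if it does not increase a fixed-normalization global energy, which
#' makes the recorded per-sweep energy non-increasing. Sweeping stops when
#' fewer than `move_frac_stop` of the vertices moved, or after `max_iter`
#' sweeps. Fully deterministic: ties are broken toward the candidate closest
#' to the current position, then lexicographically by (dx, dy).
#'
#' @param slice An [image_slice()] or numeric matrix (the target slice).
#' @param initial A [contour()] to refine.
#' @param cfg A [snake_config()].
#' @return A list of class `snake_result`: `contour` (refined), `initial`
#'   (resampled initial), `iterations`, `final_energy`, `energy_trace`,
#'   `converged`.
#' @export
refine_contour <- function(slice, initial, cfg = snake_config()) {
  img <- slice_pixels(slice)
  nr <- nrow(img); nc <- ncol(img)
  band <- default_band(cfg, nc)
  win <- min(cfg$window, band)
  if (abs(polygon_area(initial$vertices)) <= 0)
    stop("initial contour is degenerate", call. = FALSE)
  v0 <- resample_closed(initial$vertices, spacing = cfg$resample_spacing)
  v <- v0
  n <- nrow(v)
  grad <- gradient_magnitude(img, cfg$smooth_sigma)
  grng <- range(grad)
  gspan <- if (diff(grng) > 0) diff(grng) else 1
  dbar0 <- mean(sqrt(rowSums((v0[c(2:n, 1L), ] - v0)^2)))

  offs <- expand.grid(dx = -win:win, dy = -win:win)
  # deterministic tie-break order: closest to current position first, then
  # lexicographic (dx, dy); candidate 0 is always the current position
  offs <- offs[order(offs$dx^2 + offs$dy^2, offs$dx, offs$dy), , drop = FALSE]

  # fixed-normalization global energy of a single vertex (for acceptance)
  vertex_energy <- function(v, i, pos) {
    ip <- if (i == 1L) n else i - 1L
    in_ <- if (i == n) 1L else i + 1L
    ec <- abs(dbar0 - sqrt(sum((pos - v[ip, ])^2))) / max(dbar0, 1e-9)
    ek <- sum((v[ip, ] - 2 * pos + v[in_, ])^2) / max(dbar0^2, 1e-9)
    ei <- -(bilinear_sample(grad, pos[1L], pos[2L]) - grng[1L]) / gspan
    cfg$alpha * ec + cfg$beta * ek + cfg$gamma * ei
  }
  total_energy <- function(v)
    sum(vapply(seq_len(n), function(i) vertex_energy(v, i, v[i, ]), 0))

  trace <- total_energy(v)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    iterations <- it
    moved <- 0L
    dbar <- mean(sqrt(rowSums((v[c(2:n, 1L), ] - v)^2)))
    for (i in seq_len(n)) {
      ip <- if (i == 1L) n else i - 1L
      in_ <- if (i == n) 1L else i + 1L
      cx <- v[i, 1L] + offs$dx
      cy <- v[i, 2L] + offs$dy
      ok <- cx >= 0.5 & cx <= nc - 0.5 & cy >= 0.5 & cy <= nr - 0.5
      if (win > 0) {
        bd <- dist_to_closed_polyline(cbind(cx, cy), v0)
        ok <- ok & bd <= band
      }
      ok[1L] <- TRUE                      # current position always allowed
      cx <- cx[ok]; cy <- cy[ok]
      if (length(cx) < 2L) next
      e_cont <- abs(dbar - sqrt((cx - v[ip, 1L])^2 + (cy - v[ip, 2L])^2))
      e_curv <- (v[ip, 1L] - 2 * cx + v[in_, 1L])^2 +
                (v[ip, 2L] - 2 * cy + v[in_, 2L])^2
      e_img <- -bilinear_sample(grad, cx, cy)
      norm01 <- function(e) {
        rng <- range(e)
        if (rng[2L] > rng[1L]) (e - rng[1L]) / (rng[2L] - rng[1L]) else e * 0
      }
      score <- cfg$alpha * norm01(e_cont) + cfg$beta * norm01(e_curv) +
        cfg$gamma * norm01(e_img)
      best <- which.min(score)            # offs pre-sorted => deterministic
      if (best == 1L) next
      old_e <- vertex_energy(v, i, v[i, ]) + vertex_energy(v, ip, v[ip, ]) +
        vertex_energy(v, in_, v[in_, ])
      vtry <- v
      vtry[i, ] <- c(cx[best], cy[best])
      new_e <- vertex_energy(vtry, i, vtry[i, ]) +
        vertex_energy(vtry, ip, vtry[ip, ]) +
        vertex_energy(vtry, in_, vtry[in_, ])
      if (new_e <= old_e + 1e-12) {
        v <- vtry
        moved <- moved + 1L
      }
    }
    trace <- c(trace, total_energy(v))
    if (moved / n < cfg$move_frac_stop) { converged <- TRUE; break }
  }
  structure(list(contour = contour(v, slice_index = initial$slice_index,
                                   label = initial$label),
                 initial = contour(v0, slice_index = initial$slice_index,
                                   label = initial$label),
                 iterations = iterations,
                 final_energy = trace[length(trace)],
                 energy_trace = trace,
                 converged = converged),
            class = "snake_result")
}
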