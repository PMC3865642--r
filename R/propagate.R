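# Orchestration of the recursive slice-by-slice contour propagation:
# detect -> describe -> match -> fit TPS -> push contour -> snake-refine.

#' Feature sub-configuration for propagation
#'
#' @param hessian_threshold Detector response threshold.
#' @param n_octaves Detector pyramid octaves.
#' @param gate Spatial matching gate (full width, px).
#' @param mutual Keep only mutual nearest neighbors.
#' @param layout GDLOH subregion layout, `"grid4x4"` or `"concentric"`.
#' @param max_keypoints Cap on keypoints per slice (strongest kept).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(hessian_threshold = 2e-4, n_octaves = 3L,
                           gate = 10, mutual = TRUE, layout = "grid4x4",
                           max_keypoints = 500L) {
  structure(list(hessian_threshold = hessian_threshold,
                 n_octaves = as.integer(n_octaves), gate = gate,
                 mutual = isTRUE(mutual), layout = layout,
                 max_keypoints = max_keypoints),
            class = "feature_config")
}

#' Propagation configuration
#'
#' @param max_distance Maximum slices to propagate per direction (default
#'   20, beyond which prior-knowledge influence decays too far).
#' @param min_matches Minimum matched point pairs for a reliable TPS fit
#'   (default 30 control points per slice).
#' @param feature A [feature_config()].
#' @param tps List with `lambda` (TPS regularization) and `resample_spacing`
#'   (contour vertex spacing in px).
#' @param snake A [snake_config()].
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(max_distance = 20L, min_matches = 30L,
                               feature = feature_config(),
                               tps = list(lambda = 0, resample_spacing = 2),
                               snake = snake_config()) {
  if (max_distance < 1L) stop("max_distance must be >= 1", call. = FALSE)
  if (min_matches < 3L) stop("min_matches must be >= 3", call. = FALSE)
  structure(list(max_distance = as.integer(max_distance),
                 min_matches = as.integer(min_matches),
                 feature = feature, tps = tps, snake = snake),
            class = "propagation_config")
}

detect_and_describe <- function(slice, fcfg, threshold = fcfg$hessian_threshold) {
  kps <- detect_keypoints(slice, hessian_threshold = threshold,
                          n_octaves = fcfg$n_octaves,
                          max_keypoints = fcfg$max_keypoints)
  list(kps = kps, desc = compute_descriptors(slice, kps, layout = fcfg$layout))
}

#' One propagation step between adjacent slices
#'
#' Detects and describes keypoints on the template and target slices,
#' matches them under the spatial gate, fits a thin-plate spline to the
#' matched pairs, pushes the contour(s) through it, and refines each with
#' the band-constrained snake on the target slice. If fewer than
#' `min_matches` pairs are found, the step is retried once with the detector
#' threshold halved; if it still fails, an error of class
#' `contourprop_step_failure` is raised with the match count attached.
#'
#' @param template,target [image_slice()]s (or matrices) of equal shape.
#' @param contours A [contour()] on the template slice, or a list of them.
#' @param cfg A [propagation_config()].
#' @param target_index Slice index stamped on the returned contours.
#' @param template_feats,target_feats Optional precomputed
#'   `detect_and_describe()` results (cache used by [propagate_volume()]).
#' @return List with `initial` (pre-snake contours), `refined` (post-snake),
#'   `model` (the `tps_model`), `diagnostics` (keypoint/match counts, mean
#'   match distance, max TPS residual at the control points, retry flag),
#'   and `target_feats` for reuse.
#' @export
propagate_step <- function(template, target, contours, cfg = propagation_config(),
                           target_index = NULL,
                           template_feats = NULL, target_feats = NULL) {
  single <- inherits(contours, "contour")
  clist <- if (single) list(contours) else contours
  stopifnot(length(clist) >= 1L)
  timg <- slice_pixels(template); gimg <- slice_pixels(target)
  if (!identical(dim(timg), dim(gimg)))
    stop("template and target slices differ in shape", call. = FALSE)
  if (is.null(target_index)) target_index <- clist[[1L]]$slice_index + 1L
  fcfg <- cfg$feature

  if (is.null(template_feats)) template_feats <- detect_and_describe(timg, fcfg)
  if (is.null(target_feats)) target_feats <- detect_and_describe(gimg, fcfg)
  matches <- match_features(template_feats$kps, template_feats$desc,
                            target_feats$kps, target_feats$desc,
                            gate = fcfg$gate, mutual = fcfg$mutual)
  retried <- FALSE
  if (nrow(matches) < cfg$min_matches) {
    retried <- TRUE
    tf2 <- detect_and_describe(timg, fcfg, threshold = fcfg$hessian_threshold / 2)
    gf2 <- detect_and_describe(gimg, fcfg, threshold = fcfg$hessian_threshold / 2)
    m2 <- match_features(tf2$kps, tf2$desc, gf2$kps, gf2$desc,
                         gate = fcfg$gate, mutual = fcfg$mutual)
    if (nrow(m2) > nrow(matches)) matches <- m2
  }
  if (nrow(matches) < cfg$min_matches) {
    cond <- structure(class = c("contourprop_step_failure", "error", "condition"),
                      list(message = paste0("propagation step failed: ",
                                            nrow(matches), " matches < min_matches = ",
                                            cfg$min_matches),
                           call = sys.call(),
                           n_matches = nrow(matches)))
    stop(cond)
  }
  model <- fit_tps(cbind(matches$src_x, matches$src_y),
                   cbind(matches$dst_x, matches$dst_y),
                   regularization = cfg$tps$lambda)
  # residual at the (merged) control points; 0 for an interpolating fit
  mapped <- apply_tps(model, model$control_points)
  fitted_dst <- merge_duplicate_points(cbind(matches$src_x, matches$src_y),
                                       cbind(matches$dst_x, matches$dst_y))$dst
  residual <- max(sqrt(rowSums((mapped - fitted_dst)^2)))

  shape <- dim(gimg)
  initial <- lapply(clist, function(ct)
    propagate_contour(model, ct, shape, spacing = cfg$tps$resample_spacing,
                      target_index = target_index))
  refined <- lapply(initial, function(ct)
    refine_contour(gimg, ct, cfg$snake)$contour)
  diagnostics <- data.frame(
    n_template_kps = nrow(template_feats$kps),
    n_target_kps = nrow(target_feats$kps),
    n_matches = nrow(matches),
    mean_match_distance = mean(matches$distance),
    tps_residual = residual,
    retried = retried)
  list(initial = if (single) initial[[1L]] else initial,
       refined = if (single) refined[[1L]] else refined,
       model = model, diagnostics = diagnostics,
       target_feats = target_feats)
}

#' Propagate a seed contour through a volume
#'
#' From one manually delineated slice, contours are carried bidirectionally,
#' slice by slice: each step registers the previous (template) slice to the
#' next (target) slice and the previous step's *refined* contour is the next
#' step's input, so every step starts from the best available contour.
#' Propagation in a direction stops at the volume end, after `max_distance`
#' steps, or on a failed step (too few matches; logged as a warning). When
#' several structures share the seed slice they are propagated with the same
#' per-step TPS model, fitted once per slice pair.
#'
#' @param vol A [volume()].
#' @param seed A [contour()] or list of contours, all on the same slice
#'   (`slice_index` 0-based within the volume).
#' @param cfg A [propagation_config()].
#' @return A list of class `propagation_result`: `contours` (refined, the
#'   seed included unchanged), `initial` (pre-snake contours for propagated
#'   slices), `diagnostics` (one row per step), `seed_slice`.
#' @export
propagate_volume <- function(vol, seed, cfg = propagation_config()) {
  stopifnot(inherits(vol, "volume"))
  seeds <- if (inherits(seed, "contour")) list(seed) else seed
  s0 <- seeds[[1L]]$slice_index
  for (ct in seeds)
    if (ct$slice_index != s0)
      stop("all seed contours must live on the same slice", call. = FALSE)
  nk <- n_slices(vol)
  if (s0 < 0L || s0 >= nk)
    stop("seed slice index ", s0, " outside volume (0..", nk - 1L, ")",
         call. = FALSE)
  if (vol$slice_thickness > 3)
    warning("slice thickness ", vol$slice_thickness,
            " mm exceeds the 3 mm guidance for reliable propagation")
  shape <- slice_shape(vol)
  for (ct in seeds) validate_contour_bounds(ct, shape)

  contours <- seeds            # refined (seed kept byte-identical)
  initial <- list()
  diag_rows <- list()
  fcfg <- cfg$feature

  for (dir in c(1L, -1L)) {
    cur <- seeds
    feats <- NULL              # cache: features of the current template slice
    k <- s0
    steps <- 0L
    while (steps < cfg$max_distance) {
      nxt <- k + dir
      if (nxt < 0L || nxt >= nk) break
      step <- tryCatch(
        propagate_step(vol$slices[[k + 1L]], vol$slices[[nxt + 1L]],
                       cur, cfg, target_index = nxt,
                       template_feats = feats),
        contourprop_step_failure = function(e) e)
      if (inherits(step, "contourprop_step_failure")) {
        warning("propagation halted at slice ", nxt, " (direction ",
                ifelse(dir > 0, "+", "-"), "): ", conditionMessage(step))
        break
      }
      d <- step$diagnostics
      d$template_slice <- k; d$target_slice <- nxt; d$direction <- dir
      diag_rows[[length(diag_rows) + 1L]] <- d
      contours <- c(contours, step$refined)
      initial <- c(initial, step$initial)
      cur <- step$refined
      feats <- step$target_feats
      k <- nxt
      steps <- steps + 1L
    }
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame()
  structure(list(contours = contours, initial = initial,
                 diagnostics = diagnostics, seed_slice = s0),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  sl <- sort(unique(vapply(x$contours, function(ct) ct$slice_index, 0L)))
  cat("<propagation_result> seed slice ", x$seed_slice, ", contours on ",
      length(sl), " slices (", min(sl), "..", max(sl), ")\n", sep = "")
  invisible(x)
}

#' Write a propagation result as per-slice contour JSONs plus diagnostics
#'
#' @param result A `propagation_result`.
#' @param dir Output directory; refined contours are written as
#'   `contour_s<slice>_<label>.json`, pre-snake ones under `initial/`, and
#'   the per-step diagnostics as `diagnostics.csv`.
#' @export
save_propagation <- function(result, dir) {
  dir.create(file.path(dir, "initial"), showWarnings = FALSE, recursive = TRUE)
  for (ct in result$contours)
    save_contour(ct, file.path(dir, sprintf("contour_s%03d_%s.json",
                                            ct$slice_index, ct$label)))
  for (ct in result$initial)
    save_contour(ct, file.path(dir, "initial",
                               sprintf("contour_s%03d_%s.json",
                                       ct$slice_index, ct$label)))
  if (nrow(result$diagnostics))
    utils::write.csv(result$diagnostics, file.path(dir, "diagnostics.csv"),
                     row.names = FALSE)
  invisible(dir)
}
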