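# Segmentation agreement metrics: Jaccard similarity and Hausdorff distances.

#' Jaccard similarity of two masks
#'
#' `|A intersect B| / |A union B|`; 1 means perfect overlap, 0 none. Two
#' empty masks are degenerate and score 1 with a warning.
#'
#' @param auto,manual Logical matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(auto, manual) {
  if (!identical(dim(auto), dim(manual)))
    stop("mask shapes differ: ", paste(dim(auto), collapse = "x"), " vs ",
         paste(dim(manual), collapse = "x"), call. = FALSE)
  uni <- sum(auto | manual)
  if (uni == 0) {
    warning("both masks are empty; Jaccard defined as 1 (degenerate)")
    return(1)
  }
  sum(auto & manual) / uni
}

#' Hausdorff distances between two contours
#'
#' Both contours are densely resampled (default 0.5 px spacing) and the
#' directed nearest-point distances computed both ways. `hd_max` is the
#' classical (100%) Hausdorff distance, the larger of the two directed
#' maxima; `hd_mean` averages the two directed mean distances (average
#' symmetric surface distance). Distances are Euclidean in pixels; multiply
#' by the pixel spacing for mm. Plain point matrices are accepted as-is
#' (no resampling), which admits degenerate single-point sets for testing.
#'
#' @param a,b [contour()] objects, or n x 2 point matrices.
#' @param resample_spacing Resampling spacing in pixels for contours.
#' @return Named numeric vector `c(hd_max, hd_mean)`.
#' @export
hausdorff <- function(a, b, resample_spacing = 0.5) {
  pa <- contour_points(a, resample_spacing)
  pb <- contour_points(b, resample_spacing)
  d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
  d_ab <- sqrt(apply(d2, 1L, min))   # each point of a to set b
  d_ba <- sqrt(apply(d2, 2L, min))
  c(hd_max = max(max(d_ab), max(d_ba)),
    hd_mean = (mean(d_ab) + mean(d_ba)) / 2)
}

# contours are densely resampled; raw point matrices are used as-is
contour_points <- function(x, spacing) {
  if (inherits(x, "contour")) return(resample_closed(x$vertices, spacing))
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) != 2L)
    stop("expected a contour or an n x 2 point matrix", call. = FALSE)
  m
}

#' Score predicted contours against reference contours
#'
#' Rasterizes both contour sets on a common shape and reports, per matched
#' (slice, structure) key, the Jaccard similarity and the maximum and mean
#' Hausdorff distances, plus per-structure aggregates (mean and sd).
#' Reference keys with no prediction are recorded as absent with a warning
#' and excluded from the aggregates.
#'
#' @param pred,truth Lists of [contour()] objects.
#' @param shape `c(rows, cols)` used for rasterization.
#' @param pixel_spacing Optional mm per pixel; when given, Hausdorff columns
#'   are also reported in mm (`hd_max_mm`, `hd_mean_mm`).
#' @return A list of class `metrics_report`: `per_key` data.frame (`slice`,
#'   `structure`, `js`, `hd_max`, `hd_mean`, `absent`), `aggregate`
#'   data.frame of per-structure mean/sd, and `shape`.
#' @export
evaluate_contours <- function(pred, truth, shape, pixel_spacing = NULL) {
  key_of <- function(ct) paste0(ct$slice_index, "|", ct$label)
  pred_keys <- vapply(pred, key_of, "")
  rows <- lapply(truth, function(tr) {
    k <- key_of(tr)
    hit <- which(pred_keys == k)
    if (!length(hit)) {
      warning("no predicted contour for slice ", tr$slice_index,
              " structure '", tr$label, "'")
      return(data.frame(slice = tr$slice_index, structure = tr$label,
                        js = NA_real_, hd_max = NA_real_, hd_mean = NA_real_,
                        absent = TRUE))
    }
    pr <- pred[[hit[1L]]]
    js <- jaccard(rasterize_contour(pr, shape), rasterize_contour(tr, shape))
    hd <- hausdorff(pr, tr)
    data.frame(slice = tr$slice_index, structure = tr$label, js = js,
               hd_max = hd[["hd_max"]], hd_mean = hd[["hd_mean"]],
               absent = FALSE)
  })
  per_key <- do.call(rbind, rows)
  per_key <- per_key[order(per_key$structure, per_key$slice), , drop = FALSE]
  rownames(per_key) <- NULL
  ok <- per_key[!per_key$absent, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(ok, ok$structure), function(d)
    data.frame(structure = d$structure[1L], n = nrow(d),
               js_mean = mean(d$js), js_sd = stats::sd(d$js),
               hd_max_mean = mean(d$hd_max), hd_max_sd = stats::sd(d$hd_max),
               hd_mean_mean = mean(d$hd_mean), hd_mean_sd = stats::sd(d$hd_mean))))
  if (!is.null(agg)) rownames(agg) <- NULL
  if (!is.null(pixel_spacing)) {
    per_key$hd_max_mm <- per_key$hd_max * pixel_spacing
    per_key$hd_mean_mm <- per_key$hd_mean * pixel_spacing
  }
  structure(list(per_key = per_key, aggregate = agg, shape = shape),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$per_key), " (slice, structure) pairs\n",
      sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' @param report A `metrics_report` from [evaluate_contours()].
#' @param path Per-key CSV path; the aggregate table is written next to it
#'   with an `_aggregate` suffix.
#' @export
save_metrics_report <- function(report, path) {
  utils::write.csv(report$per_key, path, row.names = FALSE)
  agg_path <- sub("(\\.[^.]+)?$", "_aggregate\\1", path)
  utils::write.csv(report$aggregate, agg_path, row.names = FALSE)
  invisible(path)
}
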