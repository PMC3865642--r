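# Synthetic lung-CT-like slice stacks with known ground truth: two dark lung
# fields carrying bright vascular-like texture, a bright spinal-cord disk, an
# optional tumor blob, a smooth bounded random inter-slice deformation, and
# additive Gaussian noise.

#' Specification of a synthetic phantom stack
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 256 px slices, 21 slices (a middle seed then propagates up to 10
#' each way), at most 4 px of smooth deformation between adjacent slices,
#' and mild additive noise. Intensities are unitless in `[0, 1]` and only
#' loosely mimic a CT window (lung fields dark, soft tissue and cord bright).
#'
#' @param size Pixels per (square) side, at least 64.
#' @param n_slices Number of slices.
#' @param max_disp Maximum displacement magnitude (px) of each inter-slice
#'   deformation field (enforced exactly).
#' @param texture_density Vascular-like texture blobs per 1e4 px.
#' @param noise_sigma Additive Gaussian noise sd (intensity units).
#' @param structures Subset of `c("lung_L", "lung_R", "cord", "tumor")`.
#' @param seed Integer RNG seed; identical seeds give identical stacks.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256L, n_slices = 21L, max_disp = 4,
                         texture_density = 8, noise_sigma = 0.01,
                         structures = c("lung_L", "lung_R", "cord", "tumor"),
                         seed = 42L) {
  if (size < 64L) stop("phantom size must be >= 64", call. = FALSE)
  if (n_slices < 1L) stop("need at least one slice", call. = FALSE)
  if (max_disp < 0) stop("max_disp must be >= 0", call. = FALSE)
  if (!length(structures)) stop("structures must be non-empty", call. = FALSE)
  structures <- match.arg(structures, several.ok = TRUE)
  structure(list(size = as.integer(size), n_slices = as.integer(n_slices),
                 max_disp = max_disp, texture_density = texture_density,
                 noise_sigma = noise_sigma, structures = structures,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom stack with ground truth
#'
#' Builds a base slice from smooth background plus the requested structures,
#' then chains slices: each next slice is the previous (noise-free) slice
#' warped by a fresh smooth random displacement field — a thin-plate spline
#' on a jittered 5 x 5 control grid, rescaled so its sup-norm displacement is
#' at most `max_disp` — with independent Gaussian noise added per slice.
#' Ground-truth contours are pushed through exactly the same forward fields,
#' so `truth[k + 1] = field_k(truth[k])` holds to machine precision. Images
#' are pulled back through the inverted field (fixed-point inversion,
#' 5 iterations) with bilinear resampling.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_stack`: `volume` (a [volume()]), `truth`
#'   (list of ground-truth [contour()]s, one per slice and structure),
#'   `fields` (list of `displacement_field`s, one per adjacent slice pair),
#'   `models` (the corresponding `tps_model`s), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(spec$seed)

  base <- phantom_base_slice(spec)
  clean <- base$image
  truth0 <- base$contours
  sz <- spec$size

  slices <- vector("list", spec$n_slices)
  truth <- list()
  fields <- vector("list", max(spec$n_slices - 1L, 0L))
  models <- vector("list", max(spec$n_slices - 1L, 0L))

  add_noise <- function(img)
    if (spec$noise_sigma > 0)
      img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                   nrow(img)) else img

  slices[[1L]] <- add_noise(clean)
  cur_truth <- lapply(truth0, function(ct) { ct$slice_index <- 0L; ct })
  truth <- c(truth, cur_truth)

  for (k in seq_len(spec$n_slices - 1L)) {
    fm <- random_deformation(spec, sz)
    models[[k]] <- fm$model
    fields[[k]] <- fm$field
    clean <- if (is.null(fm$model)) clean else
      warp_image_backward(clean, fm$field)
    slices[[k + 1L]] <- add_noise(clean)
    cur_truth <- lapply(cur_truth, function(ct) {
      v <- if (is.null(fm$model)) ct$vertices else apply_tps(fm$model, ct$vertices)
      contour(cbind(pmin(pmax(v[, 1L], 0), sz), pmin(pmax(v[, 2L], 0), sz)),
              slice_index = k, label = ct$label)
    })
    truth <- c(truth, cur_truth)
  }
  structure(list(volume = volume(slices), truth = truth, fields = fields,
                 models = models, spec = spec),
            class = "phantom_stack")
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat("<phantom_stack> ", x$spec$n_slices, " slices of ", x$spec$size, " x ",
      x$spec$size, ", structures: ",
      paste(x$spec$structures, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Base slice plus exact boundary contours of every structure.
phantom_base_slice <- function(spec) {
  sz <- spec$size
  xs <- seq_len(sz) - 0.5
  X <- matrix(xs, sz, sz, byrow = TRUE)    # x at each pixel center
  Y <- matrix(xs, sz, sz)                  # y at each pixel center

  img <- 0.55 + 0.06 * sin(2 * pi * Y / sz) * cos(pi * X / sz)

  lungs <- list(
    lung_L = list(cx = 0.30 * sz, cy = 0.48 * sz, a = 0.16 * sz, b = 0.28 * sz),
    lung_R = list(cx = 0.70 * sz, cy = 0.48 * sz, a = 0.16 * sz, b = 0.28 * sz))
  soft_inside <- function(e, scale) stats::plogis(-e * scale)

  lung_blend <- matrix(0, sz, sz)
  for (lg in lungs) {
    e <- sqrt(((X - lg$cx) / lg$a)^2 + ((Y - lg$cy) / lg$b)^2) - 1
    lung_blend <- pmax(lung_blend, soft_inside(e, 2 * min(lg$a, lg$b)))
  }
  img <- img * (1 - lung_blend) + 0.15 * lung_blend

  # vascular-like texture: bright blob chains inside the lung fields, plus a
  # smaller share of mediastinal vessels between them (as in real CT, these
  # anchor registration outside the lung fields)
  n_blobs <- max(8L, as.integer(round(spec$texture_density * sz^2 / 1e4)))
  for (b in seq_len(n_blobs)) {
    in_mediastinum <- stats::runif(1) < 0.2
    if (in_mediastinum) {
      bx <- stats::runif(1, 0.42 * sz, 0.58 * sz)
      by <- stats::runif(1, 0.25 * sz, 0.65 * sz)
    } else {
      lg <- lungs[[sample.int(2L, 1L)]]
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1, 0, 0.85))
      bx <- lg$cx + rad * lg$a * cos(ang)
      by <- lg$cy + rad * lg$b * sin(ang)
    }
    amp <- stats::runif(1, 0.25, 0.5) * (if (in_mediastinum) -0.7 else 1)
    sg <- stats::runif(1, 1.2, 2.4)
    n_seg <- sample(2:6, 1L)
    dir <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(n_seg)) {
      blend <- if (in_mediastinum) 1 else lung_blend
      img <- img + amp * blend *
        exp(-((X - bx)^2 + (Y - by)^2) / (2 * sg^2))
      step <- 2.2 * sg
      dir <- dir + stats::rnorm(1, 0, 0.5)
      bx <- bx + step * cos(dir); by <- by + step * sin(dir)
    }
  }

  contours <- list()
  ellipse_contour <- function(cx, cy, a, b, n, label) {
    t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    contour(cbind(cx + a * cos(t), cy + b * sin(t)), 0L, label)
  }
  for (nm in intersect(c("lung_L", "lung_R"), spec$structures)) {
    lg <- lungs[[nm]]
    contours[[nm]] <- ellipse_contour(lg$cx, lg$cy, lg$a, lg$b, 64L, nm)
  }
  if ("cord" %in% spec$structures) {
    cx <- 0.5 * sz; cy <- 0.80 * sz; r <- 0.035 * sz
    # vertebral body around the canal: the bony structure that anchors
    # registration near the cord in real CT
    ev <- sqrt(((X - cx) / (2.3 * r))^2 + ((Y - cy - 0.4 * r) / (1.9 * r))^2) - 1
    wv <- soft_inside(ev, 4 * r)
    img <- img * (1 - wv) + 0.70 * wv
    e <- sqrt((X - cx)^2 + (Y - cy)^2) / r - 1
    w <- soft_inside(e, 2 * r)
    img <- img * (1 - w) + 0.90 * w
    contours$cord <- ellipse_contour(cx, cy, r, r, 32L, "cord")
  }
  if ("tumor" %in% spec$structures) {
    cx <- 0.66 * sz; cy <- 0.36 * sz; r <- 0.05 * sz
    e <- sqrt((X - cx)^2 + (Y - cy)^2) / r - 1
    w <- soft_inside(e, 2 * r)
    img <- img * (1 - w) + 0.78 * w
    contours$tumor <- ellipse_contour(cx, cy, r, r, 48L, "tumor")
  }
  list(image = img, contours = contours)
}

# Smooth random forward deformation with exact sup-norm bound `max_disp`.
random_deformation <- function(spec, sz) {
  if (spec$max_disp == 0)
    return(list(model = NULL,
                field = structure(list(dx = matrix(0, sz, sz),
                                       dy = matrix(0, sz, sz)),
                                  class = "displacement_field")))
  g <- seq(0, sz, length.out = 5L)
  grid <- as.matrix(expand.grid(x = g, y = g))
  jit <- matrix(stats::runif(nrow(grid) * 2L, -0.8, 0.8) * spec$max_disp,
                ncol = 2L)
  model <- fit_tps(grid, grid + jit)
  field <- tps_to_dvf(model, c(sz, sz))
  mx <- max(sqrt(field$dx^2 + field$dy^2))
  if (mx > spec$max_disp) {
    # TPS is linear in its targets, so scaling the jitter scales the field
    s <- spec$max_disp / mx
    model <- fit_tps(grid, grid + jit * s)
    field$dx <- field$dx * s
    field$dy <- field$dy * s
  }
  list(model = model, field = field)
}

# Pull an image back through a forward displacement field: invert the field
# by fixed-point iteration, then bilinearly resample.
warp_image_backward <- function(img, field, n_iter = 5L) {
  nr <- nrow(img); nc <- ncol(img)
  tx <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)  # field grid coords
  ty <- matrix(seq_len(nr) - 1L, nr, nc)
  sx <- tx; sy <- ty
  for (i in seq_len(n_iter)) {
    dx <- matrix(bilinear_sample(field$dx, sx + 0.5, sy + 0.5), nr, nc)
    dy <- matrix(bilinear_sample(field$dy, sx + 0.5, sy + 0.5), nr, nc)
    sx <- tx - dx
    sy <- ty - dy
  }
  matrix(bilinear_sample(img, sx + 0.5, sy + 0.5), nr, nc)
}

#' Export a phantom stack to disk
#'
#' Writes the volume as NIfTI plus 16-bit slice PNGs, every ground-truth
#' contour as JSON (`truth_s<slice>_<structure>.json`), and each inter-slice
#' displacement field as a 2-band 32-bit float TIFF.
#'
#' @param stack A `phantom_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
export_phantom <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_volume(stack$volume, file.path(dir, "volume.nii.gz"), "nifti")
  save_volume(stack$volume, file.path(dir, "slices"), "slice_dir")
  for (ct in stack$truth)
    save_contour(ct, file.path(dir, sprintf("truth_s%03d_%s.json",
                                            ct$slice_index, ct$label)))
  for (k in seq_along(stack$fields))
    save_field(stack$fields[[k]],
               file.path(dir, sprintf("field_%03d.tif", k - 1L)))
  invisible(dir)
}

#' Read / write a displacement field as a 2-band 32-bit float TIFF
#'
#' Band 1 is dx, band 2 dy (pixel units). Values are stored min-max scaled
#' to `[0, 1]` with the affine transform recorded in a JSON sidecar next to
#' the TIFF, so round-trips recover the field to 32-bit float precision.
#'
#' @param field A `displacement_field`.
#' @param path TIFF path (sidecar written as `<path>.json`).
#' @export
save_field <- function(field, path) {
  arr <- array(c(field$dx, field$dy), c(nrow(field$dx), ncol(field$dx), 2L))
  mn <- min(arr); mx <- max(arr)
  span <- if (mx > mn) mx - mn else 1
  suppressWarnings(tiff::writeTIFF((arr - mn) / span, path,
                                   bits.per.sample = 32L, reduce = FALSE))
  jsonlite::write_json(list(min = mn, span = span), paste0(path, ".json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  arr <- suppressWarnings(tiff::readTIFF(path)) * meta$span + meta$min
  structure(list(dx = arr[, , 1L], dy = arr[, , 2L]),
            class = "displacement_field")
}
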