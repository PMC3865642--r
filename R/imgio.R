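# Coordinate convention (pinned, used everywhere in the package):
#   x = column, y = row, both 0-based. Pixel (c, r) occupies the unit square
#   [c, c+1) x [r, r+1) and has center (c + 0.5, r + 0.5). A pixel matrix is
#   stored row x col, so pixel (c, r) is pixels[r + 1, c + 1].

#' Construct a single image slice
#'
#' An `image_slice` is a rectangular 2D grayscale matrix (rows x cols of
#' finite intensities) together with its integer position in the stack.
#'
#' @param pixels Numeric matrix of intensities, at least 16 x 16.
#' @param index Integer slice position (0-based within the stack).
#' @return An object of class `image_slice` with elements `pixels`, `index`.
#' @export
image_slice <- function(pixels, index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("slice must be at least 16 x 16, got ",
         nrow(pixels), " x ", ncol(pixels), call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("slice contains non-finite intensities", call. = FALSE)
  structure(list(pixels = pixels, index = as.integer(index)),
            class = "image_slice")
}

#' Construct a volume from ordered slices
#'
#' @param slices List of [image_slice()] objects (or plain matrices), all the
#'   same shape, ordered by acquisition position.
#' @param slice_thickness Slice-to-slice spacing in mm (must be positive).
#' @param pixel_spacing In-plane spacing in mm per pixel.
#' @return An object of class `volume`.
#' @export
volume <- function(slices, slice_thickness = 1, pixel_spacing = 1) {
  if (!length(slices)) stop("volume needs at least one slice", call. = FALSE)
  slices <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    if (is.matrix(s)) s <- image_slice(s, i - 1L)
    if (!inherits(s, "image_slice")) stop("slices must be image_slice objects")
    s$index <- i - 1L
    s
  })
  shp <- dim(slices[[1L]]$pixels)
  for (s in slices)
    if (!identical(dim(s$pixels), shp))
      stop("inconsistent slice shapes: expected ", shp[1], " x ", shp[2],
           ", slice ", s$index, " is ", nrow(s$pixels), " x ", ncol(s$pixels),
           call. = FALSE)
  if (!is.numeric(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be > 0", call. = FALSE)
  structure(list(slices = slices,
                 slice_thickness = as.numeric(slice_thickness),
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  shp <- dim(x$slices[[1L]]$pixels)
  cat("<volume> ", length(x$slices), " slices of ", shp[1], " x ", shp[2],
      ", thickness ", x$slice_thickness, " mm, pixel spacing ",
      x$pixel_spacing, " mm\n", sep = "")
  invisible(x)
}

n_slices <- function(vol) length(vol$slices)
slice_shape <- function(vol) dim(vol$slices[[1L]]$pixels)

#' Construct a closed planar contour
#'
#' A contour is an ordered closed polyline in pixel coordinates (x = column,
#' y = row, 0-based); the last vertex implicitly connects back to the first.
#'
#' @param vertices Numeric n x 2 matrix of (x, y) vertices, n >= 3.
#' @param slice_index Integer index of the slice the contour lives on.
#' @param label Structure name, e.g. `"lung_L"`, `"cord"`, `"tumor"`.
#' @return An object of class `contour`.
#' @export
contour <- function(vertices, slice_index = 0L, label = "structure") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("contour needs an n x 2 vertex matrix with n >= 3, got ",
         nrow(vertices), " vertices", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("contour vertices must be finite", call. = FALSE)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, slice_index = as.integer(slice_index),
                 label = as.character(label)),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat("<contour> '", x$label, "' on slice ", x$slice_index, ", ",
      nrow(x$vertices), " vertices, area ",
      format(abs(polygon_area(x$vertices)), digits = 4), " px^2\n", sep = "")
  invisible(x)
}

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise vertex order in the (x right, y down)
#' pixel frame.
#'
#' @param vertices n x 2 matrix of (x, y) vertices of a closed polygon.
#' @return Signed area in px^2.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

#' Check contour vertices against an image shape
#'
#' @param contour A [contour()].
#' @param shape `c(rows, cols)` of the image the contour attaches to.
#' @return Invisibly `TRUE`; errors if any vertex falls outside `[0, cols] x
#'   [0, rows]`.
#' @export
validate_contour_bounds <- function(contour, shape) {
  v <- contour$vertices
  if (any(v[, 1L] < 0 | v[, 1L] > shape[2L] | v[, 2L] < 0 | v[, 2L] > shape[1L]))
    stop("contour '", contour$label, "' has vertices outside image bounds ",
         shape[1L], " x ", shape[2L], call. = FALSE)
  invisible(TRUE)
}

# ---- volume I/O --------------------------------------------------------------

#' Read a volume from disk
#'
#' Supported formats: a NIfTI file (`.nii` / `.nii.gz`) or a directory of
#' same-sized grayscale PNG/TIFF slices ordered by file name. In NIfTI files
#' the first dimension is x (columns) and the second y (rows); spacing
#' metadata is taken from the header and defaults to 1.0 when absent.
#'
#' @param path File or directory path.
#' @param format One of `"auto"`, `"nifti"`, `"slice_dir"`, `"dicom_dir"`.
#'   `"auto"` infers from the path. DICOM series are not supported by this
#'   build and raise an error.
#' @return A [volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "slice_dir", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "slice_dir"
              else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
              else stop("cannot infer volume format from path: ", path, call. = FALSE)
  }
  switch(format,
    nifti = {
      if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
      img <- RNifti::readNifti(path)
      a <- as.array(img)
      if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
      if (length(dim(a)) != 3L)
        stop("expected a 3D NIfTI volume, got ", length(dim(a)), " dimensions",
             call. = FALSE)
      pd <- RNifti::pixdim(img)
      slices <- lapply(seq_len(dim(a)[3L]), function(k) t(a[, , k]))
      volume(slices,
             slice_thickness = if (length(pd) >= 3 && pd[3] > 0) pd[3] else 1,
             pixel_spacing = if (length(pd) >= 1 && pd[1] > 0) pd[1] else 1)
    },
    slice_dir = {
      if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
      files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (!length(files)) stop("no PNG/TIFF slices in ", path, call. = FALSE)
      slices <- lapply(files, read_slice_image)
      volume(slices)
    },
    dicom_dir = stop("DICOM series input is not supported by this build; ",
                     "convert to NIfTI or a PNG/TIFF slice directory",
                     call. = FALSE)
  )
}

read_slice_image <- function(file) {
  a <- if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
       else tiff::readTIFF(file)
  if (length(dim(a)) == 3L) a <- a[, , 1L]   # take first channel
  a
}

#' Write a volume to disk
#'
#' @param vol A [volume()].
#' @param path Output `.nii`/`.nii.gz` file (format `"nifti"`) or directory
#'   (format `"slice_dir"`, 16-bit PNGs normalized to the volume's intensity
#'   range).
#' @param format `"nifti"` or `"slice_dir"`.
#' @return Invisibly `path`.
#' @export
save_volume <- function(vol, path, format = c("nifti", "slice_dir")) {
  format <- match.arg(format)
  if (format == "nifti") {
    shp <- slice_shape(vol)
    a <- array(0, c(shp[2L], shp[1L], n_slices(vol)))
    for (k in seq_len(n_slices(vol))) a[, , k] <- t(vol$slices[[k]]$pixels)
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- c(vol$pixel_spacing, vol$pixel_spacing,
                             vol$slice_thickness)
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    rng <- range(vapply(vol$slices, function(s) range(s$pixels),
                        numeric(2L)))
    span <- if (diff(rng) > 0) diff(rng) else 1
    for (k in seq_len(n_slices(vol))) {
      p <- (vol$slices[[k]]$pixels - rng[1L]) / span
      png::writePNG(p, file.path(path, sprintf("slice_%04d.png", k - 1L)),
                    dpi = NULL)
    }
  }
  invisible(path)
}

# ---- contour I/O -------------------------------------------------------------

#' Read / write a contour as JSON
#'
#' The native contour format is a JSON object with fields `label`,
#' `slice_index`, and `vertices` (an array of `[x, y]` pairs). Round-trips
#' preserve vertex coordinates exactly (full double precision).
#'
#' @param path JSON file path.
#' @return [load_contour()] returns a [contour()]; [save_contour()] returns
#'   its `path`, invisibly.
#' @export
load_contour <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$vertices))
    stop("contour JSON lacks a 'vertices' field: ", path, call. = FALSE)
  contour(doc$vertices,
          slice_index = if (is.null(doc$slice_index)) 0L else doc$slice_index,
          label = if (is.null(doc$label)) "structure" else doc$label)
}

#' @rdname load_contour
#' @param contour A [contour()] to serialize.
#' @export
save_contour <- function(contour, path) {
  doc <- list(label = contour$label,
              slice_index = contour$slice_index,
              vertices = contour$vertices)
  # I(17) significant digits makes the double round-trip bit-exact
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

# ---- rasterization -----------------------------------------------------------

#' Rasterize a closed contour to a boolean mask
#'
#' A pixel belongs to the mask iff its center (c + 0.5, r + 0.5) lies inside
#' the closed polygon under the even-odd rule, computed by horizontal
#' scanline crossing counts. A degenerate (zero-area) polygon yields an empty
#' mask with a warning.
#'
#' @param contour A [contour()] (vertices may lie anywhere in `[0, cols] x
#'   [0, rows]`).
#' @param shape `c(rows, cols)` of the target mask.
#' @return A logical rows x cols matrix.
#' @export
rasterize_contour <- function(contour, shape) {
  v <- if (inherits(contour, "contour")) contour$vertices else as.matrix(contour)
  rows <- as.integer(shape[1L]); cols <- as.integer(shape[2L])
  if (any(v[, 1L] < 0 | v[, 1L] > cols | v[, 2L] < 0 | v[, 2L] > rows))
    stop("contour has vertices outside image bounds ", rows, " x ", cols,
         call. = FALSE)
  mask <- matrix(FALSE, rows, cols)
  if (abs(polygon_area(v)) < .Machine$double.eps * max(1, max(abs(v)))^2) {
    warning("degenerate (zero-area) contour rasterizes to an empty mask")
    return(mask)
  }
  n <- nrow(v)
  j <- c(seq_len(n)[-1L], 1L)
  x1 <- v[, 1L]; y1 <- v[, 2L]; x2 <- v[j, 1L]; y2 <- v[j, 2L]
  keep <- y1 != y2
  xc <- seq_len(cols) - 0.5
  for (r in seq_len(rows)) {
    yc <- r - 0.5
    hit <- keep & (pmin(y1, y2) <= yc) & (yc < pmax(y1, y2))
    if (!any(hit)) next
    xs <- x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    mask[r, ] <- (findInterval(xc, sort(xs)) %% 2L) == 1L
  }
  mask
}

#' Write a boolean mask as a PNG (0 / 255)
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
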