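#' Construct a volume from a 3-D intensity array
#'
#' A `svf_volume` is the carrier of all filtering in the package: a 3-D grid
#' of finite intensities on the 8-bit scale `[0, 255]` plus a per-axis
#' physical voxel spacing.
#'
#' @section Coordinate convention:
#' Voxel centers sit at integer, 0-based coordinates `(x, y, z)` with
#' `x` varying fastest within a slice and `z` the slice index; the voxel at
#' `(x, y, z)` is the array element `data[x + 1, y + 1, z + 1]`. All point
#' coordinates in the package (seeds, snake nodes, centerlines, SWC before
#' spacing is applied) use this convention. Samples taken between voxel
#' centers are trilinear; samples outside the volume read as 0.
#'
#' @param data numeric 3-D array, all values finite and in `[0, 255]`.
#' @param spacing numeric length-3, physical size of a voxel per axis.
#' @return An object of class `svf_volume` with fields `data` and `spacing`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  if (min(data) < 0 || max(data) > 255)
    stop("volume intensities must lie in [0, 255]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  structure(list(data = data, spacing = spacing), class = "svf_volume")
}

#' @export
print.svf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<svf_volume> %d x %d x %d voxels, intensity [%.2f, %.2f], spacing (%g, %g, %g)\n",
              d[1], d[2], d[3], min(x$data), max(x$data),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Volume dimensions
#' @param volume an `svf_volume`.
#' @return Integer vector `(nx, ny, nz)`.
#' @export
vol_shape <- function(volume) dim(volume$data)

is_volume <- function(x) inherits(x, "svf_volume")

assert_volume <- function(x) {
  if (!is_volume(x)) stop("expected an `svf_volume` (see `as_volume()`)")
  invisible(x)
}

#' Load an image stack as a volume
#'
#' Reads a multi-page TIFF, or a directory of equally sized single-page 2-D
#' TIFF slices (sorted by file name), into an [as_volume()] object. The slice
#' page index becomes the z axis. 8-bit data is kept as-is; 16-bit data is
#' linearly rescaled so 65535 maps to 255; 32-bit float data is taken
#' verbatim and must already be in `[0, 255]`.
#'
#' @param path a TIFF file or a directory of TIFF slices.
#' @param spacing voxel spacing recorded on the volume (default isotropic 1).
#' @return An `svf_volume`.
#' @export
load_stack <- function(path, spacing = c(1, 1, 1)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) stop("no TIFF slices found in directory: ", path)
    pages <- unlist(lapply(files, read_tiff), recursive = FALSE)
  } else if (file.exists(path)) {
    pages <- read_tiff(path)
  } else {
    stop("no such file or directory: ", path)
  }
  shapes <- vapply(pages, function(p) dim(p$data), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes across pages")
  nx <- shapes[1, 1]; ny <- shapes[2, 1]; nz <- length(pages)
  data <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) {
    p <- pages[[z]]
    m <- p$data
    if (p$bits == 16L) m <- m * (255 / 65535)
    data[, , z] <- m
  }
  as_volume(data, spacing = spacing)
}

#' Save a volume as a multi-page TIFF stack
#'
#' With `bits = 8` (default) intensities are rounded to the nearest 8-bit
#' level, so a save/load round trip reproduces them within 0.5. `bits = 16`
#' rescales `[0, 255]` onto `[0, 65535]`; `bits = 32` stores float values
#' verbatim (used for filter-response volumes).
#'
#' @param volume an `svf_volume`.
#' @param path output file path.
#' @param bits 8, 16 or 32.
#' @return `path`, invisibly.
#' @export
save_stack <- function(volume, path, bits = 8L) {
  assert_volume(volume)
  bits <- as.integer(bits)
  data <- volume$data
  if (bits == 8L) {
    data <- pmin(pmax(data, 0), 255)
  } else if (bits == 16L) {
    data <- pmin(pmax(data, 0), 255) * (65535 / 255)
  } else if (bits != 32L) {
    stop("`bits` must be 8, 16 or 32")
  }
  write_tiff(data, path, bits = bits)
  invisible(path)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)
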