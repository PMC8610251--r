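#' Image containers
#'
#' Images are plain numeric arrays carrying physical calibration as
#' attributes. A [volumetric_image()] is a single-channel 3D stack stored as
#' an array with `dim = c(ny, nx, nz)`; a [time_lapse()] is an ordered set of
#' 2D frames stored as `dim = c(ny, nx, n_frames)`. Throughout the package
#' the x axis runs along array columns and y along rows; the centre of pixel
#' `(i, j)` (1-based) sits at `((j - 0.5) * pixel_size, (i - 0.5) *
#' pixel_size)` micrometres from the image corner, which pins down all
#' sub-pixel coordinates used by the ground-truth recovery machinery.
#'
#' @param data numeric array, `c(ny, nx, nz)` for stacks, `c(ny, nx)` or
#'   `c(ny, nx, n_frames)` for 2D images and movies.
#' @param voxel_size numeric length-3, physical voxel edge lengths
#'   `(x, y, z)` in micrometres.
#' @param channel_name optional channel label.
#' @return The array with class `volumetric_image` (or `time_lapse`) and
#'   calibration attributes.
#' @name image-containers
NULL

#' @rdname image-containers
#' @export
volumetric_image <- function(data, voxel_size, channel_name = "channel") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- c(voxel_size, voxel_size, voxel_size)
  if (any(voxel_size <= 0)) abort("voxel_size components must be > 0")
  structure(data,
    voxel_size = voxel_size, channel_name = channel_name,
    class = c("volumetric_image", "array")
  )
}

#' @rdname image-containers
#' @param frame_interval seconds between consecutive frames.
#' @param pixel_size micrometres per pixel (square pixels).
#' @export
time_lapse <- function(data, frame_interval, pixel_size) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] < 2L) abort("a time lapse needs at least 2 frames")
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  structure(data,
    frame_interval = frame_interval, pixel_size = pixel_size,
    class = c("time_lapse", "array")
  )
}

voxel_size <- function(image) attr(image, "voxel_size")

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x); vs <- voxel_size(x)
  cat(sprintf(
    "<volumetric_image> %s: %d x %d x %d voxels, %.3g x %.3g x %.3g um\n",
    attr(x, "channel_name"), d[1], d[2], d[3], vs[1], vs[2], vs[3]
  ))
  invisible(x)
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<time_lapse> %d frames of %d x %d px, dt = %g s, %g um/px\n",
    d[3], d[1], d[2], attr(x, "frame_interval"), attr(x, "pixel_size")
  ))
  invisible(x)
}

#' Read and write calibrated TIFF stacks
#'
#' Multi-plane images are written as multi-page 32-bit float TIFF
#' (ImageJ-compatible page order: z or t varies along pages), one file per
#' channel. Intensities are stored scaled by 1/65535 to fit the float TIFF
#' (0, 1) convention and rescaled on read.
#'
#' @param image a `volumetric_image`, `time_lapse`, or plain array.
#' @param path output file.
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   returns a numeric array `c(ny, nx, n_pages)`.
#' @export
write_image_tiff <- function(image, path) {
  arr <- unclass(image)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) {
    pmin(pmax(arr[, , k] / 65535, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1] # collapse grey-written-as-RGB
    arr[, , k] <- pg * 65535
  }
  arr
}

# mean of pixel values selected by a logical mask (same shape as image)
masked_mean <- function(image, mask) {
  mean(as.numeric(image)[as.logical(mask)])
}
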