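#' Calibrated microscopy image
#'
#' A thin container pairing a pixel array with its spatial calibration and,
#' for multi-channel images, a map from channel role to array slice. All
#' measurement functions in the package take and return physical units
#' (micrometres, square micrometres, counts per square millimetre); the
#' calibration travels with the pixels so unit bookkeeping cannot drift.
#'
#' @param data A numeric matrix (single channel) or a 3-D array
#'   `rows x cols x channels` with intensities in `[0, 1]`.
#' @param pixel_size_um Pixel edge length in micrometres per pixel.
#' @param channels Optional named integer vector mapping channel roles
#'   (e.g. `c(laminin = 1, nuclei = 2, cd68 = 3)`) to slices of `data`.
#'
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(data, pixel_size_um, channels = NULL) {
  if (!(is.matrix(data) || (is.array(data) && length(dim(data)) == 3L))) {
    stop_dmq("dmq_domain_error", "`data` must be a matrix or rows x cols x channels array")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = .Machine$double.eps)
  if (!is.null(channels)) {
    nch <- if (is.matrix(data)) 1L else dim(data)[3L]
    if (is.null(names(channels)) || any(channels < 1L) || any(channels > nch)) {
      stop_dmq("dmq_domain_error", "`channels` must be a named vector of valid slice indices")
    }
    channels <- vapply(channels, as.integer, integer(1))
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um, channels = channels),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_image> %d x %d px%s @ %.4g um/px (%.1f x %.1f um)\n",
    d[1], d[2],
    if (length(d) == 3L) sprintf(" x %d ch [%s]", d[3],
                                 paste(names(x$channels), collapse = ",")) else "",
    x$pixel_size_um, d[1] * x$pixel_size_um, d[2] * x$pixel_size_um
  ))
  invisible(x)
}

#' Extract one channel of a calibrated image by role
#'
#' @param image A `calibrated_image`.
#' @param role Channel role name (must be present in `image$channels`), or
#'   `NULL` for a single-channel image.
#' @return A single-channel `calibrated_image`.
#' @export
get_channel <- function(image, role = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.matrix(image$data)) {
    if (!is.null(role) && !is.null(image$channels) && !role %in% names(image$channels)) {
      stop_dmq("dmq_domain_error", "channel role '%s' not present", role)
    }
    return(calibrated_image(image$data, image$pixel_size_um))
  }
  if (is.null(role) || is.null(image$channels) || !role %in% names(image$channels)) {
    stop_dmq("dmq_domain_error", "channel role '%s' not present in channel map", role %||% "<null>")
  }
  calibrated_image(image$data[, , image$channels[[role]]], image$pixel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a calibrated TIFF image
#'
#' Reads a single- or multi-channel TIFF; calibration is supplied by the
#' caller (TIFF resolution tags from microscope exports are unreliable).
#'
#' @inheritParams calibrated_image
#' @param path Path to a TIFF file.
#' @return A `calibrated_image`.
#' @export
read_calibrated_tiff <- function(path, pixel_size_um, channels = NULL) {
  arr <- tiff::readTIFF(path)
  calibrated_image(arr, pixel_size_um, channels)
}

#' Write a calibrated image to TIFF (32-bit float)
#'
#' Intensities are clipped to `[0, 1]`. A 3-channel image is written as one
#' RGB-style TIFF; the channel-role map is the caller's to persist (the
#' synthetic generators write it into the ground-truth JSON sidecar).
#'
#' @param image A `calibrated_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  d <- pmin(pmax(image$data, 0), 1)
  tiff::writeTIFF(d, path, bits.per.sample = 32L)
  invisible(path)
}
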