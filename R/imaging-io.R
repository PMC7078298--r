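#' Calibrated multi-plane, multi-channel image stack
#'
#' An `image_stack` holds the pixel data of one microscope field: one 3-D
#' array per channel (dimensions z, y, x), plus the spatial calibration
#' needed to convert pixel measurements to micrometres. Channels are named;
#' the conventional names are `"iba1"` (red, microglial marker) and
#' `"p2ry12"` (green, resident-microglia marker).
#'
#' @param channels Named list of 3-D numeric arrays, all with identical
#'   `dim` of the form `c(z, y, x)`. A 2-D matrix is promoted to a
#'   single-plane stack.
#' @param pixel_size_um Isotropic x/y pixel size in micrometres (> 0).
#' @param z_step_um Distance between consecutive z planes in micrometres
#'   (> 0). Whole-mount time-course acquisitions typically scan every 2 um.
#' @param bit_depth Either 8 or 16; pixel values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param id Optional identifier carried into provenance records.
#'
#' @return An object of class `image_stack`.
#' @seealso [read_stack()], [max_project()]
#' @export
image_stack <- function(channels, pixel_size_um, z_step_um = 2,
                        bit_depth = 8, id = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a named list of arrays.")
  }
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(1L, dim(a)))
    if (length(dim(a)) != 3L) abort("each channel must be a (z, y, x) array")
    a
  })
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) abort("all channels must share one shape")
  stopifnot(pixel_size_um > 0, z_step_um > 0, bit_depth %in% c(8L, 16L))
  vmax <- 2^bit_depth - 1
  for (a in channels) {
    if (min(a) < 0 || max(a) > vmax) {
      abort(sprintf("pixel values outside [0, %d] for bit depth %d",
                    vmax, bit_depth))
    }
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, bit_depth = as.integer(bit_depth),
         id = id %||% "stack"),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<image_stack '%s'> %d plane(s) of %d x %d px, channels: %s\n",
    x$id, d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size %.4g um, z step %.3g um, %d-bit\n",
              x$pixel_size_um, x$z_step_um, x$bit_depth))
  invisible(x)
}

#' Single-channel 2-D field image
#'
#' A `field_image` is one calibrated 2-D image: either a projection of an
#' [image_stack()] or a directly acquired single plane (e.g. the OPL-OS
#' interface plane used for vertical-process counting). Pixel (r, c) is
#' taken to be centred at `((r-1) * pixel_size_um, (c-1) * pixel_size_um)`
#' so that pixel coordinates are zero-based at pixel centres; this
#' convention is shared by the synthetic renderer and every measurement,
#' which makes planted and measured coordinates directly comparable.
#'
#' @param pixels Numeric matrix (y, x) of non-negative values.
#' @param pixel_size_um Pixel size in micrometres.
#' @param channel Channel name the pixels came from.
#' @param provenance Free-form string recording how the image was produced.
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_um, channel = "iba1",
                        provenance = "direct") {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  if (min(pixels) < 0) abort("field_image pixels must be non-negative")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = channel, provenance = provenance),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> %d x %d px (%.1f x %.1f um), channel %s, %s\n",
    nrow(x$pixels), ncol(x$pixels),
    nrow(x$pixels) * x$pixel_size_um, ncol(x$pixels) * x$pixel_size_um,
    x$channel, x$provenance))
  invisible(x)
}

#' Field area in mm^2
#'
#' @param img A [field_image()].
#' @return Scalar area in mm^2 (`height * width * pixel_size^2 / 1e6`).
#' @export
field_area_mm2 <- function(img) {
  stopifnot(inherits(img, "field_image"))
  nrow(img$pixels) * ncol(img$pixels) * img$pixel_size_um^2 / 1e6
}

#' Read a calibrated TIFF z-stack
#'
#' Reads a multi-page TIFF into an [image_stack()]. Pages are interpreted
#' as z-major, channel-minor: with `k` channels, page `(z-1)*k + c` holds
#' plane `z` of channel `channel_order[c]` (the layout [write_stack()]
#' produces). Calibration is not read from TIFF tags; it must be supplied,
#' mirroring configuration-driven pipelines where the acquisition settings
#' are known.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um,z_step_um Spatial calibration in micrometres.
#' @param channel_order Character vector naming the channels in page order,
#'   e.g. `c("iba1", "p2ry12")` for red-then-green.
#' @param bit_depth 8 or 16.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um, z_step_um = 2,
                       channel_order = "iba1", bit_depth = 8) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  k <- length(channel_order)
  if (length(pages) %% k != 0L) {
    abort(sprintf("%d TIFF pages are not divisible by %d channels",
                  length(pages), k))
  }
  nz <- length(pages) %/% k
  d <- dim(pages[[1]])
  channels <- lapply(seq_len(k), function(ci) {
    a <- array(0, dim = c(nz, d[1], d[2]))
    for (z in seq_len(nz)) a[z, , ] <- pages[[(z - 1L) * k + ci]]
    a
  })
  names(channels) <- channel_order
  image_stack(channels, pixel_size_um = pixel_size_um,
              z_step_um = z_step_um, bit_depth = bit_depth,
              id = basename(path))
}

#' Write an image stack to a multi-page TIFF
#'
#' Inverse of [read_stack()]: pages are written z-major, channel-minor.
#' Pixel values are stored at the stack's bit depth, so a round trip
#' preserves integer pixel content exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vmax <- 2^stack$bit_depth - 1
  nz <- dim(stack$channels[[1]])[1]
  pages <- list()
  for (z in seq_len(nz)) {
    for (ch in names(stack$channels)) {
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][z, , ] / vmax
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  invisible(path)
}

#' Project a stack channel to a single field image
#'
#' Maximum-intensity projection (the default, appropriate for sparse
#' bright structures such as immunolabelled microglia) or mean projection
#' over z of one channel.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name to project.
#' @param method `"max"` (default) or `"mean"`.
#' @return A [field_image()] with provenance recording the method.
#' @export
max_project <- function(stack, channel = "iba1", method = c("max", "mean")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("channel '%s' not in stack (has: %s)", channel,
                  paste(names(stack$channels), collapse = ", ")))
  }
  a <- stack$channels[[channel]]
  planes <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
  px <- if (method == "max") {
    do.call(pmax, planes)
  } else {
    Reduce(`+`, planes) / length(planes)
  }
  field_image(px, pixel_size_um = stack$pixel_size_um, channel = channel,
              provenance = sprintf("%s-projection of %s", method, stack$id))
}
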