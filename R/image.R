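#' Construct a stimulus image
#'
#' A stimulus image is an 8-bit RGB raster: an `H x W x 3` integer array with
#' intensities in `[0, 255]`, plus a string id. This is the common currency of
#' the feature-extraction pipeline.
#'
#' @param pixels numeric `H x W x 3` array, intensities in `[0, 255]`.
#' @param id character label for the image.
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(pixels, id = "img") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array (8-bit RGB)")
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L)
    stop("image must be at least 8 x 8 pixels")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(pixels = array(as.integer(px), dim(px)), id = as.character(id)),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stimulus_image '%s': %d x %d, 8-bit RGB>\n", x$id, d[1], d[2]))
  invisible(x)
}

#' Read an image file as a stimulus image
#'
#' Reads PNG or JPEG files (by extension) and converts to 8-bit RGB.
#' Grayscale images are replicated across channels; an alpha channel is
#' dropped.
#'
#' @param path file path to a `.png`, `.jpg` or `.jpeg` image.
#' @param id image id; defaults to the file name without extension.
#' @return A [stimulus_image()].
#' @export
read_stimulus <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (PNG and JPEG are supported)"))
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  nc <- dim(arr)[3]
  rgb <- if (nc == 1L) arr[, , c(1, 1, 1)] else arr[, , 1:3, drop = FALSE]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  stimulus_image(round(rgb * 255), id = id)
}

#' Write a stimulus image as a lossless PNG
#'
#' @param img a [stimulus_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(img, path) {
  stopifnot(inherits(img, "stimulus_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' Construct a channel plane
#'
#' An `H x W` matrix of reals in `[0, 1]` tagged with its channel of
#' origin; the unit every feature metric operates on. Usually produced by
#' [rgb_to_hsv_planes()] or [apply_edge_filter()], but can be built
#' directly for synthetic planes.
#'
#' @param values numeric matrix with values in `[0, 1]`.
#' @param channel channel tag (`"H"`, `"S"`, `"V"`, `"H+CS"`, or a free
#'   label for synthetic planes).
#' @return A `channel_plane` object.
#' @export
channel_plane <- function(values, channel = "V") {
  stopifnot(is.matrix(values), min(values) >= 0, max(values) <= 1)
  structure(list(values = values, channel = channel), class = "channel_plane")
}

#' @export
print.channel_plane <- function(x, ...) {
  cat(sprintf("<channel_plane %s: %d x %d, range [%.3f, %.3f]>\n",
              x$channel, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Decompose an RGB stimulus into HSV channel planes
#'
#' Converts 8-bit RGB pixels to the hue/saturation/value colour model. Each
#' plane is an `H x W` matrix of reals in `[0, 1]`. Hue is treated as an
#' ordinary linear channel in `[0, 1]` (no circular statistics); this is a
#' deliberate, documented simplification.
#'
#' @param img a [stimulus_image()].
#' @return Named list with elements `H`, `S`, `V`, each a `channel_plane`.
#' @export
rgb_to_hsv_planes <- function(img) {
  stopifnot(inherits(img, "stimulus_image"))
  d <- dim(img$pixels)
  r <- as.vector(img$pixels[, , 1])
  g <- as.vector(img$pixels[, , 2])
  b <- as.vector(img$pixels[, , 3])
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
  mk <- function(row, tag)
    channel_plane(matrix(hsv[row, ], d[1], d[2]), tag)
  list(H = mk(1, "H"), S = mk(2, "S"), V = mk(3, "V"))
}

## Composite plane used by the "H+CS" registry alias: mean of the hue plane
## and a contrast-stretched saturation plane. The composite is a documented
## registry choice, not a standard colour channel.
composite_hcs_plane <- function(planes) {
  s <- planes$S$values
  rng <- range(s)
  cs <- if (diff(rng) < .Machine$double.eps) s * 0 else (s - rng[1]) / diff(rng)
  channel_plane((planes$H$values + cs) / 2, "H+CS")
}
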