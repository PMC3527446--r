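#' Two-dimensional intensity channel
#'
#' A `channel_image` is the basic container for one fluorescence channel:
#' a numeric matrix of non-negative intensities together with its bit depth,
#' physical pixel size and channel role. `max_intensity` records the current
#' working intensity ceiling; it starts at `2^bit_depth - 1` and is lowered
#' by [clip_intensity()] so downstream operators (contrast stretch, elevation
#' building) know the active dynamic range.
#'
#' @param pixels numeric matrix of intensities, all in
#'   `[0, 2^bit_depth - 1]`. Rows are image rows (y), columns are x.
#' @param bit_depth integer, 8 or 16.
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param role one of `"nuclear"`, `"foci"`, `"object"`.
#' @param max_intensity working intensity ceiling; defaults to the bit-depth
#'   maximum.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, bit_depth = 16L, pixel_size_um = 0.2,
                          role = c("nuclear", "foci", "object"),
                          max_intensity = 2^bit_depth - 1) {
  role <- match.arg(role)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixels must be finite and non-negative")
  if (any(pixels > 2^bit_depth - 1))
    stop("pixel intensities exceed the bit-depth maximum")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um, role = role,
         max_intensity = max_intensity),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %dx%d px, %d-bit, %.3g um/px, role=%s, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
              x$role, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

# internal: clone with new pixels
replace_pixels <- function(img, pixels, max_intensity = img$max_intensity) {
  img$pixels <- pixels
  img$max_intensity <- max_intensity
  img
}

#' Bundle the channels of one imaged field
#'
#' @param nuclear,foci `channel_image` objects sharing dimensions and pixel
#'   size; `object` is an optional third channel (e.g. synapses).
#' @param field_id identifier of the field of view.
#' @param well_id optional well identifier for screening mode.
#' @return an object of class `image_set`.
#' @export
image_set <- function(nuclear, foci, object = NULL,
                      field_id = "field", well_id = NA_character_) {
  stopifnot(inherits(nuclear, "channel_image"), inherits(foci, "channel_image"))
  chans <- list(nuclear = nuclear, foci = foci)
  if (!is.null(object)) chans$object <- object
  dims <- vapply(chans, function(ch) dim(ch$pixels), integer(2))
  if (any(dims != dims[, 1])) stop("all channels must share dimensions")
  ps <- vapply(chans, function(ch) ch$pixel_size_um, numeric(1))
  if (max(ps) - min(ps) > 1e-9) stop("all channels must share pixel_size_um")
  structure(list(nuclear = nuclear, foci = foci, object = object,
                 field_id = field_id, well_id = well_id),
            class = "image_set")
}
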