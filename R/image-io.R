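#' Read one grayscale TIFF plane as a channel
#'
#' Reads a single-plane grayscale TIFF (Zeiss LSM pages are a TIFF dialect)
#' as raw integer intensities, with no rescaling. Multi-page files are
#' addressed by `page`.
#'
#' @param path path to an 8- or 16-bit grayscale TIFF.
#' @param role channel role, see [channel_image()].
#' @param pixel_size_um physical pixel size in micrometres; the TIFF tags of
#'   exported confocal planes rarely carry a trustworthy value, so it is
#'   supplied explicitly.
#' @param page 1-based page index for multi-page files.
#' @return a [channel_image()].
#' @export
load_channel <- function(path, role = c("nuclear", "foci", "object"),
                         pixel_size_um = 0.2, page = 1L) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("cannot read image file: ", path)
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")"))
  if (page < 1L || page > length(planes))
    stop("page ", page, " not present in ", path)
  px <- planes[[page]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    else stop("not a single-plane grayscale image: ", path)
  }
  if (length(dim(px)) != 2L) stop("not a 2-D image plane: ", path)
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) stop("unsupported sample depth (", bits, "-bit): ", path)
  channel_image(px, bit_depth = as.integer(bits),
                pixel_size_um = pixel_size_um, role = role)
}

#' Write a channel as TIFF (for audit of intermediates)
#'
#' @param img a [channel_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(img, path) {
  top <- 2^img$bit_depth - 1
  tiff::writeTIFF(pmin(pmax(img$pixels, 0), top) / top, path,
                  bits.per.sample = img$bit_depth)
  invisible(path)
}

#' Clip intensities to a cap
#'
#' High-intensity outliers (typically far below 0.1% of pixels in either
#' channel) are clipped to `cap` so that both channels work on a common
#' dynamic range. The fraction of clipped pixels is reported via message
#' so a data set where the constant is inappropriate is visible in the log.
#'
#' @param img a [channel_image()].
#' @param cap intensity ceiling; default 255.
#' @param quiet suppress the clipped-fraction message.
#' @return the clipped channel, with `max_intensity` lowered to `cap`.
#' @export
clip_intensity <- function(img, cap = 255, quiet = FALSE) {
  stopifnot(inherits(img, "channel_image"), cap > 0)
  frac <- mean(img$pixels > cap)
  if (!quiet && frac > 0)
    message(sprintf("clip_intensity: %.3g%% of %s pixels above cap %g",
                    100 * frac, img$role, cap))
  replace_pixels(img, pmin(img$pixels, cap),
                 max_intensity = min(cap, img$max_intensity))
}

#' Linear contrast stretch between intensity quantiles
#'
#' Remaps the `[low_frac, high_frac]` intensity quantiles linearly onto
#' `[0, max_intensity]`, clamping values outside. A constant image is
#' returned unchanged with a message.
#'
#' @param img a [channel_image()].
#' @param low_frac,high_frac quantile bounds, `0 <= low_frac < high_frac <= 1`.
#' @return the stretched channel.
#' @export
contrast_stretch <- function(img, low_frac = 0.01, high_frac = 0.99) {
  stopifnot(inherits(img, "channel_image"),
            low_frac >= 0, high_frac <= 1, low_frac < high_frac)
  qs <- stats::quantile(img$pixels, c(low_frac, high_frac), names = FALSE)
  if (qs[2] <= qs[1]) {
    message("contrast_stretch: constant image, returned unchanged")
    return(img)
  }
  out <- (img$pixels - qs[1]) / (qs[2] - qs[1])
  out <- pmin(pmax(out, 0), 1) * img$max_intensity
  replace_pixels(img, out)
}

# internal: local box mean via FFT filtering with replicated borders
box_mean <- function(x, window) {
  k <- matrix(1 / (window * window), window, window)
  EBImage::filter2(x, k, boundary = "replicate")
}

#' Adaptive Wiener denoising
#'
#' Local adaptive noise removal: with local window mean `mu` and variance
#' `s2`, and `nu` the mean of the local variances (the noise estimate),
#' `out = mu + max(s2 - nu, 0) / max(s2, nu) * (in - mu)`. Flat regions are
#' smoothed towards the local mean; structured regions are preserved.
#'
#' @param img a [channel_image()].
#' @param window odd window side >= 3; default 3.
#' @return the denoised channel.
#' @export
wiener_denoise <- function(img, window = 3L) {
  stopifnot(inherits(img, "channel_image"), window >= 3L, window %% 2L == 1L)
  x <- img$pixels
  mu <- box_mean(x, window)
  s2 <- pmax(box_mean(x * x, window) - mu * mu, 0)
  nu <- mean(s2)
  out <- mu + pmax(s2 - nu, 0) / pmax(s2, nu) * (x - mu)
  out[s2 == 0 & nu == 0] <- mu[s2 == 0 & nu == 0]
  replace_pixels(img, pmin(pmax(out, 0), img$max_intensity))
}

#' The 3x3 unsharp kernel
#'
#' `1/(alpha+1) * [[-a, a-1, -a], [a-1, a+5, a-1], [-a, a-1, -a]]`; sums to 1,
#' so constant regions are untouched while small bright structure is amplified.
#' @param alpha sharpening shape parameter in `[0, 1]`.
#' @return a 3x3 numeric matrix.
#' @export
unsharp_kernel <- function(alpha = 0.2) {
  stopifnot(alpha >= 0, alpha <= 1)
  matrix(c(-alpha, alpha - 1, -alpha,
           alpha - 1, alpha + 5, alpha - 1,
           -alpha, alpha - 1, -alpha), 3, 3) / (alpha + 1)
}

#' Unsharp sharpening filter
#'
#' Convolution with [unsharp_kernel()], replicate border handling, output
#' clamped to the valid intensity range. Used as the second correlation pass
#' so faint or blurry foci cross their similarity thresholds.
#'
#' @param img a [channel_image()].
#' @param alpha kernel parameter in `[0, 1]`; default 0.2.
#' @return the sharpened channel.
#' @export
unsharp_filter <- function(img, alpha = 0.2) {
  stopifnot(inherits(img, "channel_image"))
  out <- EBImage::filter2(img$pixels, unsharp_kernel(alpha), boundary = "replicate")
  replace_pixels(img, pmin(pmax(out, 0), img$max_intensity))
}

# Keys cubic interpolation kernel, a = -0.5
keys_cubic <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# 1-D cubic resampling weights along one axis, antialiased when shrinking
resample_1d <- function(n_in, n_out) {
  scale <- n_out / n_in
  # kernel widened by 1/scale when downscaling (antialiasing)
  kw <- if (scale < 1) 1 / scale else 1
  support <- 2 * kw
  u <- (seq_len(n_out) - 0.5) / scale + 0.5  # 1-based centre mapping
  lo <- floor(u - support) + 1
  hi <- ceiling(u + support) - 1
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    idx <- lo[i]:hi[i]
    w <- keys_cubic((u[i] - idx) / kw)
    idx <- pmin(pmax(idx, 1L), n_in)  # replicate border
    for (k in seq_along(idx)) W[i, idx[k]] <- W[i, idx[k]] + w[k]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Resize a channel to a target side
#'
#' Separable cubic (Keys, a = -0.5) resampling with antialiasing on
#' downscale. `pixel_size_um` is rescaled by the geometric factor so the
#' physical field size is preserved.
#'
#' @param img a square [channel_image()].
#' @param target_side output side in pixels (>= 64).
#' @return the resized channel.
#' @export
resize_image <- function(img, target_side = 512L) {
  stopifnot(inherits(img, "channel_image"), target_side >= 64L)
  n <- nrow(img$pixels)
  if (ncol(img$pixels) != n) stop("resize_image expects a square field")
  if (target_side == n) return(img)
  if (target_side > n) warning("upscaling requested; interpolating anyway")
  W <- resample_1d(n, target_side)
  out <- W %*% img$pixels %*% t(W)
  out <- pmin(pmax(out, 0), img$max_intensity)
  img$pixel_size_um <- img$pixel_size_um * n / target_side
  replace_pixels(img, out)
}
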