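#' The default prototype bank
#'
#' Eight prototypes extracted from a deterministic, noise-free synthetic
#' reference field, spanning the four recurring granule morphologies: round
#' of several sizes, elliptical in both orientations, and brighter-cored.
#' Each carries its own similarity threshold; the strictest thresholds sit
#' on the large, high-contrast morphologies and the laxest on the small
#' round one, whose correlations are most attenuated by noise.
#'
#' @param margin cytoplasm margin around each granule box, in pixels.
#' @param sigma_scale multiplies all prototype radii, mirroring prototype
#'   re-extraction at a higher magnification or resolution (default 1).
#' @param st_override single similarity threshold applied to every
#'   prototype (several applications of the method re-tune to one common
#'   ST, e.g. 0.8 for processing-body sizing); `NULL` keeps the per-slot
#'   defaults.
#' @param id_suffix appended to prototype ids (needed when two scaled banks
#'   are combined into one).
#' @return a [prototype_bank()] of 8 prototypes with ids `I`..`VIII`.
#' @export
default_prototype_bank <- function(margin = 3L, sigma_scale = 1,
                                   st_override = NULL, id_suffix = "") {
  # (sx, sy, core, profile) per morphology slot: round at three sizes, one
  # dense uniform-intensity body, two ellipse orientations, two bright-cored
  par <- list(
    I    = list(sx = 2.2, sy = 2.2, core = FALSE, profile = "gaussian", st = 0.89),
    II   = list(sx = 1.6, sy = 1.6, core = TRUE,  profile = "gaussian", st = 0.88),
    III  = list(sx = 1.2, sy = 1.2, core = FALSE, profile = "gaussian", st = 0.80),
    IV   = list(sx = 2.6, sy = 2.6, core = FALSE, profile = "gaussian", st = 0.88),
    V    = list(sx = 2.0, sy = 1.3, core = FALSE, profile = "gaussian", st = 0.86),
    VI   = list(sx = 1.3, sy = 2.0, core = FALSE, profile = "gaussian", st = 0.86),
    VII  = list(sx = 1.7, sy = 1.7, core = FALSE, profile = "gaussian", st = 0.92),
    VIII = list(sx = 2.0, sy = 2.0, core = FALSE, profile = "disk",     st = 0.85))
  for (i in seq_along(par)) {
    par[[i]]$sx <- par[[i]]$sx * sigma_scale
    par[[i]]$sy <- par[[i]]$sy * sigma_scale
    if (!is.null(st_override)) par[[i]]$st <- st_override
  }
  hmax <- max(vapply(par, function(p)
    ceiling(2.5 * max(p$sx, p$sy)) + margin, 0))
  pitch <- 2L * hmax + 5L
  ref <- matrix(30, 4L * pitch, 2L * pitch)  # flat cytoplasm-level reference
  centers <- expand.grid(row = pitch * (0:3) + pitch %/% 2L,
                         col = pitch * (0:1) + pitch %/% 2L)
  centers <- centers[order(centers$col, centers$row), ]
  protos <- vector("list", length(par))
  for (i in seq_along(par)) {
    p <- par[[i]]
    ref <- render_granule(ref, centers$row[i], centers$col[i],
                          p$sx, p$sy, 120, p$core, p$profile)
  }
  ref_img <- channel_image(ref, bit_depth = 8L, pixel_size_um = 0.2,
                           role = "foci", max_intensity = 255)
  for (i in seq_along(par)) {
    p <- par[[i]]
    box <- 2L * ceiling(2.5 * max(p$sx, p$sy)) + 1L
    protos[[i]] <- extract_prototype(
      ref_img, c(centers$row[i], centers$col[i]), granule_box = box,
      margin = margin, id = paste0(names(par)[i], id_suffix),
      similarity_threshold = p$st)
  }
  prototype_bank(protos)
}

#' A dense size ladder of round prototypes for size measurement
#'
#' Focus size is read off the merged-object pixel count, which tracks the
#' true object area only when some prototype closely matches the granule
#' scale: the supra-threshold correlation neighbourhood of a well-matched
#' template scales with the granule, while a mismatched one clips it. For
#' sizing runs this bank therefore covers `[sigma_min, sigma_max]` with a
#' geometric ladder of round Gaussian prototypes (step about 12%), each with
#' a margin proportional to its radius, all at one moderate similarity
#' threshold.
#'
#' @param sigma_min,sigma_max radius range to cover (px).
#' @param st common similarity threshold; default 0.6 (moderate, which
#'   keeps the supra-threshold area insensitive to small template
#'   mismatches).
#' @param step geometric step between consecutive ladder radii.
#' @return a [prototype_bank()].
#' @export
size_ladder_bank <- function(sigma_min, sigma_max, st = 0.6, step = 1.12) {
  stopifnot(sigma_min > 0, sigma_max > sigma_min, step > 1)
  sigmas <- sigma_min * step^(0:ceiling(log(sigma_max / sigma_min) / log(step)))
  protos <- lapply(seq_along(sigmas), function(i) {
    s <- sigmas[i]
    margin <- max(3L, ceiling(s))
    ext <- ceiling(2.5 * s)
    side <- 2L * (ext + margin) + 1L
    patch <- matrix(30, side, side)
    ctr <- ext + margin + 1L
    patch <- render_granule(patch, ctr, ctr, s, s, 120, FALSE)
    prototype(patch, id = paste0("L", i), similarity_threshold = st)
  })
  prototype_bank(protos)
}

#' Write a prototype bank to a directory
#'
#' One 8-bit TIFF per patch plus a `manifest.csv` with id, file, similarity
#' threshold and rotation.
#'
#' @param bank a [prototype_bank()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_prototype_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(bank$prototypes, function(p) {
    file <- paste0("prototype_", p$id, ".tif")
    top <- max(p$patch, 255)
    tiff::writeTIFF(round(p$patch) / top, file.path(dir, file),
                    bits.per.sample = 8L)
    data.frame(id = p$id, file = file,
               similarity_threshold = p$similarity_threshold,
               rotation_deg = p$rotation_deg)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a prototype bank from a directory
#'
#' @param dir directory containing `manifest.csv` and the patch TIFFs
#'   written by [write_prototype_bank()].
#' @return a [prototype_bank()].
#' @export
read_prototype_bank <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  protos <- lapply(seq_len(nrow(manifest)), function(i) {
    patch <- tiff::readTIFF(file.path(dir, manifest$file[i]), as.is = TRUE)
    prototype(patch, id = manifest$id[i],
              similarity_threshold = manifest$similarity_threshold[i],
              rotation_deg = manifest$rotation_deg[i])
  })
  prototype_bank(protos)
}
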