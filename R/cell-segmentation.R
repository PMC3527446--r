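#' Nuclear mask from the DAPI channel
#'
#' Thresholds the (already contrast-stretched) nuclear channel at
#' `threshold_frac` of its maximum: pixels at or above the threshold become
#' 1, others 0. Interior holes (nucleolar dark spots) are filled so each
#' connected component is one candidate nucleus marker.
#'
#' @param nuclear a [channel_image()] (clipped and contrast-stretched).
#' @param threshold_frac fraction of the maximum, in (0, 1); default 0.6.
#' @param absolute if `TRUE`, threshold against `max_intensity` instead of
#'   the observed maximum (useful for dim control fields).
#' @return integer 0/1 matrix of the same shape, with attribute
#'   `"empty"` set when no nucleus survives (the field should be skipped).
#' @export
make_nuclear_mask <- function(nuclear, threshold_frac = 0.6, absolute = FALSE) {
  stopifnot(inherits(nuclear, "channel_image"),
            threshold_frac > 0, threshold_frac < 1)
  top <- if (absolute) nuclear$max_intensity else max(nuclear$pixels)
  if (top <= 0) {
    warning("empty nuclear mask: nuclear channel is all zero")
    mask <- matrix(0L, nrow(nuclear$pixels), ncol(nuclear$pixels))
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  mask <- (nuclear$pixels >= threshold_frac * top) * 1L
  if (all(mask == 1L)) warning("nuclear mask covers the whole field (degenerate)")
  if (any(mask == 1L)) {
    mask <- EBImage::fillHull(mask)
    storage.mode(mask) <- "integer"
  } else {
    warning("empty nuclear mask: no nuclei detected in field")
    attr(mask, "empty") <- TRUE
    storage.mode(mask) <- "integer"
  }
  mask
}

#' Elevation surface for cell segmentation
#'
#' Complements the (denoised, gain-multiplied) foci channel so that brightly
#' stained cell material lies low and unstained background high, then forces
#' all nuclear pixels to 0 so nuclei are the global minima: the catchment
#' basin grown from each nucleus is the cell.
#'
#' @param foci a [channel_image()], typically clipped and Wiener-denoised.
#' @param nuc_mask 0/1 nuclear mask from [make_nuclear_mask()].
#' @param gain multiplier compensating faint cytoplasmic staining; default 2.
#' @return numeric elevation matrix (0 at nuclei, `max_intensity` at empty
#'   background).
#' @export
build_elevation <- function(foci, nuc_mask, gain = 2) {
  stopifnot(inherits(foci, "channel_image"), gain >= 1)
  if (!all(dim(nuc_mask) == dim(foci$pixels))) stop("mask/channel shapes differ")
  top <- foci$max_intensity
  elev <- top - pmin(gain * foci$pixels, top)
  elev[nuc_mask == 1L] <- 0
  elev
}

#' Partition a field into per-cell basins
#'
#' Marker-controlled watershed (Meyer flooding, topographic order,
#' 8-connectivity): each nucleus component is one marker, flooding climbs the
#' elevation surface, and pixels reached simultaneously from two basins form
#' the watershed ridge (label 0). The number of cell labels equals the number
#' of nucleus components and every basin contains its whole marker.
#'
#' @param elevation numeric matrix from [build_elevation()].
#' @param nuc_mask 0/1 nuclear mask.
#' @param pixel_size_um physical pixel size (um).
#' @return a `cell_label_map`: list with `labels` (integer matrix, 0 = ridge
#'   or excluded), `nuclei` (per-label data frame with nucleus centroids and
#'   border flag), `pixel_size_um`.
#' @export
segment_cells <- function(elevation, nuc_mask, pixel_size_um) {
  if (!any(nuc_mask == 1L)) stop("segment_cells needs at least one nucleus")
  markers <- label8_cpp(matrix(as.integer(nuc_mask), nrow(nuc_mask)))
  labels <- watershed_cpp(elevation, markers)
  k <- max(markers)
  cent <- centroids_by_label(markers, k)
  border <- vapply(seq_len(k), function(l) {
    any(labels[1, ] == l) || any(labels[nrow(labels), ] == l) ||
      any(labels[, 1] == l) || any(labels[, ncol(labels)] == l)
  }, logical(1))
  basin_px <- tabulate(labels[labels > 0L], nbins = k)
  nuclei <- data.frame(cell_id = seq_len(k),
                       nucleus_row = cent[, 1], nucleus_col = cent[, 2],
                       basin_px = basin_px,
                       basin_area_um2 = basin_px * pixel_size_um^2,
                       border_touching = border)
  structure(list(labels = labels, nuclei = nuclei,
                 pixel_size_um = pixel_size_um),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %dx%d px, %d cells, %.3g um/px\n",
              nrow(x$labels), ncol(x$labels), nrow(x$nuclei), x$pixel_size_um))
  invisible(x)
}

# internal: centroid (row, col) of every positive label
centroids_by_label <- function(labels, k) {
  pos <- which(labels > 0L)
  l <- labels[pos]
  r <- (pos - 1L) %% nrow(labels) + 1L
  cc <- (pos - 1L) %/% nrow(labels) + 1L
  n <- tabulate(l, nbins = k)
  cbind(row = rowsum(as.numeric(r), l)[, 1] / n,
        col = rowsum(as.numeric(cc), l)[, 1] / n)
}

#' Stained-material foreground mask
#'
#' Watershed basins tessellate the whole field, so "extracellular" needs its
#' own definition: pixels whose denoised foci-channel intensity reaches
#' `foreground_frac` of the image maximum are stained cell material;
#' the complement is extracellular. Specks smaller than `min_region_px` are
#' dropped and interior holes filled. `foreground_frac = 0` disables the
#' filter (everything is foreground).
#'
#' @param foci a [channel_image()], clipped and denoised but not
#'   contrast-stretched (stretching lifts dim background toward the
#'   threshold).
#' @param foreground_frac fraction of the image maximum in `[0, 1)`;
#'   default 0.05.
#' @param min_region_px smallest kept foreground component; default 25.
#' @return integer 0/1 matrix.
#' @export
cell_foreground <- function(foci, foreground_frac = 0.05, min_region_px = 25L) {
  stopifnot(inherits(foci, "channel_image"),
            foreground_frac >= 0, foreground_frac < 1)
  if (foreground_frac == 0)
    return(matrix(1L, nrow(foci$pixels), ncol(foci$pixels)))
  mask <- (foci$pixels >= foreground_frac * max(foci$pixels)) * 1L
  if (!any(mask == 1L)) return(mask)
  # opening breaks up the speckle mesh that contrast stretching lifts over
  # the threshold in noisy background before components are size-filtered
  mask <- EBImage::opening(mask, EBImage::makeBrush(3L, "box"))
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L)) return(mask)
  lab <- label8_cpp(matrix(as.integer(mask), nrow(mask)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_region_px)
  mask <- matrix(as.integer(lab %in% keep), nrow(mask))
  mask <- EBImage::fillHull(mask)
  storage.mode(mask) <- "integer"
  mask
}

#' Remove implausibly small cells
#'
#' Cells whose stained-foreground area (basin intersected with the
#' foreground mask) is below `min_cell_area_um2` - partially attached or
#' unhealthy cells - are excluded from all downstream statistics: their basin
#' pixels are set to 0 and their row dropped from the per-cell table.
#' Surviving labels keep their original ids.
#'
#' @param clm a `cell_label_map` from [segment_cells()].
#' @param min_cell_area_um2 area threshold in um^2; default 30.
#' @param foreground optional 0/1 mask from [cell_foreground()]; if `NULL`,
#'   the full basin area is used.
#' @return the filtered `cell_label_map`, with `cell_area_um2` recorded.
#' @export
filter_small_cells <- function(clm, min_cell_area_um2 = 30, foreground = NULL) {
  stopifnot(inherits(clm, "cell_label_map"), min_cell_area_um2 >= 0)
  k <- nrow(clm$nuclei)
  lab <- clm$labels
  if (is.null(foreground)) {
    area_px <- clm$nuclei$basin_px
  } else {
    inside <- lab * (foreground == 1L)
    area_px <- tabulate(inside[inside > 0L], nbins = k)
  }
  area_um2 <- area_px * clm$pixel_size_um^2
  drop <- clm$nuclei$cell_id[area_um2 < min_cell_area_um2]
  if (length(drop)) lab[lab %in% drop] <- 0L
  clm$labels <- lab
  clm$nuclei$cell_area_px <- area_px
  clm$nuclei$cell_area_um2 <- area_um2
  clm$nuclei <- clm$nuclei[!(clm$nuclei$cell_id %in% drop), , drop = FALSE]
  rownames(clm$nuclei) <- NULL
  clm
}
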