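#' A prototype granule template
#'
#' A small image patch containing one example granule plus a margin of
#' surrounding cytoplasm, with the similarity threshold (ST) above which a
#' correlation counts as a detection seed. The cytoplasm margin is part of
#' the template on purpose: it anchors the local contrast between granule
#' and surroundings, which is what makes strict STs possible.
#'
#' @param patch odd-sided numeric matrix with nonzero variance; side must be
#'   at least 3.
#' @param id prototype label (e.g. `"I"` .. `"VIII"`).
#' @param similarity_threshold minimum correlation for a seed, in (0, 1).
#' @param rotation_deg one of 0, 90, 180, 270.
#' @return an object of class `prototype`.
#' @export
prototype <- function(patch, id, similarity_threshold, rotation_deg = 0L) {
  patch <- as.matrix(patch)
  storage.mode(patch) <- "double"
  if (min(dim(patch)) < 3L) stop("prototype patch side must be >= 3")
  if (nrow(patch) %% 2L == 0L || ncol(patch) %% 2L == 0L)
    stop("prototype patch sides must be odd")
  if (stats::var(as.vector(patch)) == 0) stop("prototype patch has zero variance")
  if (similarity_threshold <= 0 || similarity_threshold >= 1)
    stop("similarity_threshold must be in (0, 1)")
  if (!rotation_deg %in% c(0L, 90L, 180L, 270L))
    stop("rotation_deg must be 0, 90, 180 or 270")
  structure(list(patch = patch, id = as.character(id),
                 similarity_threshold = similarity_threshold,
                 rotation_deg = as.integer(rotation_deg)),
            class = "prototype")
}

#' Cut a prototype patch out of an image
#'
#' Extracts a square patch of side `granule_box + 2 * margin` centred on
#' `center`. Keeping a cytoplasm margin around the granule markedly improves
#' template performance.
#'
#' @param img a [channel_image()].
#' @param center `(row, col)` of the granule centre (1-based).
#' @param granule_box odd side of the granule core box, in pixels.
#' @param margin cytoplasm margin width, in pixels.
#' @param id,similarity_threshold passed to [prototype()].
#' @return a [prototype()].
#' @export
extract_prototype <- function(img, center, granule_box, margin = 3L,
                              id = "P", similarity_threshold = 0.85) {
  stopifnot(inherits(img, "channel_image"), granule_box %% 2L == 1L,
            granule_box >= 3L, margin >= 0L)
  h <- (granule_box - 1L) %/% 2L + margin
  r <- center[1]; cc <- center[2]
  if (r - h < 1L || cc - h < 1L || r + h > nrow(img$pixels) ||
      cc + h > ncol(img$pixels))
    stop("prototype box does not fit inside the image")
  patch <- img$pixels[(r - h):(r + h), (cc - h):(cc + h)]
  prototype(patch, id = id, similarity_threshold = similarity_threshold)
}

#' Rotate a prototype clockwise by quarter turns
#'
#' The similarity threshold is inherited unchanged, matching how rotated
#' template variants are assessed at the ST of their parent.
#'
#' @param p a [prototype()].
#' @param quarter_turns 1, 2 or 3 clockwise 90-degree turns.
#' @return the rotated [prototype()], id suffixed with `_r<deg>`.
#' @export
rotate_prototype <- function(p, quarter_turns) {
  stopifnot(inherits(p, "prototype"), quarter_turns %in% 1:3)
  rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  patch <- p$patch
  for (i in seq_len(quarter_turns)) patch <- rot_cw(patch)
  deg <- (p$rotation_deg + 90L * quarter_turns) %% 360L
  prototype(patch, id = paste0(sub("_r\\d+$", "", p$id), "_r", deg),
            similarity_threshold = p$similarity_threshold, rotation_deg = deg)
}

#' An ordered bank of prototypes
#'
#' @param prototypes list of [prototype()] objects; `(id, rotation_deg)`
#'   pairs must be unique.
#' @return an object of class `prototype_bank`.
#' @export
prototype_bank <- function(prototypes) {
  stopifnot(length(prototypes) >= 1,
            all(vapply(prototypes, inherits, logical(1), "prototype")))
  keys <- vapply(prototypes, function(p) paste(p$id, p$rotation_deg), "")
  if (anyDuplicated(keys)) stop("duplicate (id, rotation) in prototype bank")
  structure(list(prototypes = prototypes), class = "prototype_bank")
}

#' @export
length.prototype_bank <- function(x) length(x$prototypes)

#' @export
print.prototype_bank <- function(x, ...) {
  cat(sprintf("<prototype_bank> %d prototypes\n", length(x)))
  for (p in x$prototypes)
    cat(sprintf("  %-8s side %2d  ST %.2f  rot %d\n", p$id, nrow(p$patch),
                p$similarity_threshold, p$rotation_deg))
  invisible(x)
}

#' Add rotated variants to a bank
#'
#' @param bank a [prototype_bank()].
#' @return a bank with each prototype plus its 90/180/270-degree rotations.
#' @export
with_rotations <- function(bank) {
  rot <- unlist(lapply(bank$prototypes, function(p)
    lapply(1:3, function(q) rotate_prototype(p, q))), recursive = FALSE)
  prototype_bank(c(bank$prototypes, rot))
}

#' Normalized 2-D cross-correlation against a prototype
#'
#' At every position where the patch fits entirely inside the image, the
#' Pearson correlation between the patch and the co-located image window
#' (both mean-centred, normalised by their standard deviations). Values lie
#' in `[-1, 1]`; zero-variance windows give 0; border positions where the
#' patch does not fit are `NA` (no padding - padded correlations are biased
#' and produce rim artifacts).
#'
#' @param img a [channel_image()].
#' @param p a [prototype()].
#' @return a `correlation_map`: list with `values` (matrix registered to the
#'   image grid) and `prototype_id`.
#' @export
normxcorr <- function(img, p) {
  stopifnot(inherits(img, "channel_image"), inherits(p, "prototype"))
  structure(list(values = normxcorr_fft(img$pixels, p$patch),
                 prototype_id = p$id),
            class = "correlation_map")
}

# FFT + integral-image NCC: the cross term through EBImage::filter2 (FFT
# convolution; the patch is flipped to give correlation), window mean and
# variance through summed-area tables of the globally centred image (the
# centring is what keeps the E[x^2] - E[x]^2 form numerically safe here).
# Exact at every interior position; border positions are NA.
normxcorr_fft <- function(img, patch) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- nrow(patch); pc <- ncol(patch)
  if (pr %% 2L == 0L || pc %% 2L == 0L) stop("template sides must be odd")
  if (pr > nr || pc > nc) stop("template larger than image")
  n <- pr * pc
  w <- patch - mean(patch)
  pnorm <- sqrt(sum(w * w))
  if (pnorm <= 0) stop("template has zero variance")
  x <- img - mean(img)
  cross <- EBImage::filter2(x, w[pr:1, pc:1, drop = FALSE], boundary = "circular")
  # summed-area tables with a zero row/col prefix
  sat <- function(z) {
    z <- apply(z, 2, cumsum)
    z <- t(apply(z, 1, cumsum))
    rbind(0, cbind(0, z))
  }
  S1 <- sat(x); S2 <- sat(x * x)
  hr <- pr %/% 2L; hc <- pc %/% 2L
  rows <- (hr + 1L):(nr - hr); cols <- (hc + 1L):(nc - hc)
  win_sum <- function(S) {
    S[rows + hr + 1L, cols + hc + 1L] - S[rows + hr + 1L, cols - hc] -
      S[rows - hr, cols + hc + 1L] + S[rows - hr, cols - hc]
  }
  s <- win_sum(S1)
  wvar <- pmax(win_sum(S2) - s * s / n, 0)
  denom <- sqrt(wvar) * pnorm
  r <- cross[rows, cols, drop = FALSE] / ifelse(denom > 1e-9, denom, Inf)
  r <- pmin(pmax(r, -1), 1)
  out <- matrix(NA_real_, nr, nc)
  out[rows, cols] <- r
  out
}

#' Threshold a correlation map into seeds
#'
#' Positions with correlation strictly above the similarity threshold become
#' seed pixels.
#'
#' @param cmap a `correlation_map` from [normxcorr()].
#' @param st similarity threshold in (0, 1).
#' @return a `seed_map`: list with `pixels` (logical matrix) and
#'   `by_prototype` (named list of per-prototype seed masks).
#' @export
threshold_seeds <- function(cmap, st) {
  stopifnot(inherits(cmap, "correlation_map"), st > 0, st < 1)
  seeds <- !is.na(cmap$values) & cmap$values > st
  bp <- stats::setNames(list(seeds), cmap$prototype_id)
  structure(list(pixels = seeds, by_prototype = bp), class = "seed_map")
}

# internal: union of seed maps, merging per-prototype provenance
union_seed_maps <- function(maps) {
  pixels <- Reduce(`|`, lapply(maps, `[[`, "pixels"))
  ids <- unique(unlist(lapply(maps, function(m) names(m$by_prototype))))
  bp <- lapply(ids, function(id) {
    Reduce(`|`, lapply(maps, function(m) {
      if (id %in% names(m$by_prototype)) m$by_prototype[[id]]
      else matrix(FALSE, nrow(pixels), ncol(pixels))
    }))
  })
  structure(list(pixels = pixels, by_prototype = stats::setNames(bp, ids)),
            class = "seed_map")
}

#' Detect seeds with a prototype bank
#'
#' Runs [normxcorr()] + [threshold_seeds()] for every prototype at its own
#' similarity threshold and takes the union. With the sharpened pass
#' enabled, the same bank is also correlated against the unsharp-filtered
#' image and those seeds are added, recovering the minority of weakly
#' stained foci; with an 8-prototype bank this is the classic 16-correlation
#' sweep per micrograph.
#'
#' @param img a [channel_image()] (clipped foci channel).
#' @param bank a [prototype_bank()].
#' @param use_sharpened_pass also correlate against the unsharp-filtered
#'   image; default `TRUE`.
#' @param unsharp_alpha kernel parameter for the sharpened pass.
#' @param st_overrides optional named numeric vector of per-prototype ST
#'   overrides (names are prototype ids).
#' @return a `seed_map` with per-prototype provenance.
#' @export
detect_seeds <- function(img, bank, use_sharpened_pass = TRUE,
                         unsharp_alpha = 0.2, st_overrides = NULL) {
  stopifnot(inherits(img, "channel_image"), inherits(bank, "prototype_bank"))
  imgs <- list(img)
  if (use_sharpened_pass) imgs <- c(imgs, list(unsharp_filter(img, unsharp_alpha)))
  maps <- list()
  for (p in bank$prototypes) {
    st <- p$similarity_threshold
    if (!is.null(st_overrides) && p$id %in% names(st_overrides))
      st <- st_overrides[[p$id]]
    for (im in imgs)
      maps[[length(maps) + 1L]] <- threshold_seeds(normxcorr(im, p), st)
  }
  union_seed_maps(maps)
}

#' Remove nuclear and extracellular seeds
#'
#' The polyadenylated-RNA probe also stains the nucleus, generating seeds
#' there; those and seeds outside the stained-cell foreground are dropped:
#' `seeds & !nucleus & foreground`.
#'
#' @param seeds a `seed_map`.
#' @param nuc_mask 0/1 nuclear mask.
#' @param foreground 0/1 foreground mask from [cell_foreground()] (or `NULL`
#'   to skip the extracellular filter).
#' @return the filtered `seed_map`.
#' @export
mask_seeds <- function(seeds, nuc_mask, foreground = NULL) {
  stopifnot(inherits(seeds, "seed_map"))
  keep <- nuc_mask != 1L
  if (!is.null(foreground)) keep <- keep & foreground == 1L
  seeds$pixels <- seeds$pixels & keep
  seeds$by_prototype <- lapply(seeds$by_prototype, function(m) m & keep)
  seeds
}

#' Merge seeds into counted focus objects
#'
#' Each seed is dilated to a centred 3x3 square (the size of a small focus
#' at 63x / 512 px); squares around seeds belonging to the same focus
#' overlap and fuse, and 8-connected components of the dilated mask become
#' one focus object each, so a focus redundantly hit by several prototypes
#' is counted once. Every object is reduced to a representative point (the
#' centroid snapped to the nearest in-object pixel).
#'
#' @param seeds a `seed_map` (after [mask_seeds()]).
#' @param pixel_size_um physical pixel size, for areas in um^2.
#' @return list of `focus` objects: `focus_id`, `point` (row, col),
#'   `pixel_idx` (linear indices of the merged object), `pixel_count`,
#'   `area_um2`, `bbox_side_px`, `size_reliable`, `cell_id` (0 until
#'   assigned), `prototype_hits`.
#' @export
merge_seeds <- function(seeds, pixel_size_um) {
  stopifnot(inherits(seeds, "seed_map"), pixel_size_um > 0)
  nr <- nrow(seeds$pixels)
  if (!any(seeds$pixels)) return(list())
  dil <- EBImage::dilate(seeds$pixels * 1L, EBImage::makeBrush(3L, "box"))
  lab <- label8_cpp(matrix(as.integer(dil != 0), nr))
  k <- max(lab)
  pos <- which(lab > 0L)
  comp <- split(pos, lab[pos])
  proto_idx <- lapply(seeds$by_prototype, function(m) which(m))
  foci <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- comp[[as.character(i)]]
    r <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    cr <- mean(r); ccc <- mean(cc)
    point <- c(r[which.min((r - cr)^2 + (cc - ccc)^2)][1],
               cc[which.min((r - cr)^2 + (cc - ccc)^2)][1])
    hits <- names(proto_idx)[vapply(proto_idx, function(s) any(s %in% idx),
                                    logical(1))]
    bbox <- max(max(r) - min(r), max(cc) - min(cc)) + 1L
    foci[[i]] <- structure(
      list(focus_id = i, point = point, pixel_idx = idx,
           pixel_count = length(idx),
           area_um2 = length(idx) * pixel_size_um^2,
           bbox_side_px = bbox,
           size_reliable = bbox > 6L,
           cell_id = 0L, prototype_hits = hits),
      class = "focus")
  }
  foci
}

#' Size-measurement reliability of a focus
#'
#' Pixel-count size estimates are only trustworthy once the object exceeds a
#' minimum width; below it, measure at higher magnification/resolution.
#'
#' @param obj a `focus` object.
#' @param min_width_px width threshold in pixels; default 6.
#' @return logical: larger bounding-box side exceeds `min_width_px`.
#' @export
size_reliability <- function(obj, min_width_px = 6L) {
  stopifnot(inherits(obj, "focus"), min_width_px >= 1L)
  obj$bbox_side_px > min_width_px
}

#' Tabulate a focus list
#'
#' @param foci list of `focus` objects.
#' @return data frame, one row per focus.
#' @export
foci_table <- function(foci) {
  if (!length(foci))
    return(data.frame(focus_id = integer(), row = integer(), col = integer(),
                      pixel_count = integer(), area_um2 = numeric(),
                      size_reliable = logical(), cell_id = integer(),
                      prototype_hits = character()))
  data.frame(
    focus_id = vapply(foci, `[[`, 0L, "focus_id"),
    row = vapply(foci, function(f) f$point[1], 0),
    col = vapply(foci, function(f) f$point[2], 0),
    pixel_count = vapply(foci, `[[`, 0L, "pixel_count"),
    area_um2 = vapply(foci, `[[`, 0, "area_um2"),
    size_reliable = vapply(foci, `[[`, TRUE, "size_reliable"),
    cell_id = vapply(foci, `[[`, 0L, "cell_id"),
    prototype_hits = vapply(foci, function(f)
      paste(sort(f$prototype_hits), collapse = "+"), ""))
}

#' Redundant recognition between prototypes
#'
#' Lower-triangle percentage matrix over detected objects: diagonal entry
#' (i, i) is the percentage of objects hit by prototype i; entry (i, j) the
#' percentage hit simultaneously by prototypes i and j.
#'
#' @param foci list of `focus` objects carrying `prototype_hits`.
#' @param bank the [prototype_bank()] used for detection.
#' @return numeric lower-triangular matrix (percent), dimnames = prototype ids.
#' @export
prototype_redundancy <- function(foci, bank) {
  ids <- vapply(bank$prototypes, `[[`, "", "id")
  k <- length(ids)
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  n <- length(foci)
  if (n == 0) { m[lower.tri(m, diag = TRUE)] <- 0; return(m) }
  hit <- vapply(foci, function(f) ids %in% f$prototype_hits, logical(k))
  hit <- matrix(hit, nrow = k)
  for (i in seq_len(k))
    for (j in seq_len(i))
      m[i, j] <- 100 * sum(hit[i, ] & hit[j, ]) / n
  m
}

#' Drop foci below a minimum area
#'
#' Optional physical-size filter (e.g. 0.2 um^2 for synaptic foci analyses).
#'
#' @param foci list of `focus` objects.
#' @param min_area_um2 smallest kept area; 0 disables.
#' @return filtered list, focus_ids renumbered.
#' @export
filter_small_foci <- function(foci, min_area_um2 = 0) {
  if (min_area_um2 <= 0) return(foci)
  keep <- Filter(function(f) f$area_um2 >= min_area_um2, foci)
  for (i in seq_along(keep)) keep[[i]]$focus_id <- i
  keep
}
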