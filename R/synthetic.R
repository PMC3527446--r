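#' Specification for a synthetic two-channel field
#'
#' Describes the image regime the pipeline targets: DAPI-bright nuclei,
#' faintly stained cytoplasm, compact bright granules of varied size, shape
#' and intensity, plus additive Gaussian noise. Defaults emulate a 63x
#' confocal field of semi-adherent insect cells at 512x512 px: nuclei around
#' intensity 200, cytoplasm faint, roughly half the cells positive with 2-6
#' granules each. All lengths in the stated units; intensities on the 8-bit
#' scale.
#'
#' @param side field side in pixels.
#' @param pixel_size_um physical pixel size (um/px).
#' @param n_cells number of cells to place.
#' @param cell_radius_um range (min, max) of cell radii.
#' @param nucleus_radius_um range of nucleus radii.
#' @param frac_positive fraction of cells carrying granules (>= 2).
#' @param granules_per_positive integer range of granule counts in positive
#'   cells.
#' @param neg_cell_granule_prob probability that a negative cell carries a
#'   single granule (below the >= 2 positivity rule).
#' @param granule_sigma_px range of granule Gaussian radii (px).
#' @param granule_axis_ratio range of major/minor axis ratios (1 = round).
#' @param core_prob probability of a brighter core (Gaussian-profiled
#'   granules only).
#' @param disk_prob probability that a granule has the dense
#'   uniform-intensity (disk) profile rather than the Gaussian one.
#' @param granule_peak range of granule peak amplitudes above cytoplasm.
#' @param cytoplasm_level,background_level,nuclear_level,nuclear_polya_level
#'   mean intensities of cytoplasm, empty background, DAPI nuclei, and the
#'   nuclear polyadenylated-RNA signal in the foci channel.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param min_granule_sep_px minimum centre-to-centre spacing of granules
#'   within a cell.
#' @param edge_margin_px minimum clearance between a cell edge and the
#'   field border (raise it when detection will use large templates, whose
#'   correlation is undefined near the border).
#' @param bit_depth image bit depth.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(side = 512L, pixel_size_um = 0.2, n_cells = 15L,
                           cell_radius_um = c(6, 9),
                           nucleus_radius_um = c(2.5, 3.5),
                           frac_positive = 0.5,
                           granules_per_positive = c(2L, 6L),
                           neg_cell_granule_prob = 0.3,
                           granule_sigma_px = c(1.1, 2.6),
                           granule_axis_ratio = c(1, 1.8),
                           core_prob = 0.4, disk_prob = 0.25,
                           granule_peak = c(110, 215),
                           cytoplasm_level = 30, background_level = 5,
                           nuclear_level = 200, nuclear_polya_level = 100,
                           noise_sd = 8, min_granule_sep_px = 10,
                           edge_margin_px = 2, bit_depth = 8L, seed = 1L) {
  stopifnot(side >= 64L, pixel_size_um > 0, n_cells >= 0L,
            frac_positive >= 0, frac_positive <= 1,
            all(cell_radius_um > 0), all(granule_sigma_px > 0),
            noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# smooth-edged ellipse footprint added into img; returns modified img
soft_ellipse <- function(img, r0, c0, ra, rc, level, edge = 1.5) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- max(1L, floor(r0 - ra - 3)):min(nr, ceiling(r0 + ra + 3))
  cc <- max(1L, floor(c0 - rc - 3)):min(nc, ceiling(c0 + rc + 3))
  d <- sqrt(outer(((rr - r0) / ra)^2, ((cc - c0) / rc)^2, `+`))
  w <- pmin(pmax((1 - d) * max(ra, rc) / edge + 0.5, 0), 1)
  img[rr, cc] <- img[rr, cc] + level * w
  img
}

# anisotropic granule added into img. Two body profiles:
#  - "gaussian": peak * exp(-r'^2/2), optionally with a brighter core
#  - "disk": uniform intensity inside semi-axes (sx, sy), 1.5 px soft edge
#    (the dense, uniform-intensity morphology of processing-body-like foci)
render_granule <- function(img, r0, c0, sx, sy, peak, core,
                           profile = "gaussian") {
  nr <- nrow(img); nc <- ncol(img)
  ext <- ceiling(4 * max(sx, sy))
  rr <- max(1L, r0 - ext):min(nr, r0 + ext)
  cc <- max(1L, c0 - ext):min(nc, c0 + ext)
  if (profile == "disk") {
    d <- sqrt(outer(((rr - r0) / sy)^2, ((cc - c0) / sx)^2, `+`))
    g <- peak * pmin(pmax((1 - d) * max(sx, sy) / 1.5 + 0.5, 0), 1)
  } else {
    g <- peak * exp(-0.5 * outer(((rr - r0) / sy)^2, ((cc - c0) / sx)^2, `+`))
    if (core)
      g <- g + 0.6 * peak *
        exp(-0.5 * outer(((rr - r0) / (0.45 * sy))^2,
                         ((cc - c0) / (0.45 * sx))^2, `+`))
  }
  img[rr, cc] <- img[rr, cc] + g
  img
}

# half-maximum area (px) of a rendered granule profile, noiseless
granule_halfmax_area <- function(sx, sy, peak, core, profile = "gaussian") {
  ext <- ceiling(4 * max(sx, sy))
  z <- matrix(0, 2L * ext + 1L, 2L * ext + 1L)
  z <- render_granule(z, ext + 1L, ext + 1L, sx, sy, peak, core, profile)
  sum(z >= 0.5 * max(z))
}

#' Generate one synthetic field with ground truth
#'
#' Places non-overlapping cells (disc cytoplasm, elliptical nucleus), plants
#' granules in the cytoplasmic annulus of positive cells, renders both
#' channels and adds noise. The nuclear polyadenylated-RNA signal in the
#' foci channel includes a couple of bright intranuclear speckles per cell,
#' which deliberately provoke nuclear seeds that the masking stage must
#' remove. Bit-reproducible given the spec (the spec carries the seed).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `images` (an [image_set()]) and `truth` (list:
#'   `cell_labels` footprint matrix, `nucleus_mask`, `cells` data frame,
#'   `granules` data frame with centres, axes, peak and planted half-max
#'   area).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  n <- spec$side
  ps <- spec$pixel_size_um
  top <- 2^spec$bit_depth - 1
  nuc_img <- matrix(spec$background_level, n, n)
  foci_img <- matrix(spec$background_level, n, n)
  cell_labels <- matrix(0L, n, n)
  nucleus_mask <- matrix(0L, n, n)

  # --- place cells (bounded rejection sampling) ---
  cells <- data.frame()
  if (spec$n_cells > 0L) {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        r_cell <- stats::runif(1, spec$cell_radius_um[1], spec$cell_radius_um[2]) / ps
        r0 <- stats::runif(1, r_cell + spec$edge_margin_px,
                           n - r_cell - spec$edge_margin_px)
        c0 <- stats::runif(1, r_cell + spec$edge_margin_px,
                           n - r_cell - spec$edge_margin_px)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) >
                radii + r_cell + 3)) {
          centers <- rbind(centers, c(r0, c0))
          radii <- c(radii, r_cell)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("overcrowded synthetic spec: could not place ", spec$n_cells,
             " non-overlapping cells")
    }
    r_nuc <- stats::runif(spec$n_cells, spec$nucleus_radius_um[1],
                          spec$nucleus_radius_um[2]) / ps
    cells <- data.frame(cell_id = seq_len(spec$n_cells),
                        row = centers[, 1], col = centers[, 2],
                        radius_px = radii, nucleus_radius_px = r_nuc)
  }

  # --- decide positivity and granule counts ---
  gran <- list()
  if (nrow(cells)) {
    pos <- stats::runif(nrow(cells)) < spec$frac_positive
    counts <- ifelse(pos,
                     sample(spec$granules_per_positive[1]:spec$granules_per_positive[2],
                            nrow(cells), replace = TRUE),
                     stats::rbinom(nrow(cells), 1L, spec$neg_cell_granule_prob))
    cells$planted_positive <- counts >= 2L
    cells$n_granules_planted <- 0L

    # --- render cells and plant granules ---
    grid_r <- matrix(seq_len(n), n, n)
    grid_c <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (i in seq_len(nrow(cells))) {
      r0 <- cells$row[i]; c0 <- cells$col[i]
      rcell <- cells$radius_px[i]; rnuc <- cells$nucleus_radius_px[i]
      foci_img <- soft_ellipse(foci_img, r0, c0, rcell, rcell,
                               spec$cytoplasm_level - spec$background_level)
      # nucleus: mildly elliptical, axis-aligned
      sq <- stats::runif(1, 0.85, 1.15)
      na_ <- rnuc * sq; nb <- rnuc / sq
      nuc_img <- soft_ellipse(nuc_img, r0, c0, na_, nb,
                              spec$nuclear_level - spec$background_level)
      foci_img <- soft_ellipse(foci_img, r0, c0, na_, nb,
                               spec$nuclear_polya_level - spec$cytoplasm_level)
      d2cell <- sqrt((grid_r - r0)^2 + (grid_c - c0)^2)
      cell_labels[d2cell <= rcell] <- i
      d2nuc <- sqrt(((grid_r - r0) / na_)^2 + ((grid_c - c0) / nb)^2)
      nucleus_mask[d2nuc <= 1] <- 1L
      # nuclear polyA speckles, well inside the nucleus
      for (s in seq_len(2L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.45 * min(na_, nb))
        foci_img <- render_granule(foci_img,
                                   round(r0 + rad * sin(ang)),
                                   round(c0 + rad * cos(ang)),
                                   1.3, 1.3, 80, FALSE)
      }
      # granules in the cytoplasmic annulus
      k <- counts[i]
      if (k > 0L) {
        pts <- matrix(numeric(0), 0, 2)
        for (g in seq_len(k)) {
          sx <- stats::runif(1, spec$granule_sigma_px[1], spec$granule_sigma_px[2])
          ratio <- stats::runif(1, spec$granule_axis_ratio[1],
                                spec$granule_axis_ratio[2])
          if (stats::runif(1) < 0.5) { sy <- sx / ratio } else { sy <- sx; sx <- sx / ratio }
          # optics floor: nothing images narrower than ~1 px at this scale,
          # and a dense uniform body below ~2 px radius is indistinguishable
          # from a diffraction-limited blob
          sx <- max(sx, 0.9); sy <- max(sy, 0.9)
          smax <- max(sx, sy)
          peak <- stats::runif(1, spec$granule_peak[1], spec$granule_peak[2])
          profile <- if (stats::runif(1) < spec$disk_prob && min(sx, sy) >= 1.6)
            "disk" else "gaussian"
          core <- profile == "gaussian" && stats::runif(1) < spec$core_prob
          ok <- FALSE
          for (try in seq_len(200L)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rmin <- max(na_, nb) + 3 + 2 * smax
            rmax <- rcell - 3 * smax - 2
            if (rmax <= rmin) break
            rad <- sqrt(stats::runif(1, (rmin / rmax)^2, 1)) * rmax
            gr <- round(r0 + rad * sin(ang)); gc <- round(c0 + rad * cos(ang))
            if (nrow(pts) == 0 ||
                all(sqrt((pts[, 1] - gr)^2 + (pts[, 2] - gc)^2) >=
                    spec$min_granule_sep_px)) { ok <- TRUE; break }
          }
          if (!ok) next  # cell too crowded for this granule; record fewer
          pts <- rbind(pts, c(gr, gc))
          foci_img <- render_granule(foci_img, gr, gc, sx, sy, peak, core,
                                     profile)
          gran[[length(gran) + 1L]] <- data.frame(
            cell_id = i, row = gr, col = gc, sigma_x = sx, sigma_y = sy,
            peak = peak, core = core, profile = profile,
            planted_area_px = granule_halfmax_area(sx, sy, peak, core, profile))
        }
        cells$n_granules_planted[i] <- nrow(pts)
      }
    }
    # planted positivity reflects what was actually placed
    cells$planted_positive <- cells$n_granules_planted >= 2L
  }

  if (spec$noise_sd > 0) {
    nuc_img <- nuc_img + stats::rnorm(n * n, 0, spec$noise_sd)
    foci_img <- foci_img + stats::rnorm(n * n, 0, spec$noise_sd)
  }
  nuc_img <- round(pmin(pmax(nuc_img, 0), top))
  foci_img <- round(pmin(pmax(foci_img, 0), top))

  granules <- if (length(gran)) do.call(rbind, gran) else
    data.frame(cell_id = integer(), row = integer(), col = integer(),
               sigma_x = numeric(), sigma_y = numeric(), peak = numeric(),
               core = logical(), profile = character(),
               planted_area_px = numeric())

  list(
    images = image_set(
      nuclear = channel_image(nuc_img, spec$bit_depth, ps, "nuclear"),
      foci = channel_image(foci_img, spec$bit_depth, ps, "foci"),
      field_id = paste0("synth_seed", spec$seed)),
    truth = list(cell_labels = cell_labels, nucleus_mask = nucleus_mask,
                 cells = cells, granules = granules, spec = spec))
}

#' Generate a synthetic screening plate
#'
#' Renders `n_fields` fields per well, with the fraction of positive cells
#' set per treatment. The per-field seeds are derived deterministically from
#' `seed`, the well index and the field index.
#'
#' @param layout data frame with columns `plate_id`, `well_id`, `treatment`,
#'   `is_control`.
#' @param base_spec a [synthetic_spec()] used for every field (its
#'   `frac_positive` and `seed` are overridden).
#' @param frac_positive_by_treatment named numeric vector mapping treatment
#'   labels to the planted positive fraction.
#' @param n_fields fields per well.
#' @param seed base seed.
#' @return list with `fields` (list of per-well lists of
#'   [generate_field()] results) and `expected` (layout plus the planted
#'   positive fraction and expected score vs the control mean).
#' @export
generate_plate <- function(layout, base_spec, frac_positive_by_treatment,
                           n_fields = 20L, seed = 1L) {
  stopifnot(nrow(layout) >= 1, n_fields >= 1L,
            all(layout$treatment %in% names(frac_positive_by_treatment)))
  fields <- vector("list", nrow(layout))
  names(fields) <- layout$well_id
  for (w in seq_len(nrow(layout))) {
    fr <- frac_positive_by_treatment[[layout$treatment[w]]]
    fields[[w]] <- lapply(seq_len(n_fields), function(i) {
      sp <- base_spec
      sp$frac_positive <- fr
      sp$seed <- (seed + 7919L * w + i) %% .Machine$integer.max
      generate_field(sp)
    })
  }
  expected <- layout
  expected$frac_positive <- frac_positive_by_treatment[layout$treatment]
  ctrl_mean <- mean(expected$frac_positive[layout$is_control])
  expected$expected_score <- expected$frac_positive / ctrl_mean
  list(fields = fields, expected = expected)
}

#' Match detections against planted granules
#'
#' Greedy one-to-one matching: candidate (detection, granule) pairs within
#' `match_radius_um` are accepted in order of increasing distance, each
#' detection and each granule used at most once. Precision is the matched
#' share of detections (reported as 1 with a flag when there are no
#' detections), recall the matched share of planted granules.
#'
#' @param foci list of detected `focus` objects.
#' @param truth ground truth from [generate_field()].
#' @param match_radius_um maximum centre distance for a match.
#' @param pixel_size_um physical pixel size.
#' @return list: `n_detected`, `n_planted`, `n_matched`, `precision`,
#'   `recall`, `no_detections` flag, `size_error_frac` (per-match relative
#'   pixel-count error, reliable detections only).
#' @export
evaluate_detection <- function(foci, truth, match_radius_um = 1,
                               pixel_size_um = truth$spec$pixel_size_um) {
  stopifnot(match_radius_um > 0)
  g <- truth$granules
  nd <- length(foci); ng <- nrow(g)
  if (nd == 0) {
    return(list(n_detected = 0L, n_planted = ng, n_matched = 0L,
                precision = 1, recall = if (ng > 0) 0 else NA_real_,
                no_detections = TRUE, size_error_frac = numeric(0)))
  }
  dp <- t(vapply(foci, `[[`, c(0, 0), "point"))
  radius_px <- match_radius_um / pixel_size_um
  pairs <- NULL
  if (ng > 0) {
    dmat <- sqrt(outer(dp[, 1], g$row, `-`)^2 + outer(dp[, 2], g$col, `-`)^2)
    idx <- which(dmat <= radius_px, arr.ind = TRUE)
    if (nrow(idx)) {
      ord <- order(dmat[idx])
      pairs <- idx[ord, , drop = FALSE]
    }
  }
  used_d <- logical(nd); used_g <- logical(max(ng, 1L))
  matches <- matrix(integer(0), 0, 2)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      di <- pairs[k, 1]; gi <- pairs[k, 2]
      if (!used_d[di] && !used_g[gi]) {
        used_d[di] <- TRUE; used_g[gi] <- TRUE
        matches <- rbind(matches, c(di, gi))
      }
    }
  }
  size_err <- numeric(0)
  if (nrow(matches)) {
    for (k in seq_len(nrow(matches))) {
      f <- foci[[matches[k, 1]]]
      if (isTRUE(f$size_reliable)) {
        planted <- g$planted_area_px[matches[k, 2]]
        size_err <- c(size_err, (f$pixel_count - planted) / planted)
      }
    }
  }
  list(n_detected = nd, n_planted = ng, n_matched = nrow(matches),
       precision = nrow(matches) / nd,
       recall = if (ng > 0) nrow(matches) / ng else NA_real_,
       no_detections = FALSE, size_error_frac = size_err)
}
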