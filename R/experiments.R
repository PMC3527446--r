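#' Detection benchmark on the default synthetic suite
#'
#' Generates `n_fields` default 512 px fields (about 15 cells each, half of
#' them granule-positive), runs the full pipeline with the default prototype
#' bank and matches detections against the planted granules. The pooled
#' precision/recall over the suite is the package's standing detection
#' benchmark.
#'
#' @param n_fields number of fields; default 20.
#' @param base_seed seed; field i uses `base_seed + i`.
#' @param bank prototype bank; default [default_prototype_bank()].
#' @param config pipeline configuration overrides.
#' @param match_radius_um match radius for detection-truth pairing.
#' @param spec_overrides named list of [synthetic_spec()] arguments to
#'   override.
#' @return list: `precision`, `recall`, `n_detected`, `n_matched`,
#'   `n_planted`, `fields` (per-field summary data frame),
#'   `mean_foci_per_positive_cell`, `pct_positive`.
#' @export
detection_benchmark <- function(n_fields = 20L, base_seed = 100L,
                                bank = default_prototype_bank(),
                                config = NULL, match_radius_um = 1,
                                spec_overrides = list()) {
  nd <- nm <- np <- 0
  fields <- list()
  for (i in seq_len(n_fields)) {
    args <- utils::modifyList(list(seed = base_seed + i), spec_overrides)
    f <- generate_field(do.call(synthetic_spec, args))
    out <- run_pipeline(list(f$images), config = config, bank = bank)
    ev <- evaluate_detection(out$objects[[1]], f$truth,
                             match_radius_um = match_radius_um)
    nd <- nd + ev$n_detected; nm <- nm + ev$n_matched; np <- np + ev$n_planted
    fields[[i]] <- out$fields
  }
  fields <- do.call(rbind, fields)
  list(precision = if (nd > 0) nm / nd else 1,
       recall = if (np > 0) nm / np else NA_real_,
       n_detected = nd, n_matched = nm, n_planted = np, fields = fields,
       mean_foci_per_positive_cell =
         sum(fields$mean_foci_per_positive_cell * fields$n_positive_cells,
             na.rm = TRUE) / sum(fields$n_positive_cells),
       pct_positive = 100 * sum(fields$n_positive_cells) / sum(fields$n_cells))
}

# the well layout used by the screening benchmark: six untreated control
# wells, three wells with an irrelevant knockdown, three effect wells
screen_layout <- function() {
  data.frame(
    plate_id = "P1",
    well_id = c(paste0("C", 1:6), paste0("L", 1:3), paste0("K", 1:3)),
    treatment = c(rep("none", 6), rep("LacZ", 3), rep("knockdown", 3)),
    is_control = c(rep(TRUE, 6), rep(FALSE, 6)))
}

#' Screening benchmark on a synthetic plate
#'
#' Builds a 12-well synthetic plate (six untreated control wells, three
#' wells with an irrelevant knockdown at the control positive fraction, and
#' three knockdown wells planted at `knockdown_factor` times the control
#' positive fraction), runs the pipeline on every field and scores each
#' well against the in-plate control mean.
#'
#' @param n_fields fields per well; default 20.
#' @param seed base seed.
#' @param control_frac planted positive fraction of control wells; default
#'   0.45 (the regime of untreated stressed-plate controls).
#' @param knockdown_factor planted effect size; default 0.6.
#' @return list: `report` (scored well table), `mean_knockdown_score`,
#'   `mean_control_score`, `mean_lacz_score`, `expected` (planted design).
#' @export
screening_benchmark <- function(n_fields = 20L, seed = 1L,
                                control_frac = 0.45,
                                knockdown_factor = 0.6) {
  layout <- screen_layout()
  base <- synthetic_spec(side = 336L, n_cells = 10L,
                         cell_radius_um = c(5, 7),
                         nucleus_radius_um = c(1.8, 2.4))
  fracs <- c(none = control_frac, LacZ = control_frac,
             knockdown = control_frac * knockdown_factor)
  plate <- generate_plate(layout, base, fracs, n_fields = n_fields,
                          seed = seed)
  images <- list()
  for (w in names(plate$fields)) {
    for (i in seq_along(plate$fields[[w]])) {
      iset <- plate$fields[[w]][[i]]$images
      iset$well_id <- w
      iset$field_id <- paste0(w, "_f", i)
      images[[iset$field_id]] <- iset
    }
  }
  out <- run_pipeline(images)
  report <- score_plate(out$fields, layout)
  list(report = report,
       mean_knockdown_score = mean(report$score[report$treatment == "knockdown"]),
       mean_control_score = mean(report$score[report$treatment == "none"]),
       mean_lacz_score = mean(report$score[report$treatment == "LacZ"]),
       expected = plate$expected)
}

#' Focus-size-change benchmark
#'
#' The processing-body regime: paired basal and stressed synthetic
#' populations at high resolution (0.05 um/px), the stressed granules
#' planted at `area_factor` times the basal areas via common random
#' numbers. Detection uses a dense size-ladder bank at one moderate
#' similarity threshold and sizes are re-measured by local half-maximum
#' segmentation ([measure_focus_sizes()]); the recovered ratio of mean
#' areas over size-reliable objects is the benchmark.
#'
#' @param n_fields fields per group; default 5.
#' @param base_seed seed; group pairs share seeds.
#' @param area_factor planted enlargement of the stressed group; default 3.5.
#' @return list: `report` (from [size_change_report()]), `recovered_ratio`,
#'   `planted_ratio`.
#' @export
size_change_benchmark <- function(n_fields = 5L, base_seed = 700L,
                                  area_factor = 3.5) {
  bank <- size_ladder_bank(6, 17, st = 0.8)
  cfg <- list(detection = list(use_sharpened_pass = FALSE))
  mkspec <- function(scale, seed) synthetic_spec(
    side = 768L, pixel_size_um = 0.05, n_cells = 2L,
    cell_radius_um = c(6.5, 7.0), nucleus_radius_um = c(1.8, 2.2),
    frac_positive = 1, granules_per_positive = c(2L, 3L),
    granule_sigma_px = c(6.5, 8.5) * scale, granule_axis_ratio = c(1, 1.2),
    core_prob = 0, disk_prob = 0, granule_peak = c(150, 215), noise_sd = 4,
    min_granule_sep_px = 80, edge_margin_px = 70, seed = seed)
  collect <- function(scale) {
    objs <- list(); planted <- numeric(0)
    for (i in seq_len(n_fields)) {
      f <- generate_field(mkspec(scale, base_seed + i))
      out <- run_pipeline(list(f$images), config = cfg, bank = bank)
      objs <- c(objs, measure_focus_sizes(
        out$objects[[1]], clip_intensity(f$images$foci, quiet = TRUE)))
      planted <- c(planted, f$truth$granules$planted_area_px)
    }
    attr(objs, "planted_mean") <- mean(planted)
    objs
  }
  basal <- collect(1)
  stressed <- collect(sqrt(area_factor))
  report <- size_change_report(list(basal = basal, stressed = stressed))
  list(report = report,
       recovered_ratio = report$ratio_vs_reference[report$group == "stressed"],
       planted_ratio = attr(stressed, "planted_mean") /
         attr(basal, "planted_mean"))
}
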