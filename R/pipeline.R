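#' Default pipeline configuration
#'
#' All tunables of the pipeline with their default values. Where a constant
#' comes from the published tuning of the method (clip cap 255, 60% nuclear
#' threshold, elevation gain 2, 30 um^2 cell filter, the eight per-prototype
#' similarity thresholds, >= 2 foci positivity, 0.5 um proximity radius,
#' 6 px size-reliability width) the default equals that value.
#'
#' @return nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    pixel_size_um = 0.2,
    channels = list(nuclear_page = 1L, foci_page = 2L, object_page = NA_integer_),
    preprocessing = list(
      cap = 255, stretch_low = 0.01, stretch_high = 0.99,
      wiener_window = 3L, unsharp_alpha = 0.2, gain = 2),
    segmentation = list(
      threshold_frac = 0.6, min_cell_area_um2 = 30, foreground_frac = 0.05),
    detection = list(
      st = c(I = 0.89, II = 0.88, III = 0.80, IV = 0.88,
             V = 0.86, VI = 0.86, VII = 0.92, VIII = 0.85),
      use_sharpened_pass = TRUE, use_rotations = FALSE,
      use_preprocessed = FALSE, min_focus_area_um2 = 0),
    quantification = list(
      min_foci_for_positive = 2L, proximity_radius_um = 0.5,
      size_reliability_width_px = 6L),
    screening = list(control_label = "none"))
}

# allowed range of every numeric leaf, as c(min, max)
config_ranges <- function() {
  list(
    pixel_size_um = c(1e-6, Inf),
    "preprocessing.cap" = c(1e-9, Inf),
    "preprocessing.stretch_low" = c(0, 1),
    "preprocessing.stretch_high" = c(0, 1),
    "preprocessing.wiener_window" = c(3, 99),
    "preprocessing.unsharp_alpha" = c(0, 1),
    "preprocessing.gain" = c(1, Inf),
    "segmentation.threshold_frac" = c(1e-9, 1 - 1e-9),
    "segmentation.min_cell_area_um2" = c(0, Inf),
    "segmentation.foreground_frac" = c(0, 1 - 1e-9),
    "detection.min_focus_area_um2" = c(0, Inf),
    "quantification.min_foci_for_positive" = c(1, Inf),
    "quantification.proximity_radius_um" = c(1e-9, Inf),
    "quantification.size_reliability_width_px" = c(1, Inf))
}

#' Validate and fill in a pipeline configuration
#'
#' Accepts a nested list or a YAML/JSON file path. Unknown keys are
#' rejected; every supplied value overrides the default after a range
#' check; missing values take defaults.
#'
#' @param config nested list, path to a YAML/JSON file, or `NULL` for pure
#'   defaults.
#' @return the fully-defaulted, range-checked configuration.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  def <- default_config()
  merged <- merge_config(def, config, path = "")
  rng <- config_ranges()
  for (key in names(rng)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- merged
    for (p in parts) val <- val[[p]]
    if (!is.numeric(val) || any(!is.finite(val)) ||
        any(val < rng[[key]][1]) || any(val > rng[[key]][2]))
      stop("config value out of range for '", key, "': ", paste(val, collapse = ","))
  }
  st <- merged$detection$st
  if (any(st <= 0) || any(st >= 1))
    stop("config value out of range for 'detection.st': similarity thresholds must lie in (0, 1)")
  if (merged$preprocessing$stretch_low >= merged$preprocessing$stretch_high)
    stop("config: preprocessing.stretch_low must be < stretch_high")
  merged
}

merge_config <- function(def, user, path) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(def)) stop("unknown config key: '", full, "'")
    if (is.list(def[[key]]) && !is.null(names(def[[key]]))
        && key != "detection") {
      if (!is.list(user[[key]])) stop("config section '", full, "' must be a mapping")
      def[[key]] <- merge_config(def[[key]], user[[key]], full)
    } else if (key == "detection") {
      def[[key]] <- merge_config(def[[key]], user[[key]], full)
    } else if (key == "st") {
      st <- unlist(user[[key]])
      if (is.null(names(st)) && length(st) == length(def[[key]]))
        names(st) <- names(def[[key]])
      def[[key]] <- st
    } else {
      def[[key]] <- user[[key]]
    }
  }
  def
}

#' Run the full detection and quantification pipeline
#'
#' Deterministic end-to-end execution for a list of fields: preprocess both
#' channels, build the nuclear mask, segment cells by marker-controlled
#' watershed, filter implausible cells, detect seeds by prototype
#' correlation (on the clipped, unscaled foci channel by default), remove
#' nuclear/extracellular seeds, merge seeds into objects, assign them to
#' cells and summarise. A failing field is reported with its id and stage
#' and the remaining fields continue.
#'
#' @param image_sets list of [image_set()] objects.
#' @param config configuration from [validate_config()] (or anything it
#'   accepts).
#' @param bank a [prototype_bank()]; default [default_prototype_bank()].
#' @return list with `fields` (per-field summary data frame), `cells`
#'   (per-cell data frame), `foci` (per-focus data frame), `objects`
#'   (per-field list of focus lists), `label_maps`, `errors`.
#' @export
run_pipeline <- function(image_sets, config = NULL,
                         bank = default_prototype_bank()) {
  cfg <- validate_config(config)
  if (inherits(image_sets, "image_set")) image_sets <- list(image_sets)
  stopifnot(length(image_sets) >= 1)
  if (cfg$detection$use_rotations) bank <- with_rotations(bank)
  fields <- list(); cells <- list(); foci_tabs <- list()
  objects <- list(); label_maps <- list(); errors <- list()
  for (iset in image_sets) {
    fid <- iset$field_id
    res <- tryCatch(
      run_field(iset, cfg, bank),
      error = function(e) {
        warning("field ", fid, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      errors[[fid]] <- "pipeline error"
      next
    }
    summary_row <- res$summary
    summary_row$well_id <- iset$well_id
    fields[[fid]] <- summary_row
    if (nrow(res$cells)) res$cells$field_id <- fid
    cells[[fid]] <- res$cells
    ft <- res$foci_table
    if (nrow(ft)) ft$field_id <- fid
    foci_tabs[[fid]] <- ft
    objects[[fid]] <- res$foci
    label_maps[[fid]] <- res$clm
  }
  bind <- function(x) if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
  list(fields = bind(fields), cells = bind(cells), foci = bind(foci_tabs),
       objects = objects, label_maps = label_maps, errors = errors)
}

# one field through every stage
run_field <- function(iset, cfg, bank) {
  pp <- cfg$preprocessing
  nuc <- clip_intensity(iset$nuclear, pp$cap, quiet = TRUE)
  nuc <- contrast_stretch(nuc, pp$stretch_low, pp$stretch_high)
  foci_clip <- clip_intensity(iset$foci, pp$cap, quiet = TRUE)

  nmask <- make_nuclear_mask(nuc, cfg$segmentation$threshold_frac)
  if (isTRUE(attr(nmask, "empty"))) stop("no nuclei found")

  foci_seg <- wiener_denoise(foci_clip, pp$wiener_window)
  elev <- build_elevation(foci_seg, nmask, pp$gain)
  clm <- segment_cells(elev, nmask, iset$foci$pixel_size_um)

  fg <- cell_foreground(foci_seg, cfg$segmentation$foreground_frac)
  clm <- filter_small_cells(clm, cfg$segmentation$min_cell_area_um2, fg)

  det_img <- if (cfg$detection$use_preprocessed) foci_seg else foci_clip
  seeds <- detect_seeds(det_img, bank,
                        use_sharpened_pass = cfg$detection$use_sharpened_pass,
                        unsharp_alpha = pp$unsharp_alpha,
                        st_overrides = cfg$detection$st)
  seeds <- mask_seeds(seeds, nmask, fg)
  foci <- merge_seeds(seeds, iset$foci$pixel_size_um)
  foci <- filter_small_foci(foci, cfg$detection$min_focus_area_um2)
  w <- cfg$quantification$size_reliability_width_px
  for (i in seq_along(foci))
    foci[[i]]$size_reliable <- size_reliability(foci[[i]], w)
  foci <- assign_foci_to_cells(foci, clm)

  cells <- cell_records(clm, foci, cfg$quantification$min_foci_for_positive)
  summary <- summarize_field(cells, cfg$quantification$min_foci_for_positive,
                             foci = foci, field_id = iset$field_id)
  list(clm = clm, foci = foci, foci_table = foci_table(foci),
       cells = cells, summary = summary)
}

#' Summarise pipeline output per well and score a plate
#'
#' Groups the per-field summaries of [run_pipeline()] output by well using a
#' plate layout, pools them with [aggregate_well()] and scores each well
#' against the in-plate controls with [plate_report()].
#'
#' @param fields per-field summary data frame with a `well_id` column.
#' @param layout data frame: `plate_id`, `well_id`, `treatment`,
#'   `is_control`.
#' @param control_label treatment label of control wells.
#' @return scored well table from [plate_report()].
#' @export
score_plate <- function(fields, layout, control_label = "none") {
  wells <- lapply(seq_len(nrow(layout)), function(i) {
    fw <- fields[fields$well_id == layout$well_id[i], , drop = FALSE]
    if (nrow(fw) == 0) return(NULL)
    aggregate_well(fw, plate_id = layout$plate_id[i],
                   well_id = layout$well_id[i],
                   treatment = layout$treatment[i],
                   is_control = isTRUE(layout$is_control[i]))
  })
  wells <- do.call(rbind, wells)
  plate_report(wells, control_label = control_label)
}
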