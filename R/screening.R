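#' Pool field summaries into a well summary
#'
#' Cell and positive-cell counts are summed across the fields of a well and
#' the percentage of positive cells is computed on the pooled counts - a
#' cell-weighted percentage, not a mean of per-field percentages, because
#' fields of one well differ in cell number. Zero-cell fields contribute
#' nothing; a zero-cell well is flagged invalid.
#'
#' @param fields data frame of field summaries (rows from
#'   [summarize_field()]) belonging to one well.
#' @param plate_id,well_id,treatment,is_control well annotation.
#' @return one-row data frame (`well_summary`): counts, `pct_positive`,
#'   `mean_foci_per_positive_cell`, `valid` flag.
#' @export
aggregate_well <- function(fields, plate_id = "plate", well_id = "well",
                           treatment = "none", is_control = FALSE) {
  stopifnot(nrow(fields) >= 1)
  n_cells <- sum(fields$n_cells)
  n_pos <- sum(fields$n_positive_cells)
  # pooled foci-per-positive-cell: total foci in positive cells / positives
  foci_in_pos <- sum(fields$mean_foci_per_positive_cell *
                       fields$n_positive_cells, na.rm = TRUE)
  valid <- n_cells > 0
  if (!valid) warning("well ", well_id, " has zero cells across its fields")
  data.frame(
    plate_id = plate_id, well_id = well_id, treatment = treatment,
    is_control = is_control, n_fields = nrow(fields),
    n_cells = n_cells, n_positive_cells = n_pos,
    pct_positive = if (valid) 100 * n_pos / n_cells else NA_real_,
    mean_foci_per_positive_cell = if (n_pos > 0) foci_in_pos / n_pos else NA_real_,
    valid = valid)
}

#' Control-normalised screen score for one well
#'
#' The score is the ratio of the percentage of positive cells in the well to
#' the mean percentage of positive cells over the control wells of the same
#' plate. Scores near 1 mean no effect; below 1, impaired focus formation;
#' above 1, enhanced formation.
#'
#' @param well one-row well summary from [aggregate_well()].
#' @param controls data frame of control well summaries from the same plate.
#' @return one-row data frame: `plate_id`, `well_id`, `score`,
#'   `control_mean_pct`, `n_control_wells`.
#' @export
rnai_score <- function(well, controls) {
  stopifnot(nrow(well) == 1)
  if (nrow(controls) == 0) stop("no control wells on plate ", well$plate_id)
  if (!all(controls$plate_id == well$plate_id))
    stop("controls must come from the well's own plate")
  ctrl_mean <- mean(controls$pct_positive)
  score <- if (is.finite(ctrl_mean) && ctrl_mean > 0)
    well$pct_positive / ctrl_mean else NA_real_
  if (is.na(score)) warning("zero or undefined control mean on plate ",
                            well$plate_id)
  data.frame(plate_id = well$plate_id, well_id = well$well_id,
             score = score, control_mean_pct = ctrl_mean,
             n_control_wells = nrow(controls))
}

#' Score every well of a plate set against its in-plate controls
#'
#' @param wells data frame of well summaries ([aggregate_well()] rows).
#' @param control_label treatment label marking control wells when
#'   `is_control` is absent or all-`FALSE`; default `"none"`.
#' @return `wells` with `score`, `control_mean_pct` and `n_control_wells`
#'   columns added, ordered by (plate, well).
#' @export
plate_report <- function(wells, control_label = "none") {
  if (nrow(wells) == 0) {
    wells$score <- numeric(0)
    wells$control_mean_pct <- numeric(0)
    wells$n_control_wells <- integer(0)
    return(wells)
  }
  if (!"is_control" %in% names(wells) || !any(wells$is_control))
    wells$is_control <- wells$treatment == control_label
  out <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, , drop = FALSE]
    ctrl <- wells[wells$is_control & wells$plate_id == w$plate_id &
                    wells$valid, , drop = FALSE]
    sc <- rnai_score(w, ctrl)
    cbind(w, sc[, c("score", "control_mean_pct", "n_control_wells")])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plate_id, out$well_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
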