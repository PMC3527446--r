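#' Assign foci to segmented cells
#'
#' Each focus gets the cell label under its representative point. Foci on
#' watershed ridges or excluded basins (label 0) remain unassigned; they are
#' reported, not silently dropped.
#'
#' @param foci list of `focus` objects on the same pixel grid as `clm`.
#' @param clm a `cell_label_map`.
#' @return the focus list with `cell_id` filled in.
#' @export
assign_foci_to_cells <- function(foci, clm) {
  stopifnot(inherits(clm, "cell_label_map"))
  for (i in seq_along(foci)) {
    p <- foci[[i]]$point
    foci[[i]]$cell_id <- clm$labels[p[1], p[2]]
  }
  foci
}

#' Per-cell focus counts and positivity
#'
#' A cell is positive when it contains at least `min_foci_for_positive`
#' foci (default two or more).
#'
#' @param clm a `cell_label_map` (after [filter_small_cells()]).
#' @param foci list of assigned `focus` objects.
#' @param min_foci_for_positive positivity rule; default 2.
#' @return data frame with one row per cell (`cell_id`, `n_foci`,
#'   `positive`, `area_um2`), attribute `n_unassigned` counting foci with
#'   `cell_id` 0.
#' @export
cell_records <- function(clm, foci, min_foci_for_positive = 2L) {
  stopifnot(inherits(clm, "cell_label_map"), min_foci_for_positive >= 1L)
  ids <- clm$nuclei$cell_id
  cid <- vapply(foci, `[[`, 0L, "cell_id")
  n_foci <- vapply(ids, function(k) sum(cid == k), 0L)
  out <- data.frame(cell_id = ids, n_foci = n_foci,
                    positive = n_foci >= min_foci_for_positive,
                    area_um2 = if ("cell_area_um2" %in% names(clm$nuclei))
                      clm$nuclei$cell_area_um2 else clm$nuclei$basin_area_um2)
  attr(out, "n_unassigned") <- sum(cid == 0L | !(cid %in% ids))
  out
}

#' Field-level summary statistics
#'
#' Counts cells, foci and positive cells and reports the percentage of
#' positive cells and the mean number of foci per positive cell (means over
#' positive cells only). The mean focus area uses size-reliable objects only.
#'
#' @param cells data frame from [cell_records()].
#' @param min_foci_for_positive positivity rule; default 2 (re-applied so a
#'   summary can be recomputed under a different rule).
#' @param foci optional assigned focus list, for `n_foci` including
#'   unassigned objects and for the mean reliable focus area.
#' @param field_id identifier carried into the summary.
#' @return one-row data frame: `field_id`, `n_cells`, `n_foci`,
#'   `n_positive_cells`, `pct_positive`, `mean_foci_per_positive_cell`,
#'   `mean_focus_area_um2`.
#' @export
summarize_field <- function(cells, min_foci_for_positive = 2L, foci = NULL,
                            field_id = "field") {
  stopifnot(min_foci_for_positive >= 1L)
  n_cells <- nrow(cells)
  pos <- cells$n_foci >= min_foci_for_positive
  n_pos <- sum(pos)
  n_foci <- if (!is.null(foci)) length(foci) else sum(cells$n_foci)
  mean_area <- NA_real_
  if (!is.null(foci)) {
    rel <- Filter(function(f) isTRUE(f$size_reliable), foci)
    if (length(rel)) mean_area <- mean(vapply(rel, `[[`, 0, "area_um2"))
  }
  data.frame(
    field_id = field_id,
    n_cells = n_cells,
    n_foci = n_foci,
    n_positive_cells = n_pos,
    pct_positive = if (n_cells > 0) 100 * n_pos / n_cells else 0,
    mean_foci_per_positive_cell =
      if (n_pos > 0) sum(cells$n_foci[pos]) / n_pos else NA_real_,
    mean_focus_area_um2 = mean_area)
}

#' Nearest-focus distances from target objects
#'
#' Euclidean distance transform of the complement of the focus pixel mask
#' (distance of every pixel to the nearest focus pixel), sampled at each
#' target's representative point and converted to micrometres. A target
#' overlapping a focus has distance 0. Distances are point-to-object-mask,
#' matching distance-transform semantics, not centroid-to-centroid.
#'
#' @param targets list of `focus` objects (e.g. synapses).
#' @param foci list of `focus` objects (e.g. synaptic mRNA-silencing foci).
#' @param radius_um proximity radius; default 0.5.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param pixel_size_um physical pixel size.
#' @return list with `distances_um` (per target) and `fraction_within`
#'   (share of targets strictly closer than `radius_um`).
#' @export
nearest_object_distances <- function(targets, foci, radius_um = 0.5,
                                     dim, pixel_size_um) {
  stopifnot(radius_um > 0, pixel_size_um > 0)
  if (!length(targets))
    return(list(distances_um = numeric(0), fraction_within = 0))
  if (!length(foci))
    return(list(distances_um = rep(Inf, length(targets)), fraction_within = 0))
  mask <- matrix(1, dim[1], dim[2])
  for (f in foci) mask[f$pixel_idx] <- 0
  d <- EBImage::distmap(mask, metric = "euclidean")
  dist_um <- vapply(targets, function(t) d[t$point[1], t$point[2]], 0) *
    pixel_size_um
  list(distances_um = dist_um,
       fraction_within = mean(dist_um < radius_um))
}

#' Compare focus sizes between groups
#'
#' Mean focus area per named group (size-reliable objects only, by default)
#' and the ratio of each group mean to a reference group: the readout used
#' to show e.g. processing-body enlargement under oxidative stress.
#'
#' @param groups named list; each element a list of `focus` objects.
#' @param reference name of the reference group; default the first.
#' @param reliable_only use only size-reliable objects; default `TRUE`.
#' @return data frame with `group`, `n_objects`, `mean_area_um2`,
#'   `ratio_vs_reference`; groups with no usable objects get `NA` and a
#'   warning.
#' @export
size_change_report <- function(groups, reference = names(groups)[1],
                               reliable_only = TRUE) {
  stopifnot(length(groups) >= 1, reference %in% names(groups))
  means <- vapply(names(groups), function(g) {
    objs <- groups[[g]]
    if (reliable_only) objs <- Filter(function(f) isTRUE(f$size_reliable), objs)
    if (!length(objs)) {
      warning("group '", g, "' has no usable objects")
      return(NA_real_)
    }
    mean(vapply(objs, `[[`, 0, "area_um2"))
  }, 0)
  ns <- vapply(names(groups), function(g) {
    objs <- groups[[g]]
    if (reliable_only) objs <- Filter(function(f) isTRUE(f$size_reliable), objs)
    length(objs)
  }, 0L)
  data.frame(group = names(groups), n_objects = ns, mean_area_um2 = means,
             ratio_vs_reference = means / means[[reference]],
             row.names = NULL)
}
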