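#' Count PLA spots in a projected, background-corrected image
#'
#' The image is binarized at mean + `k_sd` * sd (the conventional
#' conversion of a projected PLA image to a binary image) and connected
#' components with areas inside `[min_area_px, max_area_px]` are counted;
#' the area filter removes single-pixel noise and large aggregates.
#'
#' @param projected 2-d background-corrected [mcs_image()].
#' @param k_sd Threshold stringency (default 4).
#' @param min_area_px,max_area_px Area filter bounds (defaults 2 and 100).
#' @return Integer spot count.
#' @export
count_pla_spots <- function(projected, k_sd = 4, min_area_px = 2,
                            max_area_px = 100) {
  stopifnot(inherits(projected, "mcs_image"),
            length(dim(projected$data)) == 2L)
  if (!projected$background_corrected)
    stop("count_pla_spots requires a background-corrected image")
  m <- projected$data
  if (all(m == m[1])) return(0L)
  thr <- mean(m) + k_sd * stats::sd(m)
  bin <- m > thr
  if (!any(bin)) return(0L)
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_area_px & sizes <= max_area_px)
}

#' Per-field PLA result
#'
#' @param n_spots,n_cells Spot and nucleus counts (`n_cells >= 1`).
#' @param field_id Field identifier.
#' @param condition Condition label.
#' @param experiment_id Optional matched-experiment identifier for
#'   repeated-measures designs.
#' @return A `field_result` list including `spots_per_cell`.
#' @export
field_result <- function(n_spots, n_cells, field_id = "field1",
                         condition = "control", experiment_id = NA) {
  if (n_cells < 1L) stop("a valid field requires n_cells >= 1")
  structure(list(n_spots = as.integer(n_spots), n_cells = as.integer(n_cells),
                 spots_per_cell = n_spots / n_cells,
                 field_id = field_id, condition = condition,
                 experiment_id = experiment_id),
            class = "field_result")
}

#' Analyze one PLA field of view
#'
#' Composes the quantification chain for a field: maximum z-projection of
#' the spot stack, background subtraction, spot counting, and nucleus
#' counting on the DAPI channel; reports spots per cell. A field with no
#' detected nuclei is an error (the field should be excluded and logged,
#' not scored 0/0).
#'
#' @param spot_stack PLA-channel [mcs_image()] (2-d or z-stack).
#' @param dapi DAPI-channel [mcs_image()].
#' @param bg_roi Background [mcs_mask()]; `NULL` (default) uses a 3-px
#'   border frame of the projected image.
#' @param field_id,condition,experiment_id Labels carried into the result.
#' @param spot_params,nuclei_params Named lists of overrides for
#'   [count_pla_spots()] and [count_nuclei()].
#' @return A [field_result()].
#' @export
analyze_field <- function(spot_stack, dapi, bg_roi = NULL,
                          field_id = "field1", condition = "control",
                          experiment_id = NA,
                          spot_params = list(), nuclei_params = list()) {
  proj <- max_z_project(spot_stack)
  if (is.null(bg_roi)) {
    m <- matrix(TRUE, nrow(proj$data), ncol(proj$data))
    m[4:(nrow(m) - 3), 4:(ncol(m) - 3)] <- FALSE
    bg_roi <- mcs_mask(m, proj$pixel_size_nm, "background")
  }
  corr <- subtract_background(proj, bg_roi)
  n_spots <- do.call(count_pla_spots, c(list(projected = corr), spot_params))
  nuc <- do.call(count_nuclei, c(list(dapi = dapi), nuclei_params))
  if (nuc$count == 0L)
    stop("no nuclei detected in field '", field_id, "': field excluded")
  field_result(n_spots, nuc$count, field_id, condition, experiment_id)
}

#' Collect field results into a tidy table
#'
#' @param fields List of [field_result()]s.
#' @return data.frame with one row per field.
#' @export
fields_table <- function(fields) {
  stopifnot(length(fields) > 0, all(vapply(fields, inherits, logical(1),
                                           "field_result")))
  do.call(rbind, lapply(fields, function(f)
    data.frame(field_id = f$field_id, condition = f$condition,
               experiment_id = f$experiment_id, n_spots = f$n_spots,
               n_cells = f$n_cells, spots_per_cell = f$spots_per_cell,
               stringsAsFactors = FALSE)))
}

#' Compare PLA conditions across fields
#'
#' The unit of analysis is the field (never pooled pixels or cells):
#' per-field spots-per-cell values are summarized as mean +/- s.e.m. per
#' condition and compared with [compare_groups()] (unpaired t-test for two
#' conditions, one-way ANOVA with Tukey for more, or repeated-measures
#' ANOVA with Bonferroni when `design = "rm_bonferroni"` and matched
#' experiment IDs are present).
#'
#' @param fields List of [field_result()]s (>= 2 conditions, >= 2 fields
#'   each).
#' @param design Passed to [compare_groups()]; `NULL` picks unpaired t for
#'   two conditions and one-way ANOVA + Tukey otherwise.
#' @return A `stats_result` (see [compare_groups()]); the tidy field table
#'   is attached as attribute `fields`.
#' @export
compare_conditions <- function(fields, design = NULL) {
  tab <- fields_table(fields)
  counts <- table(tab$condition)
  if (length(counts) < 2L) stop("need at least two conditions")
  if (any(counts < 2L)) stop("need at least two fields per condition")
  if (is.null(design))
    design <- if (length(counts) == 2L) "two_group_unpaired" else "oneway_tukey"
  res <- compare_groups(values = tab$spots_per_cell, groups = tab$condition,
                        design = design, replicate_id = tab$experiment_id)
  attr(res, "fields") <- tab
  res
}
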