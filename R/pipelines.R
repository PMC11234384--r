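#' Default pipeline configuration
#'
#' One nested list drives all three analysis tracks (colocalization, PLA,
#' calcium). A single global seed is fanned out deterministically to every
#' stochastic stage, so reruns of an individual stage are independently
#' reproducible. The configuration round-trips losslessly through YAML
#' ([save_config()] / [load_config()]).
#'
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(width_px = 256L, height_px = 256L, pixel_size_nm = 77.7,
                 psf_sigma_nm = 100, gaussian_sd = 2, poisson_scaling = 1),
    coloc = list(n_cells = 3L, n_ref = 200L, n_partner = 200L,
                 f_coloc = 0.3, f_mito = 0.25, offset_sigma_nm = 50,
                 min_spacing_nm = 466, threshold_nm = 233,
                 mito_area_frac = 0.25, amplitude = 1000,
                 detection = list(k_sd = 3, min_area_px = 4,
                                  min_separation_px = 3),
                 dilate_px = 1L, hist_bin_nm = 100),
    randomization = list(n_iter = 100L),
    pla = list(n_cells = 10L, n_fields = 8L,
               conditions = list(control = 20, knockdown = 10),
               k_sd = 4, min_area_px = 2, max_area_px = 100),
    calcium = list(n_cells_per_condition = 10L, n_frames = 180L,
                   frame_interval_s = 1, stim_frame = 30L,
                   fmax_frame = 150L, noise_sd_frac = 0.02,
                   baseline_window = c(1L, 29L),
                   response_window = c(30L, 120L),
                   fmax_window = c(155L, 180L),
                   conditions = list(
                     control = list(cyto_peak = 0.45, mito_peak = 0.40,
                                    baseline = 0.10),
                     knockdown = list(cyto_peak = 0.12, mito_peak = 0.11,
                                      baseline = 0.10)))
  ), class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (save) or the `pipeline_config` (load).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

report_header <- function(config) {
  list(package = "mcsquant",
       version = as.character(utils::packageVersion("mcsquant")),
       seed = config$seed,
       config_hash = rlang::hash(unclass(config)))
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# Simulate one colocalization scene, detect puncta in both channels,
# segment mitochondria, and run the mask-restricted NND + shuffle analyses.
analyze_coloc_cell <- function(config, cell_seed, cell_id) {
  sc <- config$scene
  spec <- scene_spec(sc$width_px, sc$height_px, sc$pixel_size_nm,
                     sc$psf_sigma_nm, sc$gaussian_sd, sc$poisson_scaling,
                     seed = cell_seed)
  cl <- config$coloc
  masks <- make_cell_and_mito_masks(spec, cl$mito_area_frac)
  truth <- place_puncta(masks$cell, masks$mito, cl$n_ref, cl$n_partner,
                        cl$f_coloc, cl$f_mito, cl$offset_sigma_nm,
                        cl$min_spacing_nm, seed = derive_seed(cell_seed, 2L))
  img_ref <- render_channel(truth$ref$x_nm, truth$ref$y_nm, spec,
                            amplitudes = cl$amplitude, channel = "ref",
                            noise_seed = derive_seed(cell_seed, 3L))
  img_par <- render_channel(truth$partner$x_nm, truth$partner$y_nm, spec,
                            amplitudes = cl$amplitude, channel = "partner",
                            noise_seed = derive_seed(cell_seed, 4L))
  img_mito <- render_mask_channel(masks$mito, spec,
                                  noise_seed = derive_seed(cell_seed, 5L))
  bg <- border_bg_roi(spec)
  det <- cl$detection
  pf_ref <- detect_puncta(subtract_background(img_ref, bg),
                          sigma_nm = spec$psf_sigma_nm, k_sd = det$k_sd,
                          min_area_px = det$min_area_px,
                          min_separation_px = det$min_separation_px)
  pf_par <- detect_puncta(subtract_background(img_par, bg),
                          sigma_nm = spec$psf_sigma_nm, k_sd = det$k_sd,
                          min_area_px = det$min_area_px,
                          min_separation_px = det$min_separation_px)
  mito_mask <- make_organelle_mask(subtract_background(img_mito, bg),
                                   cell = masks$cell)
  parts <- subset_by_mask(pf_ref, mito_mask, dilate_px = cl$dilate_px)
  run_rand <- function(ref_pf) {
    if (n_puncta(ref_pf) == 0L) return(NULL)
    randomization_test(ref_pf, pf_par, masks$cell, cl$threshold_nm,
                       config$randomization$n_iter,
                       seed = derive_seed(cell_seed, 6L))
  }
  rt_mito <- run_rand(parts$inside)
  rt_nonmito <- run_rand(parts$outside)
  rt_all <- run_rand(pf_ref)
  list(cell_id = cell_id, truth = truth, masks = masks,
       mito_mask = mito_mask, pf_ref = pf_ref, pf_partner = pf_par,
       parts = parts, rt_mito = rt_mito, rt_nonmito = rt_nonmito,
       rt_all = rt_all)
}

border_bg_roi <- function(spec) {
  m <- matrix(TRUE, spec$height_px, spec$width_px)
  m[4:(spec$height_px - 3), 4:(spec$width_px - 3)] <- FALSE
  mcs_mask(m, spec$pixel_size_nm, "background")
}

rand_summary <- function(rt) {
  if (is.null(rt)) return(NULL)
  list(observed_fraction = rt$observed_fraction,
       null_mean = mean(rt$null_fractions),
       null_sd = stats::sd(rt$null_fractions),
       ci_low = rt$ci_low, ci_high = rt$ci_high,
       significant = rt$significant, n_iter = rt$n_iter)
}

#' Run the object-colocalization analysis track
#'
#' Simulates `n_cells` scenes with the configured ground truth, detects
#' puncta in both channels, segments the mitochondrial mask, partitions
#' reference puncta into mitochondria-associated and non-associated
#' subsets, and runs the nearest-neighbour colocalization analysis with
#' the shuffle null on each subset. Writes per-punctum and per-cell CSVs,
#' nearest-neighbour distance histograms and a JSON report embedding the
#' seed, config hash and package version.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if missing).
#' @return The per-cell summary data.frame, invisibly.
#' @export
run_coloc_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- config$coloc
  cells <- lapply(seq_len(cl$n_cells), function(i)
    analyze_coloc_cell(config, derive_seed(config$seed, 100L + i),
                       sprintf("cell%02d", i)))
  per_cell <- do.call(rbind, lapply(cells, function(x) data.frame(
    cell_id = x$cell_id,
    n_ref_detected = n_puncta(x$pf_ref),
    n_partner_detected = n_puncta(x$pf_partner),
    n_ref_mito = n_puncta(x$parts$inside),
    fraction_mito = if (n_puncta(x$pf_ref)) mean(x$parts$inside_flag) else NA,
    fraction_coloc_mito =
      if (is.null(x$rt_mito)) NA else x$rt_mito$observed_fraction,
    fraction_coloc_nonmito =
      if (is.null(x$rt_nonmito)) NA else x$rt_nonmito$observed_fraction,
    null_mean_mito =
      if (is.null(x$rt_mito)) NA else mean(x$rt_mito$null_fractions),
    significant_mito = if (is.null(x$rt_mito)) NA else x$rt_mito$significant,
    stringsAsFactors = FALSE)))
  utils::write.csv(per_cell, file.path(out_dir, "coloc_per_cell.csv"),
                   row.names = FALSE)
  per_punctum <- do.call(rbind, lapply(cells, function(x) {
    if (n_puncta(x$pf_ref) == 0L) return(NULL)
    nn <- x$rt_all$observed_nnd
    data.frame(cell_id = x$cell_id, ref_id = seq_along(nn$distances_nm),
               nnd_nm = nn$distances_nm, partner_id = nn$partner_idx,
               colocalized = nn$colocalized,
               in_mito_mask = x$parts$inside_flag,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(per_punctum, file.path(out_dir, "coloc_per_punctum.csv"),
                   row.names = FALSE)
  hists <- do.call(rbind, lapply(cells, function(x) {
    if (is.null(x$rt_all)) return(NULL)
    h <- nnd_histogram(x$rt_all$observed_nnd, cl$hist_bin_nm)
    cbind(cell_id = x$cell_id, h)
  }))
  utils::write.csv(hists, file.path(out_dir, "nnd_histograms.csv"),
                   row.names = FALSE)
  report <- c(report_header(config), list(
    track = "coloc",
    cells = lapply(cells, function(x) list(
      cell_id = x$cell_id,
      mito_associated = rand_summary(x$rt_mito),
      non_associated = rand_summary(x$rt_nonmito),
      all_ref = rand_summary(x$rt_all)))))
  write_report_json(report, file.path(out_dir, "coloc_report.json"))
  invisible(per_cell)
}

#' Run the PLA analysis track
#'
#' Simulates fields for each configured condition (Poisson spot counts per
#' cell), quantifies each field (projection, background subtraction, spot
#' and nucleus counting) and compares conditions on per-field
#' spots-per-cell values. Fields failing quantification (no nuclei) are
#' excluded and logged in the report.
#'
#' @inheritParams run_coloc_pipeline
#' @return The tidy fields data.frame, invisibly.
#' @export
run_pla_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pl <- config$pla
  sc <- config$scene
  fields <- list(); excluded <- list()
  k <- 0L
  for (cond in names(pl$conditions)) {
    for (f in seq_len(pl$n_fields)) {
      k <- k + 1L
      fseed <- derive_seed(config$seed, 200L + k)
      spec <- scene_spec(sc$width_px, sc$height_px, sc$pixel_size_nm,
                         sc$psf_sigma_nm, sc$gaussian_sd,
                         sc$poisson_scaling, seed = fseed)
      scn <- make_pla_scene(pl$n_cells, pl$conditions[[cond]], spec,
                            seed = fseed)
      fid <- sprintf("%s_field%02d", cond, f)
      res <- tryCatch(
        analyze_field(scn$spots, scn$dapi, field_id = fid, condition = cond,
                      experiment_id = f,
                      spot_params = list(k_sd = pl$k_sd,
                                         min_area_px = pl$min_area_px,
                                         max_area_px = pl$max_area_px)),
        error = function(e) conditionMessage(e))
      if (inherits(res, "field_result")) fields[[fid]] <- res
      else excluded[[fid]] <- res
    }
  }
  tab <- fields_table(fields)
  utils::write.csv(tab, file.path(out_dir, "pla_fields.csv"),
                   row.names = FALSE)
  stats_res <- compare_conditions(unname(fields))
  report <- c(report_header(config), list(
    track = "pla",
    summary = stats_res$summary,
    omnibus_p = stats_res$omnibus_p,
    pairwise = stats_res$pairwise,
    method = stats_res$method,
    excluded_fields = excluded))
  write_report_json(report, file.path(out_dir, "pla_report.json"))
  invisible(tab)
}

#' Run the calcium analysis track
#'
#' Simulates dual-indicator trace pairs per condition, normalizes each
#' trace to its saturated plateau (F/F_max), extracts peak responses
#' (dF/F_max) and compares conditions per channel.
#'
#' @inheritParams run_coloc_pipeline
#' @return The tidy per-cell data.frame, invisibly.
#' @export
run_calcium_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ca <- config$calcium
  rows <- list(); k <- 0L
  for (cond in names(ca$conditions)) {
    cc <- ca$conditions[[cond]]
    for (i in seq_len(ca$n_cells_per_condition)) {
      k <- k + 1L
      cs <- derive_seed(config$seed, 300L + k)
      mk_spec <- function(peak, seed) calcium_trace_spec(
        n_frames = ca$n_frames, frame_interval_s = ca$frame_interval_s,
        baseline_frac = cc$baseline, peak_frac = peak,
        stim_frame = ca$stim_frame, fmax_frame = ca$fmax_frame,
        noise_sd_frac = ca$noise_sd_frac, seed = seed)
      pair <- make_calcium_trace_pair(
        mk_spec(cc$cyto_peak, derive_seed(cs, 1L)),
        mk_spec(cc$mito_peak, derive_seed(cs, 2L)),
        roi_id = sprintf("%s_cell%02d", cond, i))
      for (ch in c("cyto", "mito")) {
        q <- quantify_trace(pair[[ch]], ca$baseline_window,
                            ca$response_window, ca$fmax_window)
        q$condition <- cond
        q$cell <- i
        rows[[length(rows) + 1L]] <- q
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "calcium_per_cell.csv"),
                   row.names = FALSE)
  by_channel <- lapply(split(tab, tab$channel), function(d) {
    res <- compare_groups(d$delta_f_over_fmax, d$condition,
                          design = if (length(unique(d$condition)) == 2L)
                            "two_group_unpaired" else "oneway_tukey")
    list(summary = res$summary, omnibus_p = res$omnibus_p,
         pairwise = res$pairwise, method = res$method)
  })
  report <- c(report_header(config),
              list(track = "calcium", by_channel = by_channel))
  write_report_json(report, file.path(out_dir, "calcium_report.json"))
  invisible(tab)
}

#' Run all three analysis tracks
#'
#' @inheritParams run_coloc_pipeline
#' @return NULL, invisibly; reports are written under
#'   `out_dir/{coloc,pla,calcium}`.
#' @export
run_all_pipelines <- function(config, out_dir) {
  run_coloc_pipeline(config, file.path(out_dir, "coloc"))
  run_pla_pipeline(config, file.path(out_dir, "pla"))
  run_calcium_pipeline(config, file.path(out_dir, "calcium"))
  invisible(NULL)
}
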