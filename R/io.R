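#' Write a multichannel scene to TIFF with a JSON ground-truth sidecar
#'
#' Each channel is stored as one page of a multipage 32-bit float TIFF,
#' scaled to [0, 1]; per-channel scale factors, pixel size and channel
#' labels go into the JSON sidecar together with any ground truth, so the
#' scene round-trips losslessly to working precision.
#'
#' @param images Named list of 2-d [mcs_image()]s (shared geometry).
#' @param path Output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param truth Optional ground-truth list to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(images, path, truth = NULL) {
  stopifnot(length(images) > 0, !is.null(names(images)))
  scales <- vapply(images, function(im) max(im$data, 1e-12), numeric(1))
  pages <- mapply(function(im, s) pmin(pmax(im$data / s, 0), 1),
                  images, scales, SIMPLIFY = FALSE)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L)
  meta <- list(channels = names(images),
               scale = as.list(scales),
               pixel_size_nm = images[[1]]$pixel_size_nm,
               background_corrected = lapply(images, function(im)
                 im$background_corrected),
               truth = truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scene written by [write_scene_tiff()]
#'
#' @param path TIFF path (sidecar expected at `paste0(path, ".json")`).
#' @return A list: `images` (named list of [mcs_image()]s) and `truth`.
#' @export
read_scene_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  images <- stats::setNames(lapply(seq_along(pages), function(i) {
    mcs_image(pages[[i]] * meta$scale[[i]], meta$pixel_size_nm,
              channel = meta$channels[i],
              background_corrected =
                isTRUE(meta$background_corrected[[i]]))
  }), meta$channels)
  list(images = images, truth = meta$truth)
}

#' Write a puncta field to CSV
#'
#' Columns: `x_nm`, `y_nm`, `intensity`, `area_px`.
#' @param puncta A [puncta_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(puncta, path) {
  stopifnot(inherits(puncta, "puncta_field"))
  utils::write.csv(data.frame(x_nm = puncta$x_nm, y_nm = puncta$y_nm,
                              intensity = puncta$intensity,
                              area_px = puncta$area_px),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a puncta field from CSV
#' @param path CSV path written by [write_puncta_csv()].
#' @param channel,pixel_size_nm Metadata not stored in the CSV.
#' @return A [puncta_field()].
#' @export
read_puncta_csv <- function(path, channel = "unknown", pixel_size_nm = 77.7) {
  d <- utils::read.csv(path)
  puncta_field(d$x_nm, d$y_nm, d$intensity, d$area_px,
               channel = channel, pixel_size_nm = pixel_size_nm)
}

#' Write a cytosolic/mitochondrial trace pair to CSV
#'
#' Columns: `frame`, `time_s`, `F_cyto`, `F_mito`.
#' @param pair List with `cyto` and `mito` [mcs_trace()]s on a common time
#'   base.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_pair_csv <- function(pair, path) {
  stopifnot(identical(pair$cyto$time_s, pair$mito$time_s))
  utils::write.csv(data.frame(frame = seq_along(pair$cyto$time_s),
                              time_s = pair$cyto$time_s,
                              F_cyto = pair$cyto$F,
                              F_mito = pair$mito$F),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trace pair written by [write_trace_pair_csv()]
#' @param path CSV path.
#' @param roi_id Cell identifier to attach.
#' @return List with `cyto` and `mito` [mcs_trace()]s.
#' @export
read_trace_pair_csv <- function(path, roi_id = "cell1") {
  d <- utils::read.csv(path)
  list(cyto = mcs_trace(d$time_s, d$F_cyto, roi_id, "cytosolic"),
       mito = mcs_trace(d$time_s, d$F_mito, roi_id, "mitochondrial"))
}
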