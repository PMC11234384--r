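#' Subtract background measured outside the cell
#'
#' Implements the standard background correction for fluorescence images:
#' the mean intensity over a region outside the cell is subtracted from the
#' whole image and the result is clipped at zero. For 3-d stacks the
#' background mean is computed and subtracted per plane.
#'
#' @param img An [mcs_image()].
#' @param bg_roi Background [mcs_mask()] (must be non-empty).
#' @param cell_mask Optional cell [mcs_mask()]; if supplied, `bg_roi` must
#'   not overlap it.
#' @return A background-corrected [mcs_image()].
#' @export
subtract_background <- function(img, bg_roi, cell_mask = NULL) {
  stopifnot(inherits(img, "mcs_image"), inherits(bg_roi, "mcs_mask"))
  if (!any(bg_roi$data)) stop("background ROI is empty")
  if (!is.null(cell_mask) && any(bg_roi$data & cell_mask$data))
    stop("background ROI overlaps the cell mask")
  d <- img$data
  if (length(dim(d)) == 2L) {
    out <- pmax(d - mean(d[bg_roi$data]), 0)
  } else {
    out <- d
    for (k in seq_len(dim(d)[3])) {
      plane <- d[, , k]
      out[, , k] <- pmax(plane - mean(plane[bg_roi$data]), 0)
    }
  }
  mcs_image(out, img$pixel_size_nm, channel = img$channel,
            background_corrected = TRUE)
}

# 8-neighbourhood local maxima of a matrix (strictly >= all neighbours,
# with the raster-order first pixel winning inside flat plateaus).
local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  ge <- matrix(TRUE, h, w)
  gt_earlier <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    if (dr < 0L || (dr == 0L && dc < 0L)) {
      gt_earlier <- gt_earlier & (m > nb)   # strict vs earlier pixels
    } else {
      ge <- ge & (m >= nb)                  # ties allowed vs later pixels
    }
  }
  ge & gt_earlier
}

#' Detect diffraction-limited puncta
#'
#' Spot segmentation by Gaussian smoothing at the PSF scale followed by a
#' global mean + k*sd threshold on the smoothed image, connected-component
#' labelling, and splitting of touching spots when a component contains two
#' or more local maxima separated by at least `min_separation_px`
#' (non-maximum suppression keeps the brighter maximum on conflicts; split
#' pixels are assigned to the nearest surviving maximum). Centroids are
#' intensity-weighted on the background-corrected image and reported in nm
#' using the 0-based-pixel-centre convention.
#'
#' @param img Background-corrected [mcs_image()] (2-d).
#' @param sigma_nm Detection scale; defaults to 100 nm (diffraction-limited
#'   PSF sd).
#' @param k_sd Threshold stringency: threshold = mean + `k_sd` * sd of the
#'   smoothed image (default 3).
#' @param min_area_px Minimum supra-threshold area per spot (default 4).
#' @param min_separation_px Minimum separation of local maxima before a
#'   component is split (default 3).
#' @return A [puncta_field()] (possibly empty).
#' @export
detect_puncta <- function(img, sigma_nm = 100, k_sd = 3, min_area_px = 4,
                          min_separation_px = 3) {
  stopifnot(inherits(img, "mcs_image"), length(dim(img$data)) == 2L)
  if (!img$background_corrected)
    stop("detect_puncta requires a background-corrected image")
  psz <- img$pixel_size_nm
  raw <- img$data
  empty <- puncta_field(numeric(), numeric(), numeric(), numeric(),
                        channel = img$channel, pixel_size_nm = psz)
  if (all(raw == 0)) return(empty)
  sig_px <- sigma_nm / psz
  sm <- if (sig_px > 0) as.matrix(EBImage::gblur(raw, sigma = sig_px)) else raw
  thr <- mean(sm) + k_sd * stats::sd(sm)
  bin <- sm > thr
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(raw), ncol(raw))
  nlab <- max(lab)

  mx <- local_maxima(sm) & bin
  ids <- lab
  next_id <- nlab
  # split components holding >= 2 well-separated maxima
  mx_idx <- which(mx)
  if (length(mx_idx)) {
    mx_lab <- lab[mx_idx]
    multi <- as.integer(names(which(table(mx_lab) > 1L)))
    for (l in multi) {
      pk <- mx_idx[mx_lab == l]
      ord <- order(sm[pk], decreasing = TRUE)
      pk <- pk[ord]
      pr <- (pk - 1L) %% nrow(raw); pc <- (pk - 1L) %/% nrow(raw)
      keep <- logical(length(pk))
      for (i in seq_along(pk)) {
        if (!any(keep)) { keep[i] <- TRUE; next }
        d2 <- (pr[keep] - pr[i])^2 + (pc[keep] - pc[i])^2
        if (min(d2) >= min_separation_px^2) keep[i] <- TRUE
      }
      if (sum(keep) < 2L) next
      kr <- pr[keep]; kc <- pc[keep]
      comp <- which(lab == l)
      cr <- (comp - 1L) %% nrow(raw); cc <- (comp - 1L) %/% nrow(raw)
      d2m <- outer(cr, kr, function(a, b) (a - b)^2) +
             outer(cc, kc, function(a, b) (a - b)^2)
      assign_k <- max.col(-d2m, ties.method = "first")
      for (k in seq_along(kr)) {
        if (k == 1L) next
        sel <- comp[assign_k == k]
        next_id <- next_id + 1L
        ids[sel] <- next_id
      }
    }
  }

  sel <- which(ids > 0L)
  g <- ids[sel]
  wts <- raw[sel]
  r0 <- (sel - 1L) %% nrow(raw)      # 0-based row = y
  c0 <- (sel - 1L) %/% nrow(raw)     # 0-based col = x
  area <- rowsum(rep(1, length(sel)), g)
  isum <- rowsum(wts, g)
  xw <- rowsum(wts * c0, g)
  yw <- rowsum(wts * r0, g)
  ok <- area[, 1] >= min_area_px & isum[, 1] > 0
  if (!any(ok)) return(empty)
  puncta_field(x_nm = (xw[ok, 1] / isum[ok, 1]) * psz,
               y_nm = (yw[ok, 1] / isum[ok, 1]) * psz,
               intensity = isum[ok, 1], area_px = area[ok, 1],
               channel = img$channel, pixel_size_nm = psz)
}

otsu_threshold <- function(m, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(m) else m[mask]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[2])
  scaled <- (v - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1L)),
                       range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

#' Segment an organelle (mitochondria) mask
#'
#' Gaussian smoothing followed by Otsu thresholding (computed within the
#' cell mask when one is given) and removal of objects smaller than
#' `min_object_px`.
#'
#' @param img Background-corrected organelle-channel [mcs_image()].
#' @param smoothing_sigma_px Smoothing sd in px (default 1.5).
#' @param threshold_mode "otsu" (default) or "mean_sd".
#' @param k_sd Stringency for `threshold_mode = "mean_sd"`.
#' @param min_object_px Minimum object size kept (default 20).
#' @param cell Optional cell [mcs_mask()] restricting the analysis.
#' @return An [mcs_mask()] of kind "mitochondria".
#' @export
make_organelle_mask <- function(img, smoothing_sigma_px = 1.5,
                                threshold_mode = c("otsu", "mean_sd"),
                                k_sd = 2, min_object_px = 20,
                                cell = NULL) {
  stopifnot(inherits(img, "mcs_image"), length(dim(img$data)) == 2L)
  if (!img$background_corrected)
    stop("make_organelle_mask requires a background-corrected image")
  threshold_mode <- match.arg(threshold_mode)
  m <- img$data
  empty <- mcs_mask(matrix(FALSE, nrow(m), ncol(m)), img$pixel_size_nm,
                    "mitochondria")
  if (all(m == 0)) return(empty)
  sm <- if (smoothing_sigma_px > 0)
    as.matrix(EBImage::gblur(m, sigma = smoothing_sigma_px)) else m
  cm <- if (is.null(cell)) NULL else cell$data
  thr <- if (threshold_mode == "otsu") otsu_threshold(sm, cm)
         else {
           v <- if (is.null(cm)) as.numeric(sm) else sm[cm]
           mean(v) + k_sd * stats::sd(v)
         }
  bin <- sm > thr
  if (!is.null(cm)) bin <- bin & cm
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_px)
  mcs_mask(matrix(lab %in% keep, nrow(m), ncol(m)), img$pixel_size_nm,
           "mitochondria")
}

#' Count nuclei in a DAPI image
#'
#' Smooths the nuclear channel, thresholds (Otsu by default), labels
#' connected components and counts those passing the size filter. Nuclei
#' closer than roughly one diameter can merge into a single object after
#' smoothing; this undercounting is an accepted limitation of
#' connected-component counting.
#'
#' @param dapi DAPI-channel [mcs_image()] (2-d).
#' @param smoothing_sigma_px Smoothing sd in px (default 2).
#' @param threshold_mode "otsu" (default) or "mean_sd".
#' @param k_sd Stringency for `threshold_mode = "mean_sd"`.
#' @param min_object_px Minimum nuclear area in px (default 50).
#' @return A list with `count` (integer) and `mask` (nuclei [mcs_mask()]).
#' @export
count_nuclei <- function(dapi, smoothing_sigma_px = 2,
                         threshold_mode = c("otsu", "mean_sd"), k_sd = 4,
                         min_object_px = 50) {
  stopifnot(inherits(dapi, "mcs_image"), length(dim(dapi$data)) == 2L)
  threshold_mode <- match.arg(threshold_mode)
  m <- dapi$data
  empty <- list(count = 0L,
                mask = mcs_mask(matrix(FALSE, nrow(m), ncol(m)),
                                dapi$pixel_size_nm, "nuclei"))
  if (all(m == m[1])) return(empty)
  sm <- if (smoothing_sigma_px > 0)
    as.matrix(EBImage::gblur(m, sigma = smoothing_sigma_px)) else m
  thr <- if (threshold_mode == "otsu") otsu_threshold(sm)
         else mean(sm) + k_sd * stats::sd(sm)
  bin <- sm > thr
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_px)
  list(count = length(keep),
       mask = mcs_mask(matrix(lab %in% keep, nrow(m), ncol(m)),
                       dapi$pixel_size_nm, "nuclei"))
}

#' Maximum-intensity z-projection
#'
#' @param stack An [mcs_image()] whose data is a (y, x, z) array; a 2-d
#'   image is returned unchanged.
#' @return A 2-d [mcs_image()] of per-pixel maxima across z.
#' @export
max_z_project <- function(stack) {
  stopifnot(inherits(stack, "mcs_image"))
  d <- stack$data
  if (length(dim(d)) == 2L) return(stack)
  if (dim(d)[3] < 1L) stop("empty stack")
  proj <- apply(d, c(1, 2), max)
  mcs_image(proj, stack$pixel_size_nm, channel = stack$channel,
            background_corrected = stack$background_corrected)
}
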