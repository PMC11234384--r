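#' Extract a background-corrected ROI trace from a time-lapse stack
#'
#' Per-frame mean over the ROI minus the per-frame mean over the
#' background region, clipped at zero.
#'
#' @param stack [mcs_image()] with data (y, x, t).
#' @param roi Non-empty ROI [mcs_mask()] (the cell).
#' @param bg_roi Background [mcs_mask()] outside the cell.
#' @param frame_interval_s Sampling interval in seconds (default 1).
#' @param roi_id,channel Labels for the resulting trace.
#' @return An [mcs_trace()].
#' @export
extract_trace <- function(stack, roi, bg_roi, frame_interval_s = 1,
                          roi_id = "cell1", channel = "cytosolic") {
  stopifnot(inherits(stack, "mcs_image"), inherits(roi, "mcs_mask"),
            inherits(bg_roi, "mcs_mask"))
  d <- stack$data
  if (length(dim(d)) == 2L) d <- array(d, c(dim(d), 1L))
  if (!any(roi$data)) stop("ROI is empty")
  if (!any(bg_roi$data)) stop("background ROI is empty")
  nt <- dim(d)[3]
  Fv <- vapply(seq_len(nt), function(k) {
    plane <- d[, , k]
    max(mean(plane[roi$data]) - mean(plane[bg_roi$data]), 0)
  }, numeric(1))
  mcs_trace((seq_len(nt) - 1) * frame_interval_s, Fv, roi_id, channel)
}

# Boxcar smoothing with shrinking windows at the edges (window = odd width).
boxcar <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Normalize a trace to its saturated fluorescence (F/F_max)
#'
#' F_max is the saturated-indicator plateau reached at the end of the
#' protocol (pharmacological saturation of the indicator). It is estimated
#' as the mean of the top decile of the lightly smoothed plateau window —
#' robust to single-frame outliers without the upward bias a raw
#' order-statistic estimate would acquire from frame noise. The window
#' must actually contain the saturated plateau: if its estimate falls below
#' the pre-window maximum by more than `tol_frac`, the window is rejected.
#'
#' @param trace An [mcs_trace()].
#' @param fmax_window Integer frame range `c(first, last)` (>= 3 frames).
#' @param smooth_frames Boxcar width used before the top-decile estimate
#'   (default 3).
#' @param tol_frac Allowed fractional shortfall of the plateau below the
#'   earlier trace maximum (default 0.05).
#' @return A `norm_trace`: `F_over_Fmax`, `F_max`, `time_s`,
#'   `fmax_window`, `roi_id`, `channel`.
#' @export
normalize_fmax <- function(trace, fmax_window, smooth_frames = 3L,
                           tol_frac = 0.05) {
  stopifnot(inherits(trace, "mcs_trace"), length(fmax_window) == 2L)
  n <- length(trace$F)
  w <- as.integer(fmax_window)
  if (w[1] < 1L || w[2] > n || w[2] - w[1] + 1L < 3L)
    stop("fmax_window must lie within the trace and span >= 3 frames")
  seg <- boxcar(trace$F[w[1]:w[2]], smooth_frames)
  k <- max(1L, ceiling(0.1 * length(seg)))
  f_max <- mean(sort(seg, decreasing = TRUE)[seq_len(k)])
  if (f_max <= 0) stop("invalid F_max window: non-positive plateau")
  outside <- setdiff(seq_len(n), w[1]:w[2])
  if (length(outside)) {
    other_max <- max(boxcar(trace$F, smooth_frames)[outside])
    if (f_max < other_max * (1 - tol_frac))
      stop("invalid F_max window: plateau below the trace maximum; the ",
           "window does not contain the saturated signal")
  }
  structure(list(F_over_Fmax = trace$F / f_max, F_max = f_max,
                 time_s = trace$time_s, fmax_window = w,
                 roi_id = trace$roi_id, channel = trace$channel),
            class = "norm_trace")
}

#' Peak stimulus-evoked change in normalized fluorescence (dF/F_max)
#'
#' The baseline is the mean of F/F_max over the pre-stimulus window; the
#' peak is the maximum of the boxcar-smoothed trace over the response
#' window (smoothing suppresses the upward noise-selection bias of a raw
#' per-frame maximum). The returned value is peak minus baseline. A
#' linearity flag is raised when the peak exceeds 50% of F_max, the regime
#' boundary beyond which fluorescence changes can no longer be assumed
#' approximately linear in calcium concentration.
#'
#' @param norm A `norm_trace`.
#' @param baseline_window,response_window Integer frame ranges
#'   `c(first, last)`; must be disjoint, response after baseline.
#' @param smooth_frames Boxcar width for the peak search (default 3).
#' @return The peak dF/F_max (numeric scalar) with attributes `baseline`,
#'   `peak`, and `linearity_flag`.
#' @export
peak_delta <- function(norm, baseline_window, response_window,
                       smooth_frames = 3L) {
  stopifnot(inherits(norm, "norm_trace"),
            length(baseline_window) == 2L, length(response_window) == 2L)
  b <- as.integer(baseline_window); r <- as.integer(response_window)
  n <- length(norm$F_over_Fmax)
  if (b[1] < 1L || r[2] > n || b[1] > b[2] || r[1] > r[2])
    stop("windows must be valid frame ranges inside the trace")
  if (r[1] <= b[2]) stop("response window must start after the baseline window")
  baseline <- mean(norm$F_over_Fmax[b[1]:b[2]])
  sm <- boxcar(norm$F_over_Fmax[r[1]:r[2]], smooth_frames)
  peak <- max(sm)
  delta <- peak - baseline
  structure(delta, baseline = baseline, peak = peak,
            linearity_flag = peak > 0.5)
}

#' Baseline drift diagnostic
#'
#' Fits a line to the baseline window and warns when the per-frame slope
#' (as a fraction of the baseline mean) exceeds `max_slope_frac`.
#'
#' @param norm A `norm_trace`.
#' @param baseline_window Integer frame range.
#' @param max_slope_frac Tolerated fractional slope per frame
#'   (default 0.002).
#' @return TRUE (drift flagged) or FALSE, invisibly.
#' @export
check_baseline_drift <- function(norm, baseline_window,
                                 max_slope_frac = 0.002) {
  b <- as.integer(baseline_window)
  y <- norm$F_over_Fmax[b[1]:b[2]]
  if (length(y) < 3L) return(invisible(FALSE))
  slope <- stats::coef(stats::lm(y ~ seq_along(y)))[2]
  drift <- abs(slope) > max_slope_frac * max(mean(y), 1e-12)
  if (drift)
    warning("baseline drift exceeds ", max_slope_frac, " per frame for ROI ",
            norm$roi_id)
  invisible(drift)
}

#' Quantify one synthetic or measured trace end to end
#'
#' Convenience wrapper: [normalize_fmax()] then [peak_delta()], returning a
#' one-row data.frame ready for [compare_groups()].
#'
#' @param trace An [mcs_trace()].
#' @param baseline_window,response_window,fmax_window Frame ranges.
#' @param ... Passed to [peak_delta()].
#' @return data.frame with `roi_id`, `channel`, `delta_f_over_fmax`,
#'   `f_max`, `baseline`, `peak`, `linearity_flag`.
#' @export
quantify_trace <- function(trace, baseline_window, response_window,
                           fmax_window, ...) {
  nt <- normalize_fmax(trace, fmax_window)
  d <- peak_delta(nt, baseline_window, response_window, ...)
  data.frame(roi_id = trace$roi_id, channel = trace$channel,
             delta_f_over_fmax = as.numeric(d), f_max = nt$F_max,
             baseline = attr(d, "baseline"), peak = attr(d, "peak"),
             linearity_flag = attr(d, "linearity_flag"),
             stringsAsFactors = FALSE)
}
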