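# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a cell outline and a tubular mitochondrial mask
#'
#' The cell is a smooth star-convex blob (a circle with low-order radial
#' perturbations) centred in the scene. The mitochondrial network is built
#' from smoothed random-walk tubules dilated to a width of about 4 px and
#' clipped to the cell, added until they cover the requested fraction of the
#' cell area. The construction is purely phenomenological: any tubular
#' texture with a controllable area fraction serves the downstream analyses.
#'
#' @param spec A [scene_spec()].
#' @param mito_area_frac Target mitochondrial area as a fraction of the cell
#'   area (default 0.25). 0 gives an empty mitochondrial mask.
#' @param cell_radius_frac Mean cell radius as a fraction of the smaller
#'   scene dimension (default 0.42).
#' @return A list with elements `cell` and `mito`, both [mcs_mask()]s.
#' @export
make_cell_and_mito_masks <- function(spec, mito_area_frac = 0.25,
                                     cell_radius_frac = 0.42) {
  validate_scene_spec(spec)
  if (mito_area_frac < 0 || mito_area_frac > 1)
    stop("mito_area_frac must lie in [0, 1]: requested mitochondrial area ",
         "cannot exceed the cell area")
  h <- spec$height_px; w <- spec$width_px
  with_seed(derive_seed(spec$seed, 101L), {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    r0 <- cell_radius_frac * min(w, h)
    amp <- stats::runif(3, 0, 0.12)
    phs <- stats::runif(3, 0, 2 * pi)
    col0 <- matrix(rep(0:(w - 1), each = h), nrow = h)
    row0 <- matrix(rep(0:(h - 1), times = w), nrow = h)
    dx <- col0 - cx; dy <- row0 - cy
    theta <- atan2(dy, dx)
    rad <- r0 * (1 + amp[1] * cos(2 * theta + phs[1]) +
                     amp[2] * cos(3 * theta + phs[2]) +
                     amp[3] * cos(4 * theta + phs[3]))
    cell <- (dx^2 + dy^2) <= rad^2
    mito <- matrix(FALSE, h, w)
    cell_area <- sum(cell)
    target <- mito_area_frac * cell_area
    if (target > 0) {
      inside <- which(cell)
      brush <- EBImage::makeBrush(5, shape = "disc")
      guard <- 0L
      while (sum(mito) < target) {
        guard <- guard + 1L
        if (guard > 5000L)
          stop("could not reach requested mitochondrial area fraction")
        start <- inside[sample.int(length(inside), 1L)]
        r <- ((start - 1L) %% h) + 1L
        cc <- ((start - 1L) %/% h) + 1L
        heading <- stats::runif(1, 0, 2 * pi)
        n_steps <- 60L
        pr <- numeric(n_steps); pc <- numeric(n_steps)
        x <- cc; y <- r
        for (s in seq_len(n_steps)) {
          heading <- heading + stats::rnorm(1, 0, 0.25)
          x <- x + 1.5 * cos(heading); y <- y + 1.5 * sin(heading)
          pr[s] <- y; pc[s] <- x
        }
        pr <- round(pr); pc <- round(pc)
        ok <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
        pr <- pr[ok]; pc <- pc[ok]
        if (!length(pr)) next
        path <- matrix(FALSE, h, w)
        path[cbind(pr, pc)] <- TRUE
        tubule <- EBImage::dilate(path, brush) > 0
        mito <- mito | (tubule & cell)
      }
    }
    list(cell = mcs_mask(cell, spec$pixel_size_nm, "cell"),
         mito = mcs_mask(mito, spec$pixel_size_nm, "mitochondria"))
  })
}

# Draw n points uniformly over the TRUE pixels of a mask (continuous nm
# coordinates via uniform within-pixel jitter), enforcing a minimum pairwise
# spacing against already-accepted points by rejection sampling.
sample_points_in_mask <- function(mask, n, min_spacing_nm = 0,
                                  existing_x = numeric(), existing_y = numeric()) {
  if (n == 0L) return(list(x = numeric(), y = numeric()))
  idx <- which(mask$data)
  if (!length(idx)) stop("mask is empty: no pixels available for placement")
  h <- nrow(mask$data); psz <- mask$pixel_size_nm
  xs <- numeric(n); ys <- numeric(n)
  accepted <- 0L; attempts <- 0L
  max_attempts <- max(2000L, 500L * n)
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " puncta at min_spacing_nm = ",
           min_spacing_nm, ": spacing constraint unsatisfiable in this region")
    p <- idx[sample.int(length(idx), 1L)]
    r0 <- (p - 1L) %% h           # 0-based row
    c0 <- (p - 1L) %/% h          # 0-based col
    x <- (c0 + stats::runif(1, -0.5, 0.5)) * psz
    y <- (r0 + stats::runif(1, -0.5, 0.5)) * psz
    if (min_spacing_nm > 0) {
      prev_x <- c(xs[seq_len(accepted)], existing_x)
      prev_y <- c(ys[seq_len(accepted)], existing_y)
      if (length(prev_x) &&
          min((prev_x - x)^2 + (prev_y - y)^2) < min_spacing_nm^2)
        next
    }
    accepted <- accepted + 1L
    xs[accepted] <- x; ys[accepted] <- y
  }
  list(x = xs, y = ys)
}

#' Place reference and partner puncta with known colocalization structure
#'
#' Generates the ground truth for object-based colocalization analyses:
#' `n_ref` reference puncta (e.g. IP3R) of which a fraction `f_mito` is
#' constrained to the mitochondrial mask, and `n_partner` partner puncta
#' (e.g. KRAP) of which `round(f_coloc * n_ref)` are placed at a Gaussian
#' sub-resolution offset (sd `offset_sigma_nm`) from a randomly chosen
#' paired reference punctum; the remaining partners are uniform over the
#' cell. A minimum spacing is enforced within each channel so that puncta
#' stay individually resolvable.
#'
#' @param cell,mito Cell and mitochondrial [mcs_mask()]s from the same scene.
#' @param n_ref,n_partner Puncta counts per channel.
#' @param f_coloc Fraction of reference puncta with a truly paired partner.
#' @param f_mito Fraction of reference puncta on the mitochondrial mask.
#' @param offset_sigma_nm Gaussian sd of the pair offset (default 50 nm,
#'   well below the 233 nm colocalization threshold so true pairs classify
#'   as colocalized with high probability).
#' @param min_spacing_nm Minimum same-channel centre-to-centre distance
#'   (default 466 nm, i.e. 6 px at the default pixel size).
#' @param mito_margin_px Dilation (in px) of the mitochondrial mask used as
#'   an exclusion zone when placing non-mitochondrial reference puncta, so
#'   that the generated `f_mito` is crisp (default 3).
#' @param seed Integer seed.
#' @return A `puncta_ground_truth` list: `ref` and `partner`
#'   ([puncta_field()]s), `pair_map` (two-column matrix of ref/partner
#'   indices), `ref_on_mito` (logical), and the generating parameters.
#' @export
place_puncta <- function(cell, mito, n_ref, n_partner, f_coloc,
                         f_mito = 0, offset_sigma_nm = 50,
                         min_spacing_nm = 466, mito_margin_px = 3L,
                         seed = 1L) {
  stopifnot(inherits(cell, "mcs_mask"), inherits(mito, "mcs_mask"))
  if (f_coloc < 0 || f_coloc > 1) stop("f_coloc must lie in [0, 1]")
  if (f_mito < 0 || f_mito > 1) stop("f_mito must lie in [0, 1]")
  n_pair <- round(f_coloc * n_ref)
  n_mito <- round(f_mito * n_ref)
  if (n_pair > n_partner)
    stop("round(f_coloc * n_ref) exceeds n_partner")
  psz <- cell$pixel_size_nm
  w_nm <- (ncol(cell$data) - 0.5) * psz
  h_nm <- (nrow(cell$data) - 0.5) * psz
  with_seed(seed, {
    if (n_mito > 0L && !any(mito$data))
      stop("f_mito > 0 requires a non-empty mitochondrial mask")
    on_mito <- sample_points_in_mask(mito, n_mito, min_spacing_nm)
    cyto_mask_mat <- cell$data
    if (any(mito$data)) {
      mito_excl <- EBImage::dilate(
        mito$data, EBImage::makeBrush(2L * as.integer(mito_margin_px) + 1L,
                                      shape = "disc")) > 0
      cyto_mask_mat <- cell$data & !mito_excl
    }
    cyto_mask <- mcs_mask(cyto_mask_mat, psz, "cell")
    off_mito <- sample_points_in_mask(cyto_mask, n_ref - n_mito,
                                      min_spacing_nm,
                                      on_mito$x, on_mito$y)
    ref_x <- c(on_mito$x, off_mito$x)
    ref_y <- c(on_mito$y, off_mito$y)
    ref_on_mito <- c(rep(TRUE, n_mito), rep(FALSE, n_ref - n_mito))
    # shuffle ref order so mito status and pairing are independent
    ord <- sample.int(n_ref)
    ref_x <- ref_x[ord]; ref_y <- ref_y[ord]; ref_on_mito <- ref_on_mito[ord]

    paired_ref <- if (n_pair > 0L) sort(sample.int(n_ref, n_pair)) else integer()
    part_x <- numeric(n_pair); part_y <- numeric(n_pair)
    inside_cell <- function(x, y) {
      if (x < 0 || y < 0 || x > w_nm || y > h_nm) return(FALSE)
      rc <- nm_to_px(x, y, psz, ncol(cell$data), nrow(cell$data))
      cell$data[rc[1, "row"], rc[1, "col"]]
    }
    for (i in seq_len(n_pair)) {
      rx <- ref_x[paired_ref[i]]; ry <- ref_y[paired_ref[i]]
      repeat {
        dx <- stats::rnorm(1, 0, offset_sigma_nm)
        dy <- stats::rnorm(1, 0, offset_sigma_nm)
        # truncate at 3 sigma so every true pair stays sub-resolution
        if (offset_sigma_nm > 0 && dx^2 + dy^2 > (3 * offset_sigma_nm)^2)
          next
        x <- rx + dx; y <- ry + dy
        if (offset_sigma_nm == 0 || inside_cell(x, y)) break
      }
      part_x[i] <- x; part_y[i] <- y
    }
    bg <- sample_points_in_mask(mcs_mask(cell$data, psz, "cell"),
                                n_partner - n_pair, min_spacing_nm,
                                part_x, part_y)
    part_x <- c(part_x, bg$x); part_y <- c(part_y, bg$y)
    pair_map <- cbind(ref_idx = paired_ref, partner_idx = seq_len(n_pair))

    structure(list(
      ref = puncta_field(ref_x, ref_y, channel = "ref", pixel_size_nm = psz),
      partner = puncta_field(part_x, part_y, channel = "partner",
                             pixel_size_nm = psz),
      pair_map = pair_map,
      ref_on_mito = ref_on_mito,
      f_coloc = f_coloc, f_mito = f_mito,
      offset_sigma_nm = offset_sigma_nm, seed = seed
    ), class = "puncta_ground_truth")
  })
}

#' Render point emitters into a fluorescence image
#'
#' Each point is rendered as a 2-d Gaussian of standard deviation
#' `psf_sigma_nm` whose discrete mass sums to the point's amplitude, so the
#' integrated image intensity of a noise-free interior scene equals the sum
#' of amplitudes. Shot noise (Poisson) and read noise (Gaussian) are applied
#' according to the scene's noise model.
#'
#' @param x_nm,y_nm Emitter coordinates in nm (must lie inside the scene).
#' @param spec A [scene_spec()].
#' @param amplitudes Scalar or per-point integrated intensities.
#' @param channel Channel label for the output image.
#' @param noise_seed Seed for the noise draw (default derived from the
#'   scene seed).
#' @return An [mcs_image()] (not background-corrected).
#' @export
render_channel <- function(x_nm, y_nm, spec, amplitudes = 1000,
                           channel = "synthetic", noise_seed = NULL) {
  validate_scene_spec(spec)
  psz <- spec$pixel_size_nm
  w <- spec$width_px; h <- spec$height_px
  if (length(x_nm) &&
      (min(x_nm, y_nm) < -0.5 * psz ||
       max(x_nm) > (w - 0.5) * psz || max(y_nm) > (h - 0.5) * psz))
    stop("points outside scene bounds")
  amplitudes <- rep_len(amplitudes, length(x_nm))
  img <- matrix(0, h, w)
  sig_px <- spec$psf_sigma_nm / psz
  half <- max(1L, ceiling(4 * sig_px))
  for (i in seq_along(x_nm)) {
    cx <- x_nm[i] / psz  # 0-based continuous
    cy <- y_nm[i] / psz
    c0 <- round(cx); r0 <- round(cy)
    cols <- max(0L, c0 - half):min(w - 1L, c0 + half)
    rows <- max(0L, r0 - half):min(h - 1L, r0 + half)
    if (sig_px > 0) {
      gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
      gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
      kern <- (gy / sum(gy)) %o% (gx / sum(gx)) * amplitudes[i]
    } else {
      kern <- matrix(0, length(rows), length(cols))
      kern[rows == r0, cols == c0] <- amplitudes[i]
    }
    img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + kern
  }
  nm <- spec$noise_model
  if (nm$poisson_scaling > 0 || nm$gaussian_sd > 0) {
    if (is.null(noise_seed)) noise_seed <- derive_seed(spec$seed, 7L)
    img <- with_seed(noise_seed, {
      out <- img
      if (nm$poisson_scaling > 0)
        out <- stats::rpois(length(out), pmax(out, 0) * nm$poisson_scaling) /
          nm$poisson_scaling
      if (nm$gaussian_sd > 0)
        out <- out + stats::rnorm(length(out), 0, nm$gaussian_sd)
      matrix(out, h, w)
    })
  }
  mcs_image(img, psz, channel = channel)
}

#' Generate a synthetic PLA field
#'
#' Renders a DAPI channel of `n_cells` disjoint nuclear blobs and a spot
#' channel whose total spot count is drawn from a Poisson distribution with
#' mean `spots_per_cell_mean * n_cells`, emulating a proximity ligation
#' assay field of view. Ground truth (true counts and positions) is
#' returned alongside the images.
#'
#' @param n_cells Number of nuclei in the field (>= 1).
#' @param spots_per_cell_mean Mean PLA spots per cell.
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @param nucleus_radius_px Nuclear blob radius (default 9 px).
#' @param spot_amplitude Integrated intensity per PLA spot.
#' @param spot_min_spacing_nm Minimum spot spacing; the default (466 nm)
#'   keeps spots resolvable so counting can be exact at moderate densities.
#'   Set to 0 for fully independent uniform placement.
#' @return A list: `spots` and `dapi` ([mcs_image()]s) and `truth` (a list
#'   with `n_cells`, `nuclei_xy`, `n_spots`, `spots_xy`,
#'   `spots_per_cell_true`).
#' @export
make_pla_scene <- function(n_cells, spots_per_cell_mean, spec, seed = 1L,
                           nucleus_radius_px = 9, spot_amplitude = 1000,
                           spot_min_spacing_nm = 466) {
  validate_scene_spec(spec)
  stopifnot(n_cells >= 1)
  psz <- spec$pixel_size_nm
  w <- spec$width_px; h <- spec$height_px
  with_seed(seed, {
    # nuclei: disjoint discs away from the border
    margin <- nucleus_radius_px + 4
    nx <- numeric(n_cells); ny <- numeric(n_cells)
    placed <- 0L; attempts <- 0L
    while (placed < n_cells) {
      attempts <- attempts + 1L
      if (attempts > 50000L) stop("could not place disjoint nuclei")
      x <- stats::runif(1, margin, w - 1 - margin)
      y <- stats::runif(1, margin, h - 1 - margin)
      if (placed &&
          min((nx[seq_len(placed)] - x)^2 + (ny[seq_len(placed)] - y)^2) <
            (2.4 * nucleus_radius_px)^2) next
      placed <- placed + 1L
      nx[placed] <- x; ny[placed] <- y
    }
    col0 <- matrix(rep(0:(w - 1), each = h), nrow = h)
    row0 <- matrix(rep(0:(h - 1), times = w), nrow = h)
    dapi <- matrix(0, h, w)
    for (i in seq_len(n_cells)) {
      dapi <- dapi +
        1000 * ((col0 - nx[i])^2 + (row0 - ny[i])^2 <= nucleus_radius_px^2)
    }
    dapi <- EBImage::gblur(dapi, sigma = 2)
    nm <- spec$noise_model
    if (nm$gaussian_sd > 0)
      dapi <- dapi + stats::rnorm(length(dapi), 0, nm$gaussian_sd)
    dapi <- matrix(dapi, h, w)

    n_spots <- stats::rpois(1L, spots_per_cell_mean * n_cells)
    field_mask <- matrix(FALSE, h, w)
    field_mask[4:(h - 3), 4:(w - 3)] <- TRUE
    pts <- sample_points_in_mask(mcs_mask(field_mask, psz, "roi"),
                                 n_spots, spot_min_spacing_nm)
    spots <- render_channel(pts$x, pts$y, spec, amplitudes = spot_amplitude,
                            channel = "pla",
                            noise_seed = derive_seed(seed, 11L))
    list(spots = spots,
         dapi = mcs_image(dapi, psz, channel = "dapi"),
         truth = list(n_cells = n_cells,
                      nuclei_xy = cbind(x_nm = nx * psz, y_nm = ny * psz),
                      n_spots = n_spots,
                      spots_xy = cbind(x_nm = pts$x, y_nm = pts$y),
                      spots_per_cell_true = n_spots / n_cells))
  })
}

#' Specification of a synthetic calcium indicator trace
#'
#' Describes a single-cell fluorescence time course: a baseline at
#' `baseline_frac` of the saturated signal, a stimulus-evoked transient
#' rising to `peak_frac` (double-exponential kinetics), and a terminal step
#' to the saturated plateau (F_max) from `fmax_frame` onward, emulating the
#' pharmacological saturation of the indicator at the end of an experiment.
#'
#' @param n_frames Number of frames.
#' @param frame_interval_s Sampling interval in seconds.
#' @param baseline_frac,peak_frac Baseline and transient peak as fractions
#'   of F_max; `0 < baseline_frac <= peak_frac <= 1`.
#' @param stim_frame,fmax_frame Stimulus and saturation frame indices
#'   (1-based); `stim_frame < fmax_frame <= n_frames`.
#' @param rise_tau_s,decay_tau_s Transient rise and decay time constants.
#' @param noise_sd_frac Gaussian noise sd as a fraction of F_max.
#' @param seed Integer seed for the noise draw.
#' @return A `calcium_trace_spec` object.
#' @export
calcium_trace_spec <- function(n_frames = 180L, frame_interval_s = 1,
                               baseline_frac = 0.1, peak_frac = 0.45,
                               stim_frame = 30L, fmax_frame = 150L,
                               rise_tau_s = 2, decay_tau_s = 8,
                               noise_sd_frac = 0.01, seed = 1L) {
  spec <- structure(list(
    n_frames = as.integer(n_frames),
    frame_interval_s = as.numeric(frame_interval_s),
    baseline_frac = baseline_frac, peak_frac = peak_frac,
    stim_frame = as.integer(stim_frame), fmax_frame = as.integer(fmax_frame),
    rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
    noise_sd_frac = noise_sd_frac, seed = as.integer(seed)
  ), class = "calcium_trace_spec")
  if (!(spec$baseline_frac > 0 && spec$baseline_frac <= spec$peak_frac &&
        spec$peak_frac <= 1))
    stop("need 0 < baseline_frac <= peak_frac <= 1")
  if (!(spec$stim_frame < spec$fmax_frame && spec$fmax_frame <= spec$n_frames))
    stop("need stim_frame < fmax_frame <= n_frames")
  if (spec$rise_tau_s <= 0 || spec$decay_tau_s <= 0 ||
      spec$rise_tau_s == spec$decay_tau_s)
    stop("rise and decay time constants must be positive and distinct")
  spec
}

#' Construct a fluorescence trace object
#'
#' @param time_s Time in seconds (strictly increasing).
#' @param F Background-corrected ROI mean fluorescence.
#' @param roi_id ROI/cell identifier.
#' @param channel "cytosolic" or "mitochondrial".
#' @return An `mcs_trace` object.
#' @export
mcs_trace <- function(time_s, F, roi_id = "cell1",
                      channel = c("cytosolic", "mitochondrial")) {
  channel <- match.arg(channel)
  stopifnot(length(time_s) == length(F), !is.unsorted(time_s, strictly = TRUE))
  structure(list(time_s = as.numeric(time_s), F = as.numeric(F),
                 roi_id = roi_id, channel = channel),
            class = "mcs_trace")
}

synth_calcium_trace <- function(spec, f_max = 1000, roi_id = "cell1",
                                channel = "cytosolic") {
  stopifnot(inherits(spec, "calcium_trace_spec"))
  n <- spec$n_frames
  t <- (seq_len(n) - 1) * spec$frame_interval_s
  frac <- rep(spec$baseline_frac, n)
  resp <- spec$stim_frame:(spec$fmax_frame - 1L)
  if (spec$peak_frac > spec$baseline_frac && length(resp)) {
    ts <- t[resp] - t[spec$stim_frame]
    u <- exp(-ts / spec$decay_tau_s) - exp(-ts / spec$rise_tau_s)
    u <- u / max(u)  # discrete max = 1 so the sampled peak is exact
    frac[resp] <- spec$baseline_frac +
      (spec$peak_frac - spec$baseline_frac) * u
  }
  frac[spec$fmax_frame:n] <- 1
  F <- frac * f_max
  if (spec$noise_sd_frac > 0)
    F <- with_seed(spec$seed,
                   F + stats::rnorm(n, 0, spec$noise_sd_frac * f_max))
  tr <- mcs_trace(t, F, roi_id = roi_id, channel = channel)
  attr(tr, "truth") <- list(delta_f_over_fmax = spec$peak_frac - spec$baseline_frac,
                            f_max = f_max,
                            baseline_frac = spec$baseline_frac,
                            peak_frac = spec$peak_frac)
  tr
}

#' Generate a matched pair of cytosolic and mitochondrial calcium traces
#'
#' Emulates a dual-indicator recording from one cell: both channels share
#' the protocol structure (baseline, stimulus transient, terminal F_max
#' plateau after pharmacological saturation) but have independent
#' amplitudes, kinetics and noise. The true peak response
#' (ΔF/F_max = peak_frac − baseline_frac) of each channel is recorded in a
#' `truth` attribute.
#'
#' @param cyto,mito [calcium_trace_spec()]s for the two channels.
#' @param f_max_cyto,f_max_mito Saturated fluorescence levels (arbitrary
#'   units) of the two indicators.
#' @param roi_id Cell identifier carried by both traces.
#' @return A list with `cyto` and `mito` [mcs_trace()]s.
#' @export
make_calcium_trace_pair <- function(cyto, mito, f_max_cyto = 1000,
                                    f_max_mito = 600, roi_id = "cell1") {
  list(cyto = synth_calcium_trace(cyto, f_max_cyto, roi_id, "cytosolic"),
       mito = synth_calcium_trace(mito, f_max_mito, roi_id, "mitochondrial"))
}

#' Render a binary organelle mask as a fluorescence channel
#'
#' The mask is scaled to `amplitude`, blurred with the scene PSF and
#' carries the scene noise model, emulating an organelle-marker channel
#' (e.g. MitoTracker) whose segmentation can be compared against the
#' generating mask.
#'
#' @param mask An [mcs_mask()].
#' @param spec A [scene_spec()] on the same grid.
#' @param amplitude Peak intensity of the structure (default 500).
#' @param noise_seed Seed for the noise draw.
#' @return An [mcs_image()].
#' @export
render_mask_channel <- function(mask, spec, amplitude = 500,
                                noise_seed = NULL) {
  validate_scene_spec(spec)
  stopifnot(inherits(mask, "mcs_mask"))
  sig_px <- spec$psf_sigma_nm / spec$pixel_size_nm
  img <- amplitude * mask$data
  if (sig_px > 0 && any(mask$data))
    img <- as.matrix(EBImage::gblur(img, sigma = sig_px))
  nm <- spec$noise_model
  if (nm$poisson_scaling > 0 || nm$gaussian_sd > 0) {
    if (is.null(noise_seed)) noise_seed <- derive_seed(spec$seed, 13L)
    img <- with_seed(noise_seed, {
      out <- img
      if (nm$poisson_scaling > 0)
        out <- stats::rpois(length(out), pmax(out, 0) * nm$poisson_scaling) /
          nm$poisson_scaling
      if (nm$gaussian_sd > 0)
        out <- out + stats::rnorm(length(out), 0, nm$gaussian_sd)
      matrix(out, nrow(mask$data), ncol(mask$data))
    })
  }
  mcs_image(img, spec$pixel_size_nm, channel = "organelle")
}
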