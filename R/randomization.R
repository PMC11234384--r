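#' Shuffle puncta uniformly within a region
#'
#' Replaces each punctum position by an independent uniform draw over the
#' pixels of the region (with uniform within-pixel jitter to continuous nm
#' coordinates). Punctum count, intensities and areas are preserved. This
#' is the permutation step of the colocalization null model: shuffling the
#' partner channel within the cell destroys any spatial relationship with
#' the reference channel while keeping its abundance.
#'
#' @param puncta A [puncta_field()].
#' @param region Non-empty [mcs_mask()] (typically the cell mask).
#' @param seed Integer seed.
#' @return A [puncta_field()] with randomized positions.
#' @export
shuffle_puncta <- function(puncta, region, seed = 1L) {
  stopifnot(inherits(puncta, "puncta_field"), inherits(region, "mcs_mask"))
  idx <- which(region$data)
  if (!length(idx)) stop("shuffle region is empty")
  n <- n_puncta(puncta)
  h <- nrow(region$data); psz <- region$pixel_size_nm
  with_seed(seed, {
    p <- idx[sample.int(length(idx), n, replace = TRUE)]
    r0 <- (p - 1L) %% h
    c0 <- (p - 1L) %/% h
    x <- (c0 + stats::runif(n, -0.5, 0.5)) * psz
    y <- (r0 + stats::runif(n, -0.5, 0.5)) * psz
    puncta_field(x, y, puncta$intensity, puncta$area_px,
                 channel = puncta$channel, pixel_size_nm = psz)
  })
}

#' Permutation test for object-based colocalization
#'
#' Computes the observed fraction of reference puncta whose nearest partner
#' punctum lies within `threshold_nm`, then rebuilds that fraction
#' `n_iter` times with the partner field shuffled uniformly within the
#' region ("shuffled within each cell"). The null statistic is the per-cell
#' colocalized fraction; the empirical 2.5th and 97.5th percentiles of the
#' null fractions form a 95% interval, and the observation is flagged
#' significant when it falls outside that interval. Percentiles use linear
#' interpolation between order statistics (`quantile` type 7).
#'
#' @param ref,partner Non-empty [puncta_field()]s.
#' @param region Shuffle region [mcs_mask()] (cell mask).
#' @param threshold_nm Colocalization threshold (default 233 nm).
#' @param n_iter Number of shuffles (default 100, the conventional count).
#' @param seed Integer seed; per-iteration seeds are derived from it.
#' @param keep_null_distances Retain the pooled null nearest-neighbour
#'   distances (for frequency-distribution plots); default FALSE.
#' @return A `rand_test_result`: `observed_fraction`, `null_fractions`,
#'   `ci_low`, `ci_high`, `significant`, `n_iter`, `seed`, and optionally
#'   `null_distances_nm`.
#' @export
randomization_test <- function(ref, partner, region, threshold_nm = 233,
                               n_iter = 100L, seed = 1L,
                               keep_null_distances = FALSE) {
  stopifnot(inherits(ref, "puncta_field"), inherits(partner, "puncta_field"))
  if (n_puncta(ref) == 0L || n_puncta(partner) == 0L)
    stop("both puncta fields must be non-empty")
  obs <- nearest_neighbour_distances(ref, partner, threshold_nm)
  nulls <- numeric(n_iter)
  null_d <- if (keep_null_distances) vector("list", n_iter) else NULL
  for (i in seq_len(n_iter)) {
    shuf <- shuffle_puncta(partner, region, seed = derive_seed(seed, i))
    nn <- nearest_neighbour_distances(ref, shuf, threshold_nm)
    nulls[i] <- nn$fraction_colocalized
    if (keep_null_distances) null_d[[i]] <- nn$distances_nm
  }
  ci <- stats::quantile(nulls, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(
    observed_fraction = obs$fraction_colocalized,
    observed_nnd = obs,
    null_fractions = nulls,
    ci_low = ci[1], ci_high = ci[2],
    significant = obs$fraction_colocalized < ci[1] ||
                  obs$fraction_colocalized > ci[2],
    threshold_nm = threshold_nm, n_iter = as.integer(n_iter),
    seed = as.integer(seed),
    null_distances_nm = if (keep_null_distances)
      unlist(null_d, use.names = FALSE) else NULL
  ), class = "rand_test_result")
}

#' @export
print.rand_test_result <- function(x, ...) {
  cat(sprintf(
    paste0("<rand_test_result> observed %.3f vs null [%.3f, %.3f] ",
           "(%d shuffles): %s\n"),
    x$observed_fraction, x$ci_low, x$ci_high, x$n_iter,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Expected chance-colocalization fraction under complete spatial randomness
#'
#' For `n_partner` partner puncta placed uniformly over a region of area
#' `region_area_nm2`, the probability that a reference punctum (whose
#' threshold disc lies fully inside the region) has at least one partner
#' within `threshold_nm` is `1 - (1 - pi * r^2 / A)^n`. Edge effects are
#' ignored; the per-point probability is clamped at 1 when the disc
#' exceeds the region.
#'
#' @param n_partner Number of partner puncta (> 0).
#' @param region_area_nm2 Region area in nm^2 (> 0).
#' @param threshold_nm Colocalization threshold (> 0).
#' @return Expected colocalized fraction in [0, 1].
#' @export
csr_expected_fraction <- function(n_partner, region_area_nm2, threshold_nm) {
  if (n_partner <= 0 || region_area_nm2 <= 0 || threshold_nm < 0)
    stop("inputs must be positive")
  p <- min(1, pi * threshold_nm^2 / region_area_nm2)
  1 - (1 - p)^n_partner
}

#' Chance-corrected colocalization fraction
#'
#' Converts an observed colocalized fraction and the mean of its shuffle
#' null into an estimate of the truly paired fraction, by inverting
#' `observed = f + (1 - f) * p_chance`: unpaired reference puncta still
#' fall within the threshold of a random partner with probability
#' `p_chance`, estimated by the null mean.
#'
#' @param observed_fraction Observed colocalized fraction.
#' @param chance_fraction Chance (null-mean) colocalized fraction.
#' @return Estimated true paired fraction (can be slightly negative by
#'   sampling noise; not clamped).
#' @export
chance_corrected_fraction <- function(observed_fraction, chance_fraction) {
  if (chance_fraction >= 1) stop("chance_fraction must be < 1")
  (observed_fraction - chance_fraction) / (1 - chance_fraction)
}
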