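# Shared helpers for the test suite. The NND oracle here is written
# independently of the package's search code: plain per-point loops over
# the full distance set.

oracle_nnd <- function(ref, partner) {
  n <- length(ref$x_nm)
  d <- numeric(n)
  idx <- integer(n)
  for (i in seq_len(n)) {
    all_d <- sqrt((ref$x_nm[i] - partner$x_nm)^2 +
                  (ref$y_nm[i] - partner$y_nm)^2)
    j <- which.min(all_d)   # first minimum = lowest partner index
    d[i] <- all_d[j]
    idx[i] <- j
  }
  list(dist = d, idx = idx)
}

border_bg <- function(h, w, pixel_size_nm = 77.7, band = 3L) {
  m <- matrix(TRUE, h, w)
  m[(band + 1):(h - band), (band + 1):(w - band)] <- FALSE
  mcs_mask(m, pixel_size_nm, "background")
}

# Greedy one-to-one matching of detections to ground truth within tol_nm;
# returns precision/recall/F1.
match_detections <- function(det, truth, tol_nm) {
  nd <- length(det$x_nm); nt <- length(truth$x_nm)
  if (nd == 0L || nt == 0L)
    return(list(precision = NA, recall = 0, f1 = 0, tp = 0L))
  d2 <- outer(det$x_nm, truth$x_nm, "-")^2 + outer(det$y_nm, truth$y_nm, "-")^2
  used_t <- logical(nt)
  tp <- 0L
  ord <- order(apply(d2, 1, min))
  for (i in ord) {
    j <- which.min(ifelse(used_t, Inf, d2[i, ]))
    if (is.finite(d2[i, j]) && !used_t[j] && d2[i, j] <= tol_nm^2) {
      used_t[j] <- TRUE
      tp <- tp + 1L
    }
  }
  precision <- tp / nd
  recall <- tp / nt
  list(precision = precision, recall = recall,
       f1 = 2 * precision * recall / max(precision + recall, 1e-12), tp = tp)
}

# Uniformly scattered points with pairwise minimum spacing (test-side
# placement, independent of the generator).
scatter_points <- function(n, xlim, ylim, min_spacing) {
  xs <- numeric(n); ys <- numeric(n); k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 10000L * n) stop("scatter_points: cannot satisfy spacing")
    x <- runif(1, xlim[1], xlim[2]); y <- runif(1, ylim[1], ylim[2])
    if (k && min((xs[1:k] - x)^2 + (ys[1:k] - y)^2) < min_spacing^2) next
    k <- k + 1L; xs[k] <- x; ys[k] <- y
  }
  list(x = xs, y = ys)
}
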