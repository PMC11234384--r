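test_that("nearest-neighbour distances follow Euclidean geometry", {
  ref <- puncta_field(0, 0)
  partner <- puncta_field(c(300, 1000), c(400, 0))
  nn <- nearest_neighbour_distances(ref, partner)
  expect_equal(nn$distances_nm, 500)          # 3-4-5 triangle
  expect_equal(nn$partner_idx, 1L)
  expect_false(nn$colocalized)
  expect_equal(nn$fraction_colocalized, 0)

  same <- puncta_field(c(100, 200, 300), c(10, 20, 30))
  nn2 <- nearest_neighbour_distances(same, same)
  expect_true(all(nn2$distances_nm == 0))
  expect_equal(nn2$fraction_colocalized, 1)
  expect_equal(nn2$partner_idx, 1:3)

  expect_error(nearest_neighbour_distances(ref, puncta_field(numeric(),
                                                             numeric())),
               "no partner puncta")
})

test_that("grid-accelerated search equals the exhaustive oracle", {
  set.seed(99)
  for (i in 1:25) {
    nr <- sample(1:200, 1); np <- sample(1:200, 1)
    ref <- puncta_field(runif(nr, 0, 2e4), runif(nr, 0, 2e4))
    partner <- puncta_field(runif(np, 0, 2e4), runif(np, 0, 2e4))
    fast <- nearest_neighbour_distances(ref, partner, method = "grid")
    orc <- oracle_nnd(ref, partner)
    expect_identical(fast$partner_idx, orc$idx)
    expect_equal(fast$distances_nm, orc$dist, tolerance = 1e-12)
  }
  # clustered configuration with ties on duplicated partners
  ref <- puncta_field(rep(500, 5), rep(500, 5))
  partner <- puncta_field(c(600, 600, 100), c(500, 500, 100))
  nn <- nearest_neighbour_distances(ref, partner, method = "grid")
  expect_true(all(nn$partner_idx == 1L))  # lowest index wins ties
})

test_that("colocalization classification applies a strict threshold", {
  nn <- structure(list(distances_nm = c(100, 232.9, 233, 500),
                       partner_idx = 1:4, threshold_nm = 233,
                       colocalized = logical(4),
                       fraction_colocalized = NA_real_),
                  class = "nnd_result")
  out <- classify_colocalized(nn)   # default threshold 233 nm
  expect_identical(out$colocalized, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$fraction_colocalized, 0.5)
  expect_equal(out$threshold_nm, 233)

  none <- classify_colocalized(nn, threshold_nm = 50)
  expect_equal(none$fraction_colocalized, 0)
  expect_error(classify_colocalized(nn, threshold_nm = 0), "positive")

  # fraction is non-decreasing in the threshold
  set.seed(7)
  ref <- puncta_field(runif(100, 0, 1e4), runif(100, 0, 1e4))
  partner <- puncta_field(runif(100, 0, 1e4), runif(100, 0, 1e4))
  base <- nearest_neighbour_distances(ref, partner)
  fr <- vapply(seq(50, 2000, by = 50), function(th)
    classify_colocalized(base, th)$fraction_colocalized, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("mask partitioning splits and conserves puncta", {
  psz <- 77.7
  pf <- puncta_field(c(5, 20, 40) * psz, c(5, 20, 40) * psz,
                     pixel_size_nm = psz)
  empty <- mcs_mask(matrix(FALSE, 64, 64), psz, "mitochondria")
  full <- mcs_mask(matrix(TRUE, 64, 64), psz, "mitochondria")
  se <- subset_by_mask(pf, empty)
  expect_equal(n_puncta(se$inside), 0)
  expect_equal(n_puncta(se$outside), 3)
  sf <- subset_by_mask(pf, full)
  expect_equal(n_puncta(sf$inside), 3)

  half <- mcs_mask(cbind(matrix(TRUE, 64, 32), matrix(FALSE, 64, 32)),
                   psz, "mitochondria")
  sh <- subset_by_mask(pf, half, dilate_px = 0)
  expect_equal(n_puncta(sh$inside) + n_puncta(sh$outside), 3)
  expect_identical(sh$inside_flag, c(TRUE, TRUE, FALSE))
})

test_that("generated mitochondrial fraction is recovered through the masks", {
  spec <- scene_spec(seed = 19L)
  m <- make_cell_and_mito_masks(spec, 0.25)
  gt <- place_puncta(m$cell, m$mito, 200, 50, f_coloc = 0, f_mito = 0.25,
                     seed = 4L)
  parts <- subset_by_mask(gt$ref, m$mito, dilate_px = 1)
  expect_lt(abs(mean(parts$inside_flag) - 0.25), 0.07)
})

test_that("NND histograms bin left-closed and conserve counts", {
  one <- structure(list(distances_nm = 100, partner_idx = 1L,
                        threshold_nm = 233, colocalized = TRUE,
                        fraction_colocalized = 1),
                   class = "nnd_result")
  h <- nnd_histogram(one, 50)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$bin_start_nm == 100], 1)  # [100, 150)

  set.seed(3)
  ref <- puncta_field(runif(150, 0, 1e4), runif(150, 0, 1e4))
  partner <- puncta_field(runif(80, 0, 1e4), runif(80, 0, 1e4))
  nn <- nearest_neighbour_distances(ref, partner)
  expect_equal(sum(nnd_histogram(nn, 75)$count), 150)

  nil <- nearest_neighbour_distances(puncta_field(numeric(), numeric()),
                                     partner)
  expect_true(all(nnd_histogram(nil, 50)$count == 0))
  expect_error(nnd_histogram(nn, 0), "positive")
})
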