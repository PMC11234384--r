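test_that("cell and mito masks honour the requested area fraction", {
  spec <- scene_spec(seed = 11L)

  empty <- make_cell_and_mito_masks(spec, mito_area_frac = 0)
  expect_false(any(empty$mito$data))
  expect_true(any(empty$cell$data))

  m <- make_cell_and_mito_masks(spec, mito_area_frac = 0.25)
  frac <- sum(m$mito$data) / sum(m$cell$data)
  expect_lt(abs(frac - 0.25), 0.05)
  expect_true(all(!m$mito$data | m$cell$data))  # mito subset of cell

  # single connected cell region
  lab <- EBImage::bwlabel(m$cell$data)
  expect_equal(max(lab), 1)

  again <- make_cell_and_mito_masks(spec, mito_area_frac = 0.25)
  expect_identical(m$cell$data, again$cell$data)
  expect_identical(m$mito$data, again$mito$data)

  expect_error(make_cell_and_mito_masks(spec, mito_area_frac = 1.5),
               "cannot exceed")
})

test_that("place_puncta produces the specified pairing and mask structure", {
  spec <- scene_spec(seed = 3L)
  m <- make_cell_and_mito_masks(spec, 0.25)

  gt <- place_puncta(m$cell, m$mito, 200, 200, f_coloc = 0.3, f_mito = 0.25,
                     seed = 5L)
  expect_equal(nrow(gt$pair_map), 60)  # round(0.3 * 200)
  expect_equal(sum(gt$ref_on_mito), 50)
  expect_equal(n_puncta(gt$ref), 200)
  expect_equal(n_puncta(gt$partner), 200)

  # every point inside the cell mask
  for (pf in list(gt$ref, gt$partner)) {
    rc <- mcsquant:::nm_to_px(pf$x_nm, pf$y_nm, pf$pixel_size_nm,
                              ncol(m$cell$data), nrow(m$cell$data))
    expect_true(all(m$cell$data[rc]))
  }

  # paired partners sub-resolution from their reference
  dp <- sqrt((gt$ref$x_nm[gt$pair_map[, 1]] -
                gt$partner$x_nm[gt$pair_map[, 2]])^2 +
             (gt$ref$y_nm[gt$pair_map[, 1]] -
                gt$partner$y_nm[gt$pair_map[, 2]])^2)
  expect_true(all(dp <= 3 * gt$offset_sigma_nm))

  # same-channel minimum spacing enforced for the reference channel
  dr <- as.matrix(dist(cbind(gt$ref$x_nm, gt$ref$y_nm)))
  diag(dr) <- Inf
  expect_gte(min(dr), 466)

  # degenerate cases
  gt0 <- place_puncta(m$cell, m$mito, 50, 50, f_coloc = 0, seed = 2L)
  expect_equal(nrow(gt0$pair_map), 0)
  gt1 <- place_puncta(m$cell, m$mito, 30, 30, f_coloc = 1,
                      offset_sigma_nm = 0, seed = 2L)
  expect_equal(gt1$ref$x_nm[gt1$pair_map[, 1]],
               gt1$partner$x_nm[gt1$pair_map[, 2]])
  expect_equal(gt1$ref$y_nm[gt1$pair_map[, 1]],
               gt1$partner$y_nm[gt1$pair_map[, 2]])

  # unsatisfiable spacing names the constraint
  tiny <- mcs_mask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10), 77.7, "cell")
  expect_error(place_puncta(tiny, mcs_mask(matrix(FALSE, 10, 10), 77.7,
                                           "mitochondria"),
                            50, 50, f_coloc = 0, min_spacing_nm = 1e5,
                            seed = 1L),
               "spacing")
})

test_that("render_channel conserves mass and peaks at the emitter", {
  spec <- scene_spec(width_px = 200, height_px = 220, seed = 9L)

  blank <- render_channel(numeric(), numeric(), spec)
  expect_true(all(blank$data == 0))

  one <- render_channel(100 * 77.7, 120 * 77.7, spec, amplitudes = 500)
  pk <- which(one$data == max(one$data), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(121, 101))  # row = y + 1, col = x + 1
  expect_equal(sum(one$data), 500, tolerance = 1e-8)

  many <- render_channel(c(30, 90, 150) * 77.7, c(40, 100, 160) * 77.7,
                         spec, amplitudes = c(100, 200, 300))
  expect_equal(sum(many$data), 600, tolerance = 1e-8)

  noisy_spec <- scene_spec(seed = 9L, gaussian_sd = 2, poisson_scaling = 1)
  n1 <- render_channel(50 * 77.7, 50 * 77.7, noisy_spec, noise_seed = 4L)
  n2 <- render_channel(50 * 77.7, 50 * 77.7, noisy_spec, noise_seed = 4L)
  expect_identical(n1$data, n2$data)

  expect_error(render_channel(1e9, 0, spec), "bounds")
})

test_that("PLA scene generator matches its Poisson spot model", {
  spec <- scene_spec(seed = 21L)

  none <- make_pla_scene(5, 0, spec, seed = 1L)
  expect_equal(none$truth$n_spots, 0)
  expect_equal(none$truth$n_cells, 5)
  expect_true(all(none$spots$data == 0))

  a <- make_pla_scene(10, 20, spec, seed = 8L)
  b <- make_pla_scene(10, 20, spec, seed = 8L)
  expect_identical(a$truth$spots_xy, b$truth$spots_xy)
  expect_identical(a$spots$data, b$spots$data)

  c2 <- make_pla_scene(10, 20, spec, seed = 9L)
  expect_false(identical(a$truth$spots_xy, c2$truth$spots_xy))
  expect_equal(c2$truth$n_cells, 10)

  # total count ~ Poisson(200) across seeds
  counts <- vapply(1:40, function(s)
    make_pla_scene(10, 20, spec, seed = s)$truth$n_spots, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 40))
})

test_that("calcium trace pairs carry exact ground truth", {
  cy <- calcium_trace_spec(baseline_frac = 0.1, peak_frac = 0.45,
                           noise_sd_frac = 0)
  mi <- calcium_trace_spec(baseline_frac = 0.2, peak_frac = 0.2,
                           noise_sd_frac = 0)
  pair <- make_calcium_trace_pair(cy, mi, f_max_cyto = 1000, f_max_mito = 600)

  tr <- pair$cyto
  truth <- attr(tr, "truth")
  expect_equal(truth$delta_f_over_fmax, 0.35)
  expect_equal(max(tr$F[1:149]), 0.45 * 1000)      # sampled peak is exact
  expect_equal(mean(tr$F[150:180]), 1000)          # plateau equals F_max
  expect_equal(max(tr$F), 1000)                    # F_max is the trace max

  # flat response when peak equals baseline
  expect_true(all(pair$mito$F[1:149] == 0.2 * 600))
  expect_equal(attr(pair$mito, "truth")$delta_f_over_fmax, 0)

  expect_error(calcium_trace_spec(baseline_frac = 0.5, peak_frac = 0.4),
               "baseline_frac")
  expect_error(calcium_trace_spec(stim_frame = 160, fmax_frame = 150),
               "stim_frame")
})
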