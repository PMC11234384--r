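test_that("Manders coefficients handle identity, disjoint and partial overlap", {
  psz <- 77.7
  set.seed(8)
  a <- matrix(rexp(64 * 64, 1 / 50), 64, 64)
  imgA <- mcs_image(a, psz)
  expect_equal(manders_split(imgA, imgA)$M1, 1)
  expect_equal(manders_split(imgA, imgA)$M2, 1)

  left <- matrix(0, 32, 32); left[, 1:16] <- 100
  right <- matrix(0, 32, 32); right[, 17:32] <- 100
  dis <- manders_split(mcs_image(left, psz), mcs_image(right, psz),
                       thrA = 10, thrB = 10)
  expect_equal(dis$M1, 0)
  expect_equal(dis$M2, 0)

  # A = 10 on four pixels, two of them B-positive: M1 = 20/40
  A <- matrix(0, 8, 8); A[1, 1:4] <- 10
  B <- matrix(0, 8, 8); B[1, 3:4] <- 50
  ms <- manders_split(mcs_image(A, psz), mcs_image(B, psz),
                      thrA = 5, thrB = 5)
  expect_equal(ms$M1, 0.5)
  expect_equal(ms$M2, 1)

  # invariance under positive scaling of either channel
  ms2 <- manders_split(mcs_image(3.7 * A, psz), mcs_image(B, psz),
                       thrA = 3.7 * 5, thrB = 5)
  expect_equal(ms2$M1, ms$M1)

  blank <- mcs_image(matrix(0, 8, 8), psz)
  expect_error(manders_split(blank, mcs_image(B, psz), thrA = 5, thrB = 5),
               "undefined")
})

test_that("Costes randomization gives 100% for self-colocalized channels", {
  psz <- 77.7
  spec <- scene_spec(width_px = 128, height_px = 128, seed = 3L)
  set.seed(12)
  pts <- scatter_points(60, c(500, 9000), c(500, 9000), 466)
  img <- render_channel(pts$x, pts$y, spec, amplitudes = 1000)
  img$data <- img$data + matrix(abs(rnorm(128^2, 0, 0.5)), 128, 128)

  cp <- costes_pvalue(img, img, block_size_px = 5, n_rand = 100, seed = 7L)
  expect_equal(cp$costes_pvalue_pct, 100)
  expect_equal(cp$pearson_r, 1)
  expect_true(all(cp$null_r < 1))

  cp2 <- costes_pvalue(img, img, block_size_px = 5, n_rand = 100, seed = 7L)
  expect_identical(cp$null_r, cp2$null_r)

  small_mask <- mcs_mask(matrix(FALSE, 128, 128), psz, "cell")
  small_mask$data[1:2, 1:2] <- TRUE
  expect_error(costes_pvalue(img, img, mask = small_mask), "block")
})

test_that("Costes P-value is roughly uniform for independent channels", {
  psz <- 77.7
  set.seed(41)
  p <- vapply(1:30, function(i) {
    a <- mcs_image(matrix(rexp(64^2, 1 / 30), 64, 64), psz)
    b <- mcs_image(matrix(rexp(64^2, 1 / 30), 64, 64), psz)
    mask <- mcs_mask(matrix(TRUE, 64, 64), psz, "cell")
    costes_pvalue(a, b, n_rand = 50, mask = mask, seed = i)$costes_pvalue_pct
  }, numeric(1))
  expect_gt(mean(p), 30)
  expect_lt(mean(p), 70)
})

test_that("M1 grows with the generated colocalized fraction", {
  spec <- scene_spec(seed = 53L, gaussian_sd = 1)
  m <- make_cell_and_mito_masks(spec, 0)
  bg <- border_bg(256, 256)
  m1 <- vapply(c(0, 0.5, 1), function(f) {
    gt <- place_puncta(m$cell, m$mito, 120, 120, f_coloc = f,
                       offset_sigma_nm = 30, seed = 60L + round(10 * f))
    a <- subtract_background(render_channel(gt$ref$x_nm, gt$ref$y_nm, spec,
                                            1000, noise_seed = 1L), bg)
    b <- subtract_background(render_channel(gt$partner$x_nm, gt$partner$y_nm,
                                            spec, 1000, noise_seed = 2L), bg)
    manders_split(a, b, mask = m$cell)$M1
  }, numeric(1))
  expect_true(all(diff(m1) > 0))
})
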