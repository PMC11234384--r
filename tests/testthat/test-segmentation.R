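test_that("background subtraction clips at zero and validates its ROI", {
  psz <- 77.7
  img <- mcs_image(matrix(10, 32, 32), psz)
  bg <- border_bg(32, 32)
  out <- subtract_background(img, bg)
  expect_true(all(out$data == 0))
  expect_true(out$background_corrected)

  spotim <- matrix(20, 32, 32)
  spotim[16, 16] <- 100
  out2 <- subtract_background(mcs_image(spotim, psz), bg)
  expect_equal(out2$data[16, 16], 80)
  expect_equal(out2$data[1, 1], 0)

  # idempotent once the background region is zero-mean
  expect_identical(subtract_background(out2, bg)$data, out2$data)

  cellm <- mcs_mask(matrix(TRUE, 32, 32), psz, "cell")
  expect_error(subtract_background(img, bg, cell_mask = cellm), "overlap")
  expect_error(subtract_background(img, mcs_mask(matrix(FALSE, 32, 32),
                                                 psz, "background")),
               "empty")
})

test_that("single-spot detection is sub-pixel accurate and shift-equivariant", {
  spec <- scene_spec(width_px = 128, height_px = 128, seed = 2L)
  x0 <- 60.37 * 77.7; y0 <- 71.81 * 77.7
  img <- render_channel(x0, y0, spec, amplitudes = 1000)
  # SNR ~ 20 read noise relative to the smoothed peak
  img$data <- img$data + matrix(rnorm(128^2, 0, 1.2), 128, 128)
  img$data <- pmax(img$data, 0)
  img$background_corrected <- TRUE

  pf <- detect_puncta(img)
  expect_equal(n_puncta(pf), 1)
  expect_lt(sqrt((pf$x_nm - x0)^2 + (pf$y_nm - y0)^2), 0.5 * 77.7)

  # integer-pixel shift moves the centroid by exactly that shift
  clean <- render_channel(x0, y0, spec, amplitudes = 1000)
  clean$background_corrected <- TRUE
  shifted <- clean
  shifted$data <- matrix(0, 128, 128)
  shifted$data[(1:128) > 5, (1:128) > 3] <-
    clean$data[1:123, 1:125]  # shift down 5, right 3
  a <- detect_puncta(clean)
  b <- detect_puncta(shifted)
  expect_lt(abs(b$x_nm - (a$x_nm + 3 * 77.7)), 0.01 * 77.7)
  expect_lt(abs(b$y_nm - (a$y_nm + 5 * 77.7)), 0.01 * 77.7)

  blank <- mcs_image(matrix(0, 64, 64), 77.7, background_corrected = TRUE)
  expect_equal(n_puncta(detect_puncta(blank)), 0)
  expect_error(detect_puncta(mcs_image(matrix(1, 8, 8), 77.7)),
               "background-corrected")
})

test_that("dense fields are detected with high precision and recall", {
  spec <- scene_spec(seed = 31L, gaussian_sd = 2, poisson_scaling = 1)
  m <- make_cell_and_mito_masks(spec, 0)
  bg <- border_bg(256, 256)
  for (f in c(0, 0.3, 0.8)) {
    gt <- place_puncta(m$cell, m$mito, 100, 100, f_coloc = f,
                       min_spacing_nm = 6 * 77.7, seed = 40L + round(10 * f))
    img <- render_channel(gt$ref$x_nm, gt$ref$y_nm, spec, amplitudes = 1000,
                          noise_seed = 50L + round(10 * f))
    pf <- detect_puncta(subtract_background(img, bg))
    mt <- match_detections(pf, gt$ref, tol_nm = 2 * 77.7)
    expect_gte(mt$recall, 0.98)
    expect_gte(mt$precision, 0.98)
    expect_gte(mt$f1, 0.95)
  }
})

test_that("organelle masks recover the generating tubules", {
  spec <- scene_spec(seed = 13L, gaussian_sd = 2, poisson_scaling = 1)
  m <- make_cell_and_mito_masks(spec, 0.25)
  bg <- border_bg(256, 256)
  img <- subtract_background(render_mask_channel(m$mito, spec), bg)
  seg <- make_organelle_mask(img, cell = m$cell)
  jac <- sum(seg$data & m$mito$data) / sum(seg$data | m$mito$data)
  expect_gte(jac, 0.7)

  expect_identical(make_organelle_mask(img, cell = m$cell)$data, seg$data)

  blank <- mcs_image(matrix(0, 64, 64), 77.7, background_corrected = TRUE)
  expect_false(any(make_organelle_mask(blank)$data))
})

test_that("nucleus counting matches disjoint blobs and merges touching ones", {
  spec <- scene_spec(seed = 17L)
  scn <- make_pla_scene(10, 0, spec, seed = 23L)
  res <- count_nuclei(scn$dapi)
  expect_equal(res$count, 10)

  expect_equal(count_nuclei(mcs_image(matrix(0, 64, 64), 77.7))$count, 0)

  # two nuclei closer than one diameter merge after smoothing: documented
  # undercount of connected-component counting
  col0 <- matrix(rep(0:127, each = 128), 128)
  row0 <- matrix(rep(0:127, times = 128), 128)
  r <- 9
  touch <- 1000 * (((col0 - 55)^2 + (row0 - 64)^2 <= r^2) |
                   ((col0 - 68)^2 + (row0 - 64)^2 <= r^2))
  res2 <- count_nuclei(mcs_image(touch, 77.7))
  expect_equal(res2$count, 1)
})

test_that("max z-projection is the per-pixel maximum", {
  psz <- 77.7
  arr <- array(0, c(4, 4, 3))
  arr[2, 2, ] <- c(3, 7, 5)
  proj <- max_z_project(mcs_image(arr, psz))
  expect_equal(proj$data[2, 2], 7)
  expect_equal(proj$data[1, 1], 0)

  flat <- mcs_image(matrix(1:16, 4, 4), psz)
  expect_identical(max_z_project(flat)$data, flat$data)

  spot <- array(0, c(4, 4, 2))
  spot[3, 3, 2] <- 9
  expect_equal(max_z_project(mcs_image(spot, psz))$data[3, 3], 9)
})
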