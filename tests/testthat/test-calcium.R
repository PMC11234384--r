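test_that("trace extraction subtracts background frame by frame", {
  psz <- 77.7
  arr <- array(10, c(16, 16, 5))
  arr[1:4, 1:4, ] <- 4                      # background corner
  roi <- mcs_mask({m <- matrix(FALSE, 16, 16); m[8:12, 8:12] <- TRUE; m},
                  psz, "roi")
  bg <- mcs_mask({m <- matrix(FALSE, 16, 16); m[1:4, 1:4] <- TRUE; m},
                 psz, "background")
  tr <- extract_trace(mcs_image(arr, psz), roi, bg)
  expect_equal(tr$F, rep(6, 5))
  expect_equal(tr$time_s, 0:4)

  # ROI identical to background region gives a zero trace
  tr0 <- extract_trace(mcs_image(arr, psz), bg, bg)
  expect_true(all(tr0$F == 0))

  one <- extract_trace(mcs_image(array(7, c(4, 4, 1)), psz), roi = bg,
                       bg_roi = bg)
  expect_equal(length(one$F), 1)
  expect_error(extract_trace(mcs_image(arr, psz),
                             mcs_mask(matrix(FALSE, 16, 16), psz, "roi"), bg),
               "empty")
})

test_that("F_max normalization recovers the saturated plateau", {
  spec0 <- calcium_trace_spec(noise_sd_frac = 0)
  tr <- mcsquant:::synth_calcium_trace(spec0, f_max = 1000)
  nt <- normalize_fmax(tr, c(155, 180))
  expect_equal(nt$F_max, 1000)
  expect_equal(mean(nt$F_over_Fmax[155:180]), 1)

  spec1 <- calcium_trace_spec(baseline_frac = 0.2, peak_frac = 0.55,
                              noise_sd_frac = 0.01, seed = 5L)
  tr1 <- mcsquant:::synth_calcium_trace(spec1, f_max = 800)
  nt1 <- normalize_fmax(tr1, c(155, 180))
  expect_lt(abs(nt1$F_max - 800) / 800, 0.02)

  # window on the baseline: plateau below the response peak is rejected
  expect_error(normalize_fmax(tr, c(1, 20)), "invalid F_max window")
  expect_error(normalize_fmax(tr, c(179, 180)), "3 frames")
})

test_that("peak dF/F_max recovery, windows and the linearity flag", {
  spec0 <- calcium_trace_spec(noise_sd_frac = 0)
  nt <- normalize_fmax(mcsquant:::synth_calcium_trace(spec0), c(155, 180))
  d <- peak_delta(nt, c(1, 29), c(30, 120))
  expect_equal(as.numeric(d), 0.35, tolerance = 0.02)
  expect_false(attr(d, "linearity_flag"))

  flat_spec <- calcium_trace_spec(baseline_frac = 0.3, peak_frac = 0.3,
                                  noise_sd_frac = 0)
  ntf <- normalize_fmax(mcsquant:::synth_calcium_trace(flat_spec),
                        c(155, 180))
  expect_equal(as.numeric(peak_delta(ntf, c(1, 29), c(30, 120))), 0)

  # large responses leave the linear-fluorescence regime
  big <- calcium_trace_spec(baseline_frac = 0.2, peak_frac = 0.8,
                            noise_sd_frac = 0)
  ntb <- normalize_fmax(mcsquant:::synth_calcium_trace(big), c(155, 180))
  db <- peak_delta(ntb, c(1, 29), c(30, 120))
  expect_equal(as.numeric(db), 0.6, tolerance = 0.02)
  expect_true(attr(db, "linearity_flag"))

  expect_error(peak_delta(nt, c(1, 40), c(30, 120)), "after the baseline")

  noisy <- calcium_trace_spec(baseline_frac = 0.2, peak_frac = 0.55,
                              noise_sd_frac = 0.01, seed = 9L)
  ntn <- normalize_fmax(mcsquant:::synth_calcium_trace(noisy), c(155, 180))
  expect_lt(abs(as.numeric(peak_delta(ntn, c(1, 29), c(30, 120))) - 0.35),
            0.02)
})

test_that("quantification is scale invariant and channel independent", {
  spec1 <- calcium_trace_spec(baseline_frac = 0.15, peak_frac = 0.4,
                              noise_sd_frac = 0.02, seed = 31L)
  tr <- mcsquant:::synth_calcium_trace(spec1, f_max = 500)
  q1 <- quantify_trace(tr, c(1, 29), c(30, 120), c(155, 180))

  scaled <- tr
  scaled$F <- tr$F * 7.3
  q2 <- quantify_trace(scaled, c(1, 29), c(30, 120), c(155, 180))
  expect_identical(q1$delta_f_over_fmax, q2$delta_f_over_fmax)
  expect_equal(q2$f_max, q1$f_max * 7.3)

  # editing the mitochondrial channel leaves the cytosolic result unchanged
  pair <- make_calcium_trace_pair(
    calcium_trace_spec(seed = 1L), calcium_trace_spec(seed = 2L))
  qc <- quantify_trace(pair$cyto, c(1, 29), c(30, 120), c(155, 180))
  pair$mito$F <- rev(pair$mito$F)
  qc2 <- quantify_trace(pair$cyto, c(1, 29), c(30, 120), c(155, 180))
  expect_identical(qc$delta_f_over_fmax, qc2$delta_f_over_fmax)
})
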