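test_that("binarize separates foreground for two-level, grating and degenerate inputs", {
  two <- matrix(0, 32, 32); two[10:20, 5:25] <- 1
  expect_identical(binarize(two, "otsu"), two == 1)
  expect_identical(binarize(two, "quantile", quantile = 0.5), two == 1)

  # noiseless raised-cosine grating splits near its median level
  img <- make_grating(2.5)
  expect_gte(mean(binarize(img$data)), 0.45)
  expect_lte(mean(binarize(img$data)), 0.55)

  expect_error(binarize(matrix(0, 16, 16)), class = "dmq_degenerate_input")
  expect_error(binarize(matrix(0.7, 16, 16)), class = "dmq_degenerate_input")
})

test_that("noiseless gratings are recovered within bin quantization at all orientations", {
  for (period in c(2.0, 3.2)) {
    for (th in c(0, 30, 45, 90)) {
      img <- make_grating(period, orientation_deg = th, seed = 4)
      est <- estimate_sarcomere_length(img)
      b <- est$frequency_bin_width_cyc_per_um
      f_true <- 1 / period
      th_r <- th * pi / 180
      # each frequency axis quantizes to its nearest bin: half-bin per axis
      expect_lte(abs(est$peak_fx_cyc_per_um - f_true * cos(th_r)), b / 2 + 1e-12)
      expect_lte(abs(abs(est$peak_fy_cyc_per_um) - abs(f_true * sin(th_r))), b / 2 + 1e-12)
      # period within one full bin of truth
      expect_lte(abs(est$modal_length_um - period), 2 * period_half_bin_um(est))
      # orientation recovered modulo 180
      dang <- abs(est$peak_orientation_deg - th) %% 180
      expect_lte(min(dang, 180 - dang), 3)
    }
  }
})

test_that("rotating a grating leaves the estimate within one bin", {
  ests <- vapply(c(0, 30, 45, 90), function(th) {
    estimate_sarcomere_length(make_grating(2.5, orientation_deg = th, seed = 4))$modal_length_um
  }, numeric(1))
  ref <- estimate_sarcomere_length(make_grating(2.5, seed = 4))
  expect_lte(max(ests) - min(ests), 2 * 2 * period_half_bin_um(ref))
})

test_that("the band-pass removes out-of-band periodicities and flags empty spectra", {
  expect_error(estimate_sarcomere_length(make_grating(1.0)),
               class = "dmq_out_of_band")
  expect_error(estimate_sarcomere_length(make_grating(5.5)),
               class = "dmq_out_of_band")
  # inclusive edges: 1.5 and 4.5 um are retained
  expect_s3_class(estimate_sarcomere_length(make_grating(1.5)), "sarcomere_estimate")
  expect_s3_class(estimate_sarcomere_length(make_grating(4.5)), "sarcomere_estimate")

  wn <- make_noise_image(seed = 2)
  expect_error(estimate_sarcomere_length(wn), class = "dmq_no_estimate")
  expect_error(sarcomere_oracle(wn, orientation_deg = 0), class = "dmq_no_estimate")
})

test_that("autocorrelation oracle matches construction and tracks the estimator", {
  img <- make_grating(2.5, seed = 6)
  expect_lte(abs(sarcomere_oracle(img, orientation_deg = 0) - 2.5), 0.02)

  # paired noisy sweep (short form; the acceptance suite runs 100 seeds)
  for (seed in 1:10) {
    period <- withr::with_seed(seed, stats::runif(1, 1.8, 4.0))
    img <- make_grating(period, noise_sd = 0.3, seed = seed)
    est <- estimate_sarcomere_length(img)
    orc <- sarcomere_oracle(img, orientation_deg = 0)
    expect_lte(abs(est$modal_length_um - orc), 2 * period_half_bin_um(est))
  }
})

test_that("estimation error grows with noise (common random numbers)", {
  # the binarized full-field grating is extremely noise-tolerant, so the
  # degradation only becomes visible at noise well above the signal amplitude
  levels <- c(0, 1.0, 2.0)
  n_seed <- 100
  errs <- matrix(NA_real_, n_seed, length(levels))
  for (s in seq_len(n_seed)) {
    period <- withr::with_seed(1000 + s, stats::runif(1, 1.8, 4.0))
    for (li in seq_along(levels)) {
      img <- make_grating(period, pixel_size_um = 0.1, shape = c(256L, 256L),
                          noise_sd = levels[li], seed = s)
      est <- tryCatch(estimate_sarcomere_length(img), dmq_error = function(e) NULL)
      errs[s, li] <- if (is.null(est)) NA else abs(est$modal_length_um - period)
    }
  }
  ok <- stats::complete.cases(errs)
  expect_gte(sum(ok), 75)
  mae <- colMeans(errs[ok, , drop = FALSE])
  expect_lte(mae[1], mae[2] + 1e-12)
  expect_lte(mae[2], mae[3] + 1e-12)
})
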