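test_that("grating construction forces the banding period and is seed-deterministic", {
  img <- make_grating(2.5, pixel_size_um = 0.1, seed = 3)
  # a profile along the fiber axis autocorrelates at a 25-px lag
  prof <- img$data[256, ]
  ac <- stats::acf(prof - mean(prof), lag.max = 40, plot = FALSE)$acf[, 1, 1]
  expect_equal(which.max(ac[11:41]) + 9, 25)

  a <- generate_striation_image(striation_spec(seed = 9, noise_sd = 0.2))
  b <- generate_striation_image(striation_spec(seed = 9, noise_sd = 0.2))
  c <- generate_striation_image(striation_spec(seed = 10, noise_sd = 0.2))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image$data, c$image$data))
  expect_true(all(a$image$data >= 0 & a$image$data <= 1))
})

test_that("ground truth enumerates lanes, branches and the interstitial ratio", {
  # no branching requested -> none in truth
  g0 <- make_fiber_field(branch_fraction = 0, seed = 5)
  expect_length(g0$truth$branched_fibers, 0)

  # every branched id refers to an existing lane, exactly once
  g1 <- make_fiber_field(branch_fraction = 0.5, gap_ratio = 0.3, seed = 5)
  expect_true(all(g1$truth$branched_fibers %in% seq_len(g1$truth$n_fibers)))
  expect_false(any(duplicated(g1$truth$branched_fibers)))
  expect_equal(length(g1$truth$branched_fibers), round(0.5 * g1$truth$n_fibers))

  # exhaustive pixel census of the noiseless mask reproduces the 0.26 target
  # ratio on a 40-fiber field
  sp <- striation_spec(period_um = 2.5, pixel_size_um = 0.5,
                       image_shape = c(512L, 512L), fiber_width_um = 5,
                       gap_to_fiber_ratio = 0.26, orientation_deg = 0, seed = 2)
  g <- generate_striation_image(sp)
  expect_gte(g$truth$n_fibers, 40)
  fiber_px <- sum(g$truth$fiber_mask & g$truth$in_lane)
  gap_px <- sum(!g$truth$fiber_mask & g$truth$in_lane)
  census <- gap_px / fiber_px
  expect_gte(census, 0.24)
  expect_lte(census, 0.28)
})

test_that("degenerate striation requests are rejected with classed errors", {
  expect_error(striation_spec(period_um = 0.15, pixel_size_um = 0.1),
               class = "dmq_calibration_error")
  expect_error(
    generate_striation_image(striation_spec(gap_to_fiber_ratio = 0,
                                            branch_fraction = 0.5)),
    class = "dmq_domain_error")
  expect_error(striation_spec(branch_fraction = 1.2), class = "dmq_domain_error")
})
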