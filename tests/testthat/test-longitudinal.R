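test_that("stripe masks profile to exact run widths with border runs discarded", {
  # horizontal fibers: 30 px fiber / 6 px gap, repeating down the rows
  mask <- matrix(FALSE, 360, 200)
  for (k in 0:9) mask[(k * 36 + 1):(k * 36 + 30), ] <- TRUE
  prof <- profile_along_line(mask, pixel_size_um = 0.2, orientation_deg = 0)
  fib <- prof$width_um[prof$label == "fiber"]
  gap <- prof$width_um[prof$label == "interstitial"]
  expect_true(all(abs(fib - 30 * 0.2) < 1e-9))
  expect_true(all(abs(gap - 6 * 0.2) < 1e-9))
  # labels alternate along the line
  expect_false(any(prof$label[-1] == prof$label[-nrow(prof)]))

  expect_error(profile_along_line(matrix(TRUE, 64, 64), 0.2, orientation_deg = 0),
               class = "dmq_insufficient_sampling")
})

test_that("interstitial ratio is the gap/fiber width quotient and is scale invariant", {
  prof <- tibble::tibble(
    label = rep(c("fiber", "interstitial"), 5),
    width_um = rep(c(25, 3), 5))
  class(prof) <- c("fiber_profile", class(prof))
  expect_equal(interstitial_ratio(prof), 0.12)
  expect_equal(interstitial_ratio(prof, mode = "per_pair"), 3 / 25)

  for (c_scale in c(0.1, 2, 17)) {
    scaled <- prof
    scaled$width_um <- scaled$width_um * c_scale
    expect_equal(interstitial_ratio(scaled), 0.12)
  }
})

test_that("gap ratio of synthetic fields is recovered within discretization", {
  for (case in list(list(th = 0, seed = 2), list(th = 30, seed = 3))) {
    g <- make_fiber_field(gap_ratio = 0.26, fiber_width_um = 18,
                          pixel_size_um = 0.15, shape = c(512L, 512L),
                          orientation_deg = case$th, noise_sd = 0.1,
                          seed = case$seed)
    m <- fiber_mask(g$image, orientation_deg = case$th)
    prof <- profile_along_line(m, 0.15, orientation_deg = case$th)
    r <- interstitial_ratio(prof)
    expect_lte(abs(r - 0.26) / 0.26, 0.10)
  }
})

test_that("branch counting matches generator ground truth", {
  for (bf in c(0, 0.25)) {
    for (seed in 1:3) {
      g <- make_fiber_field(gap_ratio = 0.3, branch_fraction = bf, seed = seed)
      br <- count_branched_fibers(g$truth$fiber_mask, 0.2)
      expect_equal(br$n_fibers, g$truth$n_fibers)
      expect_equal(br$n_branched, length(g$truth$branched_fibers))
      expect_equal(br$percent_branched,
                   100 * length(g$truth$branched_fibers) / g$truth$n_fibers)
    }
  }
})

test_that("touching or collinear straight fibers are not counted as branches", {
  # two parallel fibers joined by a short bridge: junction limbs are either
  # shorter than the limb minimum or anti-parallel -> not a Y
  m1 <- matrix(FALSE, 120, 300)
  m1[40:60, ] <- TRUE
  m1[64:84, ] <- TRUE
  m1[58:66, 148:152] <- TRUE   # 5-px bridge, ~1 um at 0.2 um/px
  br1 <- count_branched_fibers(m1, 0.2)
  expect_equal(br1$n_fibers, 1)     # merged into one component
  expect_equal(br1$n_branched, 0)

  # nearly collinear stripes meeting end-to-end
  m2 <- matrix(FALSE, 120, 300)
  m2[50:70, 1:150] <- TRUE
  m2[54:74, 150:300] <- TRUE
  br2 <- count_branched_fibers(m2, 0.2)
  expect_equal(br2$n_branched, 0)

  expect_error(count_branched_fibers(matrix(FALSE, 50, 50), 0.2),
               class = "dmq_zero_fibers")
})

test_that("adding straight fibers can only dilute the branched percentage", {
  g <- make_fiber_field(gap_ratio = 0.3, branch_fraction = 0.25, seed = 4)
  base <- count_branched_fibers(g$truth$fiber_mask, 0.2)
  expect_gte(base$percent_branched, 0)
  expect_lte(base$percent_branched, 100)
  # append one straight fiber below the field
  taller <- rbind(g$truth$fiber_mask, matrix(FALSE, 10, ncol(g$truth$fiber_mask)),
                  matrix(TRUE, 20, ncol(g$truth$fiber_mask)))
  more <- count_branched_fibers(taller, 0.2)
  expect_equal(more$n_fibers, base$n_fibers + 1)
  expect_lte(more$percent_branched, base$percent_branched)
})
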