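test_that("a single enclosed square cell measures its exact pixel area", {
  # ring drawn around a 10 x 10 px interior at 0.5 um/px -> 25 um^2
  m <- matrix(0, 16, 16)
  m[3, 3:14] <- 1; m[14, 3:14] <- 1; m[3:14, 3] <- 1; m[3:14, 14] <- 1
  seg <- segment_fibers(calibrated_image(m, 0.5))
  expect_equal(nrow(seg$fibers), 1)
  expect_equal(seg$fibers$area_um2, 25)
  expect_false(seg$fibers$border)

  # the same mask at twice the pixel size quadruples the area
  seg2 <- segment_fibers(calibrated_image(m, 1.0))
  expect_equal(seg2$fibers$area_um2, 100)

  expect_error(segment_fibers(calibrated_image(matrix(1, 16, 16), 0.5)),
               class = "dmq_segmentation_failure")
})

test_that("synthetic sections close against shoelace-oracle polygon areas", {
  g <- make_section(seed = 3)
  px <- g$image$pixel_size_um
  seg <- segment_fibers(get_channel(g$image, "laminin"))
  expect_equal(nrow(seg$fibers), 40)
  mid <- match_fibers_to_truth(seg, g$truth, px)
  expect_equal(sort(mid), 1:40)        # bijective matching
  rel <- abs(seg$fibers$area_um2 - g$truth$areas_um2[mid]) / g$truth$areas_um2[mid]
  expect_lt(max(rel), 0.02)
  # tessellation bookkeeping: recovered areas account for the tissue window
  expect_lt(abs(sum(seg$fibers$area_um2) - g$truth$tissue_area_um2) /
              g$truth$tissue_area_um2, 0.03)
})

test_that("central-nucleus classification agrees exactly with planted classes", {
  g <- make_section(seed = 4, central_fraction = 0.25, n_macrophages = 0,
                    n_cd68_only = 0)
  seg <- segment_fibers(get_channel(g$image, "laminin"))
  seg <- classify_central_nuclei(seg, get_channel(g$image, "nuclei"))
  mid <- match_fibers_to_truth(seg, g$truth, g$image$pixel_size_um)
  expect_identical(seg$fibers$central_nucleus, g$truth$central_nucleus[mid])
  expect_equal(100 * mean(seg$fibers$central_nucleus), 25)
  expect_true(all(seg$fibers$n_nuclei >= 1))
})

test_that("macrophage calls require nucleus/CD68 colocalization", {
  g <- make_section(seed = 5, n_macrophages = 12, n_cd68_only = 5)
  nuc <- get_channel(g$image, "nuclei"); cd <- get_channel(g$image, "cd68")
  res <- suppressMessages(count_macrophages(nuc, cd))
  expect_equal(res$macrophage_count, 12)
  expect_equal(res$macrophage_density_per_mm2, 12 / res$field_area_mm2)

  # empty CD68 channel -> zero density
  empty <- calibrated_image(matrix(0, nrow(cd$data), ncol(cd$data)), cd$pixel_size_um)
  expect_equal(count_macrophages(nuc, empty)$macrophage_count, 0)

  # registration guard
  small <- calibrated_image(matrix(0.5, 32, 32), cd$pixel_size_um)
  expect_error(count_macrophages(nuc, small), class = "dmq_registration_error")
})

test_that("section_report is invariant to channel storage order", {
  g <- make_section(seed = 6, n_macrophages = 7, n_cd68_only = 3)
  rep1 <- suppressMessages(section_report(g$image))
  # permute the slices, remap the roles
  arr <- g$image$data[, , c(3, 1, 2)]
  img2 <- calibrated_image(arr, g$image$pixel_size_um,
                           channels = c(cd68 = 1L, laminin = 2L, nuclei = 3L))
  rep2 <- suppressMessages(section_report(img2))
  expect_equal(rep1$macrophage_count, rep2$macrophage_count)
  expect_equal(rep1$percent_regenerating, rep2$percent_regenerating)
  expect_equal(rep1$fibers$area_um2, rep2$fibers$area_um2)
  expect_equal(rep1$macrophage_count, 7)
})
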