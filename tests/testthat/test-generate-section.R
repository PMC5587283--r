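test_that("cross-section generation is deterministic with coherent ground truth", {
  a <- make_section(seed = 11)
  b <- make_section(seed = 11)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$areas_um2, b$truth$areas_um2)

  tr <- a$truth
  # exact tessellation: shoelace areas sum to the tissue window area
  expect_equal(sum(tr$areas_um2), tr$tissue_area_um2, tolerance = 1e-9)
  # every cell appears exactly once in the label image and truth
  expect_setequal(setdiff(unique(as.vector(tr$label)), 0L), seq_len(40))
  expect_length(tr$areas_um2, 40)
  # every fiber got a nucleus
  expect_false(any(is.na(tr$nucleus_centers_px)))
  expect_equal(length(tr$central_nucleus), 40)
  expect_equal(sum(tr$central_nucleus), round(0.25 * 40))
})

test_that("boundary flags of the spec are honored end to end", {
  allc <- generate_cross_section(cross_section_spec(
    n_fibers = 20, central_nucleus_fraction = 1, macrophage_density_per_mm2 = 0,
    seed = 2))
  expect_true(all(allc$truth$central_nucleus))

  none <- generate_cross_section(cross_section_spec(
    n_fibers = 20, macrophage_density_per_mm2 = 0, seed = 2))
  expect_equal(max(get_channel(none$image, "cd68")$data), 0)
  expect_equal(none$truth$n_macrophages, 0)

  expect_error(cross_section_spec(n_fibers = 500, csa_mean_um2 = 500,
                                  image_shape = c(256L, 256L)),
               class = "dmq_packing_error")
})

test_that("macrophage counts follow the requested Poisson intensity", {
  # 500 / mm^2 on a 0.25 mm^2 field: expected 125, draws within 3*sqrt(125)
  for (seed in c(1, 2)) {
    g <- generate_cross_section(cross_section_spec(
      n_fibers = 40, csa_mean_um2 = 500, central_nucleus_fraction = 0,
      macrophage_density_per_mm2 = 500, pixel_size_um = 0.5,
      image_shape = c(1000L, 1000L), seed = seed))
    expect_equal(g$truth$field_area_mm2, 0.25)
    expect_lte(abs(g$truth$n_macrophages - 125), 3 * sqrt(125))
  }
})
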