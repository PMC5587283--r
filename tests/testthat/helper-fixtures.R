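# Shared fixture builders. Everything is generated in code; no files.

# Full-field noiseless (or noisy) grating: banding only, no interstitium.
make_grating <- function(period_um, pixel_size_um = 0.1, shape = c(512L, 512L),
                         orientation_deg = 0, noise_sd = 0, seed = 1) {
  generate_striation_image(striation_spec(
    period_um = period_um, pixel_size_um = pixel_size_um, image_shape = shape,
    fiber_width_um = 60, gap_to_fiber_ratio = 0, branch_fraction = 0,
    orientation_deg = orientation_deg, noise_sd = noise_sd, seed = seed
  ))$image
}

# Striation field with resolvable fibers, for mask/profile/branch tests.
make_fiber_field <- function(gap_ratio = 0.26, branch_fraction = 0,
                             fiber_width_um = 6, pixel_size_um = 0.2,
                             shape = c(384L, 384L), orientation_deg = 0,
                             noise_sd = 0, seed = 1, period_um = 2.5) {
  generate_striation_image(striation_spec(
    period_um = period_um, pixel_size_um = pixel_size_um, image_shape = shape,
    fiber_width_um = fiber_width_um, gap_to_fiber_ratio = gap_ratio,
    branch_fraction = branch_fraction, orientation_deg = orientation_deg,
    noise_sd = noise_sd, seed = seed
  ))
}

# Uniform-intensity white-noise field (no periodic structure).
make_noise_image <- function(seed = 1, shape = c(512L, 512L), pixel_size_um = 0.1) {
  withr::with_seed(seed, {
    m <- matrix(pmin(pmax(0.5 + 0.2 * stats::rnorm(prod(shape)), 0), 1),
                shape[1], shape[2])
  })
  calibrated_image(m, pixel_size_um)
}

# Small synthetic cross-section with fixed object counts.
make_section <- function(seed = 1, n_fibers = 40, central_fraction = 0.25,
                         n_macrophages = 12, n_cd68_only = 5) {
  generate_cross_section(cross_section_spec(
    n_fibers = n_fibers, csa_mean_um2 = 500, csa_sd_um2 = 150,
    central_nucleus_fraction = central_fraction,
    macrophage_density_per_mm2 = 0, n_macrophages = n_macrophages,
    n_cd68_only = n_cd68_only, seed = seed
  ))
}

# Match segmented fibers to ground-truth cells by nearest seed point.
match_fibers_to_truth <- function(seg, truth, pixel_size_um) {
  cx <- seg$fibers$centroid_col * pixel_size_um
  cy <- seg$fibers$centroid_row * pixel_size_um
  vapply(seq_len(nrow(seg$fibers)), function(i) {
    which.min((truth$seeds_um[, 1] - cx[i])^2 + (truth$seeds_um[, 2] - cy[i])^2)
  }, integer(1))
}

# Metric table with one metric and 18 groups drawn from a single normal
# (global-null fixture for FWER checks).
null_metric_table <- function(n_per_group = 10, mean = 0, sd = 1) {
  g <- expand.grid(genotype = c("control", "mdx"), age_months = c(3L, 7L, 10L),
                   region = c("dorsal", "midcostal", "ventral"),
                   stringsAsFactors = FALSE)
  tibble::tibble(
    genotype = rep(g$genotype, each = n_per_group),
    age_months = rep(g$age_months, each = n_per_group),
    region = rep(g$region, each = n_per_group),
    image_id = sprintf("img%04d", seq_len(nrow(g) * n_per_group)),
    metric = "m",
    value = stats::rnorm(nrow(g) * n_per_group, mean, sd)
  )
}
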