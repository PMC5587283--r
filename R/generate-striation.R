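#' Specification for a synthetic longitudinal (striated-fiber) image
#'
#' Describes an idealized whole-mount confocal field: parallel muscle fibers
#' with periodic alpha-actinin-like banding along the fiber axis, interstitial
#' gaps of known relative width, and an optional fraction of fibers carrying
#' one Y-branch. The raised-cosine banding keeps the modal period analytically
#' known while remaining thresholdable like a real Z-line stain.
#'
#' @param period_um Sarcomere (banding) period in micrometres. Must exceed
#'   twice the pixel size (Nyquist).
#' @param pixel_size_um Calibration, micrometres per pixel.
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param fiber_width_um Width of each fiber in micrometres.
#' @param gap_to_fiber_ratio Interstitial gap width relative to fiber width
#'   (dimensionless, >= 0). This is the ground-truth interstitial-space ratio.
#' @param branch_fraction Fraction of in-frame fibers carrying one Y-branch.
#' @param orientation_deg Fiber-axis angle in degrees from the image x axis
#'   (columns), measured in the image coordinate frame.
#' @param noise_sd Standard deviation of additive Gaussian noise relative to
#'   the unit signal amplitude.
#' @param seed Integer seed; all randomness in the generator derives from it.
#'
#' @return An object of class `striation_spec`.
#' @export
striation_spec <- function(period_um = 2.5,
                           pixel_size_um = 0.1,
                           image_shape = c(512L, 512L),
                           fiber_width_um = 25,
                           gap_to_fiber_ratio = 0.12,
                           branch_fraction = 0,
                           orientation_deg = 0,
                           noise_sd = 0,
                           seed = 1L) {
  assert_scalar_number(period_um, "period_um", lower = 1e-6)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  assert_scalar_number(fiber_width_um, "fiber_width_um", lower = 1e-6)
  assert_scalar_number(gap_to_fiber_ratio, "gap_to_fiber_ratio", lower = 0)
  assert_scalar_number(branch_fraction, "branch_fraction", lower = 0, upper = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(orientation_deg, "orientation_deg")
  if (period_um <= 2 * pixel_size_um) {
    stop_dmq("dmq_calibration_error",
             "period %.3g um is at or below the Nyquist limit (2 px = %.3g um)",
             period_um, 2 * pixel_size_um)
  }
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16L))
  structure(
    list(period_um = period_um, pixel_size_um = pixel_size_um,
         image_shape = image_shape, fiber_width_um = fiber_width_um,
         gap_to_fiber_ratio = gap_to_fiber_ratio,
         branch_fraction = branch_fraction,
         orientation_deg = orientation_deg, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "striation_spec"
  )
}

# Baseline and banding amplitude inside fibers. Troughs stay well above the
# interstitial background so a fiber mask can be recovered by thresholding.
.FIBER_BASE <- 0.3
.FIBER_AMP  <- 0.7

#' Generate a synthetic striated-fiber image with ground truth
#'
#' Renders parallel fibers at `orientation_deg` whose intensity along the
#' fiber axis is a raised cosine of period `period_um`; inter-fiber gaps are
#' background. A chosen subset of fibers splits into two daughter branches
#' diverging at +/-15 degrees (capped so each branched fiber stays inside its
#' own lane), with banding parallel to the trunk. Deterministic per seed.
#'
#' @param spec A [striation_spec()].
#' @return A list with elements `image` (a [calibrated_image()]) and `truth`,
#'   a ground-truth list: `period_um`, `orientation_deg`, `n_fibers`,
#'   `branched_fibers` (integer ids), `interstitial_ratio`, `fiber_mask`
#'   (noiseless logical matrix), `in_lane` (logical matrix marking the region
#'   tiled by complete fiber lanes, for exact pixel-census checks), and
#'   `band_phase_um`.
#' @export
generate_striation_image <- function(spec) {
  stopifnot(inherits(spec, "striation_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px <- spec$pixel_size_um
  th <- spec$orientation_deg * pi / 180

  x <- (seq_len(nc) - 1) * px
  y <- (seq_len(nr) - 1) * px
  # u: along-fiber coordinate; v: across-fiber coordinate (um)
  U <- outer(y * sin(th), x * cos(th), "+")
  V <- outer(y * cos(th), -x * sin(th), "+")

  w <- spec$fiber_width_um
  g <- spec$gap_to_fiber_ratio * w
  p <- w + g

  s <- V - min(V)
  if (g == 0) {
    if (spec$branch_fraction > 0) {
      stop_dmq("dmq_domain_error",
               "branch_fraction > 0 requires gap_to_fiber_ratio > 0 (fibers must be resolvable)")
    }
    # continuous tissue: fibers abut with no interstitium -> one uniform field
    n_lanes <- max(1L, floor((max(s)) / w))
  } else {
    n_lanes <- max(0L, floor((max(s) - w - g) / p) + 1L)
  }
  if (n_lanes < 1L) {
    stop_dmq("dmq_domain_error",
             "field too small to hold one fiber of width %.3g um", w)
  }

  withr::with_seed(spec$seed, {
    phase <- stats::runif(1, 0, spec$period_um)
    n_br <- round(spec$branch_fraction * n_lanes)
    branched <- sort(sample.int(n_lanes, n_br))
    u_range <- range(U)
    u_span <- diff(u_range)
    u_j <- stats::runif(n_br, u_range[1] + 0.2 * u_span, u_range[1] + 0.8 * u_span)
    noise <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    } else NULL
  })

  if (g == 0) {
    in_lane <- matrix(TRUE, nr, nc)
    mask <- in_lane
  } else {
    lane <- floor(s / p)                  # 0-based lane index
    in_lane <- lane >= 0 & lane < n_lanes
    smod <- s - lane * p                  # within-lane coordinate [0, p)
    straight_ok <- !(lane + 1L) %in% branched
    mask <- in_lane & straight_ok & smod >= g / 2 & smod < g / 2 + w
  }

  # Branched lanes: trunk up to the junction, then two daughters (width 0.4 w)
  # diverging at +/-15 deg until their centers reach +/-0.3 w, leaving a
  # 0.2 w gap between daughters while staying inside the lane.
  if (length(branched)) {
    tan15 <- tan(15 * pi / 180)
    for (k in seq_along(branched)) {
      b <- branched[k]
      sel <- in_lane & lane == (b - 1L)
      sm <- smod
      cen <- g / 2 + w / 2
      d <- pmin(tan15 * (U - u_j[k]), 0.3 * w)
      trunk <- sel & U <= u_j[k] & sm >= g / 2 & sm < g / 2 + w
      daught <- sel & U > u_j[k] &
        (abs(sm - cen - d) <= 0.2 * w | abs(sm - cen + d) <= 0.2 * w)
      mask <- mask | trunk | daught
    }
  }

  band <- 0.5 * (1 + cos(2 * pi * (U - phase) / spec$period_um))
  img <- matrix(0, nr, nc)
  img[mask] <- .FIBER_BASE + .FIBER_AMP * band[mask]
  if (!is.null(noise)) img <- img + noise
  img <- pmin(pmax(img, 0), 1)

  truth <- list(
    period_um = spec$period_um,
    orientation_deg = spec$orientation_deg %% 180,
    n_fibers = n_lanes,
    branched_fibers = branched,
    interstitial_ratio = spec$gap_to_fiber_ratio,
    fiber_mask = mask,
    in_lane = in_lane,
    band_phase_um = phase
  )
  list(image = calibrated_image(img, px), truth = truth)
}
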