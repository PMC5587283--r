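#' Physiological sarcomere-length band
#'
#' The band-pass applied to the 2D power spectrum: spectral bins whose period
#' falls outside `[min_length_um, max_length_um]` are discarded as
#' unphysiological. Edges are inclusive (a 1.5 um period is retained;
#' "below 1.5 um" excludes strictly smaller periods only).
#'
#' @param min_length_um,max_length_um Band edges in micrometres.
#' @return An object of class `sarcomere_band`.
#' @export
sarcomere_band <- function(min_length_um = 1.5, max_length_um = 4.5) {
  assert_scalar_number(min_length_um, "min_length_um", lower = 1e-9)
  assert_scalar_number(max_length_um, "max_length_um", lower = min_length_um + 1e-12)
  structure(list(min_length_um = min_length_um, max_length_um = max_length_um),
            class = "sarcomere_band")
}

#' Binarize a grayscale image
#'
#' @param image A single-channel [calibrated_image()] or numeric matrix with
#'   intensities in `[0, 1]`.
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param quantile Foreground quantile when `method = "quantile"`: pixels above
#'   this intensity quantile are foreground.
#' @return A logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(image, method = c("otsu", "quantile"), quantile = 0.5) {
  method <- match.arg(method)
  m <- if (inherits(image, "calibrated_image")) image$data else image
  if (!is.matrix(m)) {
    stop_dmq("dmq_domain_error", "binarize() requires a single-channel image")
  }
  rng <- range(m)
  if (diff(rng) < 1e-9) {
    stop_dmq("dmq_degenerate_input",
             "constant image: no threshold separates foreground from background")
  }
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(pmin(pmax(m, 0), 1)), range = c(0, 1)),
    quantile = stats::quantile(m, quantile, names = FALSE)
  )
  bw <- m > thr
  frac <- mean(bw)
  if (frac <= 0 || frac >= 1) {
    stop_dmq("dmq_degenerate_input",
             "degenerate threshold: foreground fraction %.3f", frac)
  }
  bw
}

fft_freqs <- function(n, pixel_size_um) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / (n * pixel_size_um)
}

#' Estimate modal sarcomere length from the 2D power spectrum
#'
#' The image is binarized, mean-subtracted, zero-padded to the next power of
#' two at least twice each dimension, and transformed with a 2D FFT. Within a
#' scan annulus (periods in `[min_length/3, 3 * max_length]`; lower
#' frequencies are fiber-scale envelope, not banding) the strongest spectral
#' bin is located. If its magnitude does not exceed `noise_floor_mult` times
#' the median annulus magnitude, there is no periodicity to report
#' (`dmq_no_estimate`). If the strongest periodicity lies outside the
#' physiological band, the band-pass has removed it (`dmq_out_of_band`).
#' Otherwise the modal length is the period of that bin (the dominant spacing
#' in the first-harmonic ring) and the orientation is the angle of the bin's
#' frequency vector, i.e. the fiber-axis angle.
#'
#' Ties in magnitude break toward the lower frequency (longer sarcomere),
#' then the smaller angle, so output is deterministic.
#'
#' @param image A single-channel [calibrated_image()].
#' @param band A [sarcomere_band()].
#' @param threshold_method,threshold_quantile Passed to [binarize()].
#' @param use_binary Compute the spectrum of the binarized image (default,
#'   matching the thresholding step of the original workflow); set `FALSE`
#'   to use the grayscale image for sensitivity checks.
#' @param pad_factor Zero-padding factor (>= 1); the padded side is the next
#'   power of two >= `pad_factor * dim`.
#' @param noise_floor_mult Peak must exceed this multiple of the median
#'   annulus magnitude to count as a detection.
#'
#' @return A list of class `sarcomere_estimate`: `modal_length_um`,
#'   `peak_frequency_cyc_per_um`, `peak_orientation_deg` (in `[0, 180)`),
#'   `peak_magnitude`, `frequency_bin_width_cyc_per_um`, `band`.
#' @export
estimate_sarcomere_length <- function(image,
                                      band = sarcomere_band(),
                                      threshold_method = "otsu",
                                      threshold_quantile = 0.5,
                                      use_binary = TRUE,
                                      pad_factor = 2,
                                      noise_floor_mult = 5) {
  stopifnot(inherits(image, "calibrated_image"), inherits(band, "sarcomere_band"))
  px <- image$pixel_size_um
  m <- image$data
  if (!is.matrix(m)) stop_dmq("dmq_domain_error", "single-channel image required")

  src <- if (use_binary) {
    bw <- binarize(m, method = threshold_method, quantile = threshold_quantile)
    bw * 1
  } else m
  src <- src - mean(src)

  np <- 2^ceiling(log2(pad_factor * max(dim(m))))
  bin_w <- 1 / (np * px)
  f_lo <- 1 / band$max_length_um
  if (f_lo <= bin_w) {
    stop_dmq("dmq_calibration_error",
             "image too small: band frequencies do not exceed one frequency bin")
  }
  pad <- matrix(0, np, np)
  pad[seq_len(nrow(m)), seq_len(ncol(m))] <- src
  mag <- Mod(stats::fft(pad))

  fy <- fft_freqs(np, px)
  fx <- fft_freqs(np, px)
  FR <- sqrt(outer(fy^2, fx^2, "+"))

  scan_lo <- 1 / (3 * band$max_length_um)
  scan_hi <- 3 / band$min_length_um
  scan <- FR >= scan_lo & FR <= scan_hi
  vals <- mag[scan]
  floor_mag <- noise_floor_mult * stats::median(vals)
  peak_mag <- max(vals)
  if (peak_mag <= floor_mag) {
    stop_dmq("dmq_no_estimate",
             "no spectral peak above the noise floor (peak %.3g <= floor %.3g)",
             peak_mag, floor_mag)
  }

  cand <- which(scan & mag >= peak_mag * (1 - 1e-12), arr.ind = TRUE)
  cf <- FR[cand]
  cang <- (atan2(fy[cand[, 1]], fx[cand[, 2]]) * 180 / pi) %% 180
  ord <- order(cf, cang)
  besti <- ord[1]
  f_peak <- cf[besti]
  ang <- cang[besti]

  period <- 1 / f_peak
  if (period < band$min_length_um || period > band$max_length_um) {
    stop_dmq("dmq_out_of_band",
             "strongest periodicity (%.3g um) lies outside the %.3g-%.3g um band",
             period, band$min_length_um, band$max_length_um)
  }
  structure(
    list(modal_length_um = period,
         peak_frequency_cyc_per_um = f_peak,
         peak_fx_cyc_per_um = fx[cand[besti, 2]],
         peak_fy_cyc_per_um = fy[cand[besti, 1]],
         peak_orientation_deg = ang,
         peak_magnitude = peak_mag,
         frequency_bin_width_cyc_per_um = bin_w,
         band = band),
    class = "sarcomere_estimate"
  )
}

#' @export
print.sarcomere_estimate <- function(x, ...) {
  cat(sprintf(
    "<sarcomere_estimate> modal length %.4g um (f = %.4g cyc/um, bin %.4g), axis %.1f deg\n",
    x$modal_length_um, x$peak_frequency_cyc_per_um,
    x$frequency_bin_width_cyc_per_um, x$peak_orientation_deg))
  invisible(x)
}

#' Half-bin tolerance of an estimate, in period units
#'
#' The spectral bin quantization expressed as a period tolerance at the
#' estimated frequency: `bin_width / f^2 / 2`.
#'
#' @param est A `sarcomere_estimate`.
#' @return Tolerance in micrometres.
#' @export
period_half_bin_um <- function(est) {
  est$frequency_bin_width_cyc_per_um / est$peak_frequency_cyc_per_um^2 / 2
}

# Bilinear interpolation of matrix m at (row, col) positions (vectors).
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r0 <- pmin(pmax(r0, 1L), nr - 1L); c0 <- pmin(pmax(c0, 1L), nc - 1L)
  i00 <- m[cbind(r0, c0)];     i01 <- m[cbind(r0, c0 + 1L)]
  i10 <- m[cbind(r0 + 1L, c0)]; i11 <- m[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
}

# Dominant fiber-axis angle from the intensity structure tensor. Banding
# varies along the fiber axis, so the dominant gradient direction IS the
# axis; for a binary fiber mask the dominant gradient is across the fibers
# and the axis is orthogonal to it (set `across = TRUE`).
structure_tensor_axis <- function(m, across = FALSE) {
  sm <- EBImage::gblur(EBImage::Image(m), sigma = 2)
  sm <- sm@.Data
  gx <- (cbind(sm[, -1], sm[, ncol(sm)]) - cbind(sm[, 1], sm[, -ncol(sm)])) / 2
  gy <- (rbind(sm[-1, ], sm[nrow(sm), ]) - rbind(sm[1, ], sm[-nrow(sm), ])) / 2
  jxx <- mean(gx^2); jyy <- mean(gy^2); jxy <- mean(gx * gy)
  ang <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  if (across) ang <- ang + 90
  ang %% 180
}

#' Autocorrelation oracle for sarcomere length
#'
#' Mechanizes the by-hand measurement: extracts many intensity profiles along
#' the fiber axis, averages their (biased) autocorrelations, and returns the
#' dominant in-band lag converted to micrometres. The integer-lag peak is
#' refined by 3-point parabolic interpolation. This path shares nothing with
#' the spectral estimator beyond the input image, so the two can cross-check
#' one another.
#'
#' @param image A single-channel [calibrated_image()].
#' @param band A [sarcomere_band()].
#' @param orientation_deg Fiber-axis angle; if `NULL`, estimated from the
#'   image structure tensor.
#' @param n_profiles Number of parallel profiles (>= 10).
#' @param min_peak Minimum normalized autocorrelation at the dominant lag for
#'   a detection; below it a `dmq_no_estimate` error is raised.
#' @return Length in micrometres (scalar).
#' @export
sarcomere_oracle <- function(image,
                             band = sarcomere_band(),
                             orientation_deg = NULL,
                             n_profiles = 64,
                             min_peak = 0.05) {
  stopifnot(inherits(image, "calibrated_image"))
  m <- image$data
  px <- image$pixel_size_um
  if (is.null(orientation_deg)) orientation_deg <- structure_tensor_axis(m)
  th <- orientation_deg * pi / 180
  n_profiles <- max(10L, as.integer(n_profiles))

  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  half_len <- 0.35 * min(nr, nc)
  t_steps <- seq(-half_len, half_len, by = 1)
  offs <- seq(-0.3 * min(nr, nc), 0.3 * min(nr, nc), length.out = n_profiles)
  du <- c(cos(th), sin(th))     # along-axis step (x, y)
  dv <- c(-sin(th), cos(th))    # across-axis offset

  L <- length(t_steps)
  max_lag <- min(L - 2L, ceiling(band$max_length_um / px) + 2L)
  acf_sum <- numeric(max_lag + 1L)
  used <- 0L
  for (o in offs) {
    rr <- cy + o * dv[2] + t_steps * du[2]
    cc <- cx + o * dv[1] + t_steps * du[1]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (sum(ok) < 0.9 * L) next
    prof <- bilinear_sample(m, rr[ok], cc[ok])
    prof <- prof - mean(prof)
    if (stats::sd(prof) < 1e-12) next
    a <- stats::acf(prof, lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = FALSE)$acf[, 1, 1]
    acf_sum <- acf_sum + a / a[1]
    used <- used + 1L
  }
  if (used < 10L) {
    stop_dmq("dmq_insufficient_sampling",
             "fewer than 10 usable profiles along the fiber axis")
  }
  ac <- acf_sum / used

  lag_lo <- max(2L, floor(band$min_length_um / px))
  lag_hi <- min(max_lag - 1L, ceiling(band$max_length_um / px))
  if (lag_hi <= lag_lo) {
    stop_dmq("dmq_calibration_error", "band maps to an empty lag range")
  }
  lags <- lag_lo:lag_hi
  vals <- ac[lags + 1L]
  best <- lags[which.max(vals)]
  if (max(vals) < min_peak) {
    stop_dmq("dmq_no_estimate",
             "no autocorrelation peak in band (max %.3g < %.3g)",
             max(vals), min_peak)
  }
  # parabolic refinement around the integer-lag peak (ac[k + 1] holds lag k)
  ym <- ac[best]; y0 <- ac[best + 1L]; yp <- ac[best + 2L]
  denom <- ym - 2 * y0 + yp
  delta <- if (abs(denom) > 1e-15) 0.5 * (ym - yp) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  (best + delta) * px
}
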