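#' Specification for a synthetic muscle cross-section image
#'
#' Describes an immunostained transverse field: convex fiber profiles tiling
#' a tissue window (laminin-like bright boundaries), one nucleus per fiber
#' placed centrally or peripherally, and point-like macrophages present in
#' both the nuclei and CD68 channels. Fiber profiles are Voronoi cells of
#' blue-noise seed points, clipped exactly, so every fiber has a known
#' polygon and shoelace area.
#'
#' @param n_fibers Number of fiber profiles (>= 1).
#' @param csa_mean_um2 Target mean fiber cross-sectional area, square um.
#'   The tissue window area is exactly `n_fibers * csa_mean_um2`.
#' @param csa_sd_um2 Dispersion dial for fiber areas (square um); larger
#'   values jitter the seed lattice more. The realized per-fiber areas are
#'   recorded in the ground truth, which is what closure tests compare.
#' @param central_nucleus_fraction Fraction of fibers whose nucleus is
#'   centrally placed (at the fiber's incenter; peripheral nuclei sit at
#'   ~12% normalized boundary distance).
#' @param macrophage_density_per_mm2 Expected macrophages per square mm of
#'   field; the realized count is Poisson unless `n_macrophages` fixes it.
#' @param pixel_size_um Calibration, micrometres per pixel.
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param seed Integer seed.
#' @param n_macrophages Optional fixed macrophage count (overrides the
#'   Poisson draw; used by exact-recovery tests).
#' @param n_cd68_only Number of CD68-positive blobs with no nucleus
#'   (distractors that must not be counted as macrophages).
#' @param nucleus_radius_um,macrophage_radius_um Object radii in um.
#' @param boundary_halfwidth_um Half-thickness of the laminin boundary band.
#'
#' @return An object of class `cross_section_spec`.
#' @export
cross_section_spec <- function(n_fibers = 40L,
                               csa_mean_um2 = 500,
                               csa_sd_um2 = 150,
                               central_nucleus_fraction = 0.1,
                               macrophage_density_per_mm2 = 100,
                               pixel_size_um = 0.25,
                               image_shape = c(640L, 640L),
                               seed = 1L,
                               n_macrophages = NULL,
                               n_cd68_only = 0L,
                               nucleus_radius_um = 1.5,
                               macrophage_radius_um = 2.5,
                               boundary_halfwidth_um = 0.5) {
  assert_scalar_number(n_fibers, "n_fibers", lower = 1)
  assert_scalar_number(csa_mean_um2, "csa_mean_um2", lower = 1e-6)
  assert_scalar_number(csa_sd_um2, "csa_sd_um2", lower = 0)
  assert_scalar_number(central_nucleus_fraction, "central_nucleus_fraction", 0, 1)
  assert_scalar_number(macrophage_density_per_mm2, "macrophage_density_per_mm2", lower = 0)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32L))
  field_area <- prod(image_shape) * pixel_size_um^2
  if (n_fibers * csa_mean_um2 > 0.95 * field_area) {
    stop_dmq("dmq_packing_error",
             "%d fibers of mean area %.4g um^2 cannot tile a %.4g um^2 field",
             n_fibers, csa_mean_um2, field_area)
  }
  structure(
    list(n_fibers = as.integer(n_fibers), csa_mean_um2 = csa_mean_um2,
         csa_sd_um2 = csa_sd_um2,
         central_nucleus_fraction = central_nucleus_fraction,
         macrophage_density_per_mm2 = macrophage_density_per_mm2,
         pixel_size_um = pixel_size_um, image_shape = image_shape,
         seed = as.integer(seed),
         n_macrophages = if (is.null(n_macrophages)) NULL else as.integer(n_macrophages),
         n_cd68_only = as.integer(n_cd68_only),
         nucleus_radius_um = nucleus_radius_um,
         macrophage_radius_um = macrophage_radius_um,
         boundary_halfwidth_um = boundary_halfwidth_um),
    class = "cross_section_spec"
  )
}

# ---- exact polygon geometry -------------------------------------------------

# Clip a convex polygon (n x 2 matrix, counter-clockwise) by the half-plane
# a.x <= b (Sutherland-Hodgman, one edge).
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- poly %*% a - b
  out <- matrix(0, 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, poly[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Shoelace area of a polygon given as an n x 2 matrix.
shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1L)
  abs(sum(poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2])) / 2
}

# Voronoi cell of seeds[k, ] within the rectangle [x0,x1] x [y0,y1].
voronoi_cell <- function(seeds, k, x0, x1, y0, y1) {
  poly <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  sk <- seeds[k, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == k) next
    sj <- seeds[j, ]
    a <- sj - sk                       # closer to sk than sj: a.x <= b
    b <- sum((sj + sk) * a) / 2
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) < 3L) break
  }
  poly
}

draw_disc <- function(channel, cx, cy, r_px, value = 1, keep = NULL) {
  nr <- nrow(channel); nc <- ncol(channel)
  r0 <- max(1L, floor(cy - r_px)); r1 <- min(nr, ceiling(cy + r_px))
  c0 <- max(1L, floor(cx - r_px)); c1 <- min(nc, ceiling(cx + r_px))
  if (r0 > r1 || c0 > c1) return(channel)
  rows <- r0:r1; cols <- c0:c1
  dd <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r_px^2
  if (!is.null(keep)) dd <- dd & keep[rows, cols]
  sub <- channel[rows, cols]
  sub[dd] <- value
  channel[rows, cols] <- sub
  channel
}

#' Generate a synthetic cross-section image with ground truth
#'
#' Produces a 3-channel [calibrated_image()] (`laminin`, `nuclei`, `cd68`).
#' Fiber profiles are exact Voronoi polygons of jittered-lattice seed points
#' tiling a centered tissue window of area `n_fibers * csa_mean_um2`; the
#' boundary channel draws a thin band centered on every shared cell edge
#' (and just outside the tissue perimeter). Each fiber carries one nucleus,
#' central or peripheral per its ground-truth flag. Macrophages are discs
#' painted into both the nuclei and CD68 channels at interstitial
#' (near-boundary) positions, mimicking their residence between fibers.
#'
#' @param spec A [cross_section_spec()].
#' @return A list with elements `image` and `truth`. `truth` contains
#'   `polygons` (list of n x 2 matrices, um coordinates), `areas_um2`
#'   (shoelace areas), `seeds_um`, `central_nucleus` (logical),
#'   `nucleus_centers_px`, `macrophage_centers_px`, `n_macrophages`,
#'   `cd68_only_centers_px`, `label` (pixel label matrix, 0 = background),
#'   and `field_area_mm2`.
#' @export
generate_cross_section <- function(spec) {
  stopifnot(inherits(spec, "cross_section_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px <- spec$pixel_size_um
  n <- spec$n_fibers
  W <- nc * px; H <- nr * px
  field_area_mm2 <- W * H / 1e6

  # Tissue window: centered rectangle of exact area n * csa_mean.
  a_t <- n * spec$csa_mean_um2
  ar <- W / H
  tw <- sqrt(a_t * ar); th_ <- sqrt(a_t / ar)
  if (tw > W - 4 * px || th_ > H - 4 * px) {
    sc <- min((W - 4 * px) / tw, (H - 4 * px) / th_)
    tw <- tw * sc; th_ <- th_ * sc   # keep >= 2 px inset; area shrinks slightly
  }
  x0 <- (W - tw) / 2; x1 <- x0 + tw
  y0 <- (H - th_) / 2; y1 <- y0 + th_

  withr::with_seed(spec$seed, {
    # Jittered lattice of exactly n seeds inside the tissue window.
    nx <- max(1L, round(sqrt(n * tw / th_)))
    ny <- ceiling(n / nx)
    cellw <- tw / nx; cellh <- th_ / ny
    idx <- sample.int(nx * ny, n)
    ix <- (idx - 1L) %% nx; iy <- (idx - 1L) %/% nx
    jit <- min(0.45, 0.5 * spec$csa_sd_um2 / spec$csa_mean_um2)
    sx <- x0 + (ix + 0.5 + stats::runif(n, -jit, jit)) * cellw
    sy <- y0 + (iy + 0.5 + stats::runif(n, -jit, jit)) * cellh
    seeds <- cbind(sx, sy)

    central <- rep(FALSE, n)
    central[sample.int(n, round(spec$central_nucleus_fraction * n))] <- TRUE

    m_count <- if (!is.null(spec$n_macrophages)) spec$n_macrophages else
      stats::rpois(1, spec$macrophage_density_per_mm2 * field_area_mm2)
    extra_draws <- stats::runif(4000L)  # reservoir for placement rejection
  })

  polys <- lapply(seq_len(n), function(k) voronoi_cell(seeds, k, x0, x1, y0, y1))
  areas <- vapply(polys, shoelace_area, numeric(1))

  # Pixel geometry. Pixel (i, j) center: x = (j - 0.5) px, y = (i - 0.5) px.
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  in_rect <- X >= x0 & X <= x1 & Y >= y0 & Y <= y1

  # Nearest and second-nearest seed distance per pixel (chunked over seeds).
  d1 <- matrix(Inf, nr, nc); d2 <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    dk <- (X - seeds[k, 1])^2 + (Y - seeds[k, 2])^2
    newbest <- dk < d1
    d2[newbest] <- d1[newbest]
    d1[newbest] <- dk[newbest]
    lab[newbest] <- k
    second <- !newbest & dk < d2
    d2[second] <- dk[second]
  }
  d1 <- sqrt(d1); d2 <- sqrt(d2)
  edge_dist <- (d2 - d1) / 2               # um, distance to shared cell edge
  rect_dist <- pmin(X - x0, x1 - X, Y - y0, y1 - Y)
  lab[!in_rect] <- 0L

  hb <- spec$boundary_halfwidth_um
  boundary <- (in_rect & edge_dist <= hb) |
    (!in_rect & rect_dist >= -2 * hb)      # perimeter band just outside tissue
  lam <- matrix(0, nr, nc); lam[boundary] <- 1

  # interior distance to any boundary (cell edge or tissue perimeter), um
  interior_dist <- pmin(edge_dist, rect_dist)
  interior_dist[!in_rect] <- 0

  nuclei <- matrix(0, nr, nc)
  cd68 <- matrix(0, nr, nc)
  r_n <- spec$nucleus_radius_um / px
  nucleus_centers <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    cells <- which(lab == k & interior_dist > 0)
    if (!length(cells)) next
    dk <- interior_dist[cells]
    inradius <- max(dk)
    if (central[k]) {
      pick <- cells[which.max(dk)]
    } else {
      pick <- cells[which.min(abs(dk - 0.12 * inradius))]
    }
    ci <- (pick - 1L) %% nr + 1L; cj <- (pick - 1L) %/% nr + 1L
    nucleus_centers[k, ] <- c(ci, cj)
    keep <- lab == k & !boundary          # clip nucleus to its own fiber
    nuclei <- draw_disc(nuclei, cj, ci, r_n, value = 1, keep = keep)
  }

  # Macrophages: interstitial residents; centers within 1 um of a cell edge
  # (or the tissue perimeter), pairwise separated so counts stay exact.
  elig <- which(lab > 0L & interior_dist <= max(1, px))
  mac_centers <- matrix(NA_real_, 0, 2)
  r_m <- spec$macrophage_radius_um / px
  di <- 1L
  if (length(elig) && m_count > 0) {
    for (m in seq_len(m_count)) {
      placed <- FALSE
      for (try in 1:60) {
        pick <- elig[ceiling(extra_draws[di] * length(elig))]; di <- di + 1L
        if (di > length(extra_draws)) di <- 1L
        ci <- (pick - 1L) %% nr + 1L; cj <- (pick - 1L) %/% nr + 1L
        if (nrow(mac_centers) == 0L ||
            min((mac_centers[, 1] - ci)^2 + (mac_centers[, 2] - cj)^2) > (2.5 * r_m)^2) {
          mac_centers <- rbind(mac_centers, c(ci, cj))
          placed <- TRUE
          break
        }
      }
      if (!placed) break   # field saturated; truth records what was placed
    }
  }
  for (m in seq_len(nrow(mac_centers))) {
    nuclei <- draw_disc(nuclei, mac_centers[m, 2], mac_centers[m, 1], r_m)
    cd68 <- draw_disc(cd68, mac_centers[m, 2], mac_centers[m, 1], r_m)
  }

  # CD68-only distractors: away from every nucleus.
  cd68_only <- matrix(NA_real_, 0, 2)
  if (spec$n_cd68_only > 0) {
    all_nuc <- rbind(nucleus_centers[stats::complete.cases(nucleus_centers), , drop = FALSE],
                     mac_centers)
    tissue_idx <- which(lab > 0L)
    min_sep <- (2 * spec$macrophage_radius_um + 2 * spec$nucleus_radius_um) / px
    for (m in seq_len(spec$n_cd68_only)) {
      for (try in 1:200) {
        pick <- tissue_idx[ceiling(extra_draws[di] * length(tissue_idx))]; di <- di + 1L
        if (di > length(extra_draws)) di <- 1L
        ci <- (pick - 1L) %% nr + 1L; cj <- (pick - 1L) %/% nr + 1L
        sep_nuc <- !nrow(all_nuc) ||
          min((all_nuc[, 1] - ci)^2 + (all_nuc[, 2] - cj)^2) > min_sep^2
        sep_self <- !nrow(cd68_only) ||
          min((cd68_only[, 1] - ci)^2 + (cd68_only[, 2] - cj)^2) > (2.5 * r_m)^2
        if (sep_nuc && sep_self) {
          cd68_only <- rbind(cd68_only, c(ci, cj))
          break
        }
      }
    }
    for (m in seq_len(nrow(cd68_only))) {
      cd68 <- draw_disc(cd68, cd68_only[m, 2], cd68_only[m, 1], 0.8 * r_m)
    }
  }

  arr <- array(0, dim = c(nr, nc, 3L))
  arr[, , 1] <- lam; arr[, , 2] <- nuclei; arr[, , 3] <- cd68
  img <- calibrated_image(arr, px, channels = c(laminin = 1L, nuclei = 2L, cd68 = 3L))

  truth <- list(
    polygons = polys,
    areas_um2 = areas,
    seeds_um = seeds,
    central_nucleus = central,
    nucleus_centers_px = nucleus_centers,
    macrophage_centers_px = mac_centers,
    n_macrophages = nrow(mac_centers),
    cd68_only_centers_px = cd68_only,
    label = lab,
    tissue_area_um2 = tw * th_,
    field_area_mm2 = field_area_mm2
  )
  list(image = img, truth = truth)
}
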