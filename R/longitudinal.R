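#' Recover a binary fiber mask from a longitudinal striation image
#'
#' Banding troughs inside fibers approach the interstitial background level,
#' so naive thresholding splits fibers into bands. Morphological closing
#' fills the troughs first; Otsu on the closed image then separates fibers
#' from interstitium.
#'
#' Banding troughs run across the fiber axis while interstitial gaps run
#' along it, so the closing uses a line-shaped structuring element oriented
#' along the fiber axis: troughs are filled, gaps (parallel to the line) are
#' left open even when narrower than a sarcomere.
#'
#' @param image A single-channel [calibrated_image()].
#' @param orientation_deg Fiber-axis angle; if `NULL`, estimated from the
#'   image structure tensor (banding gradients point along the axis).
#' @param close_length_um Length of the closing line (default 3, a little
#'   over one sarcomere).
#' @return A logical matrix (`TRUE` = fiber).
#' @export
fiber_mask <- function(image, orientation_deg = NULL, close_length_um = 3) {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.null(orientation_deg)) orientation_deg <- structure_tensor_axis(image$data)
  len <- max(3L, round(close_length_um / image$pixel_size_um))
  if (len %% 2 == 0) len <- len + 1L
  # brush angle 0 is a column (down the rows); a fiber axis at angle theta
  # from the column axis (x) maps to brush angle (90 - theta)
  brush <- EBImage::makeBrush(len, shape = "line",
                              angle = (90 - orientation_deg) %% 180)
  closed <- EBImage::closing(EBImage::Image(image$data), brush)@.Data
  binarize(closed, method = "otsu")
}

#' Fiber/interstitial width profile along a reference line
#'
#' Run-length encodes a binary fiber mask along a line orthogonal to the
#' fibers (the mechanized version of drawing a reference line across the
#' image), converting run lengths to micrometres. Leading and trailing runs
#' are discarded because they are cut by the image border.
#'
#' @param mask Logical matrix (`TRUE` = fiber) or a single-channel
#'   [calibrated_image()] holding one.
#' @param pixel_size_um Calibration; ignored when `mask` is calibrated.
#' @param line Optional list with `p0`, `p1` (each `c(row, col)`) giving the
#'   reference line endpoints in pixels. When omitted the line runs through
#'   the image center orthogonal to the dominant fiber orientation.
#' @param orientation_deg Optional fiber-axis angle used for automatic line
#'   placement; if `NULL` it is estimated from the mask structure tensor.
#' @return A tibble of class `fiber_profile` with columns `label`
#'   (`"fiber"`/`"interstitial"`) and `width_um`, in order along the line.
#' @export
profile_along_line <- function(mask, pixel_size_um = NULL, line = NULL,
                               orientation_deg = NULL) {
  if (inherits(mask, "calibrated_image")) {
    pixel_size_um <- mask$pixel_size_um
    mask <- mask$data > 0.5
  }
  stopifnot(is.matrix(mask))
  if (is.null(pixel_size_um)) {
    stop_dmq("dmq_calibration_error", "pixel_size_um is required for a bare mask")
  }
  mask <- mask > 0.5
  nr <- nrow(mask); nc <- ncol(mask)

  if (is.null(line)) {
    if (is.null(orientation_deg)) {
      orientation_deg <- structure_tensor_axis(mask * 1, across = TRUE)
    }
    phi <- (orientation_deg + 90) * pi / 180   # line direction, orthogonal to fibers
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    half <- max(nr, nc)
    ts <- seq(-half, half, by = 1)
    rr <- cy + ts * sin(phi)
    cc <- cx + ts * cos(phi)
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
  } else {
    p0 <- line$p0; p1 <- line$p1
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
    rr <- p0[1] + ts * (p1[1] - p0[1])
    cc <- p0[2] + ts * (p1[2] - p0[2])
  }
  vals <- mask[cbind(pmin(pmax(round(rr), 1L), nr), pmin(pmax(round(cc), 1L), nc))]

  r <- rle(vals)
  if (length(r$lengths) >= 3L) {
    keep <- 2:(length(r$lengths) - 1L)         # drop border-cut partial runs
    labels <- r$values[keep]
    widths <- r$lengths[keep] * pixel_size_um
  } else {
    labels <- logical(0); widths <- numeric(0)
  }
  if (sum(labels) < 2L || sum(!labels) < 1L) {
    stop_dmq("dmq_insufficient_sampling",
             "reference line crosses fewer than 2 fibers or no interstitium")
  }
  out <- tibble::tibble(
    label = ifelse(labels, "fiber", "interstitial"),
    width_um = widths
  )
  class(out) <- c("fiber_profile", class(out))
  attr(out, "line_px") <- list(p0 = c(rr[1], cc[1]), p1 = c(rr[length(rr)], cc[length(cc)]))
  out
}

#' Interstitial-space ratio from a width profile
#'
#' The ratio of interstitial width to fiber width along the reference line.
#' `mode = "mean_widths"` (default) divides the mean gap width by the mean
#' fiber width per image; `mode = "per_pair"` divides each gap by the mean of
#' its flanking fibers and averages the per-gap ratios (the aggregation is
#' ambiguous in manual workflows, so both are provided).
#'
#' @param profile A [profile_along_line()] result.
#' @param mode `"mean_widths"` or `"per_pair"`.
#' @return Dimensionless ratio (scalar).
#' @export
interstitial_ratio <- function(profile, mode = c("mean_widths", "per_pair")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "fiber_profile") || is.data.frame(profile))
  lab <- profile$label; w <- profile$width_um
  if (sum(lab == "fiber") < 1L || sum(lab == "interstitial") < 1L) {
    stop_dmq("dmq_insufficient_sampling", "profile needs >=1 fiber and >=1 gap segment")
  }
  mfw <- mean(w[lab == "fiber"])
  if (mfw <= 0) stop_dmq("dmq_degenerate_profile", "zero mean fiber width")
  if (mode == "mean_widths") {
    return(mean(w[lab == "interstitial"]) / mfw)
  }
  gi <- which(lab == "interstitial")
  ratios <- vapply(gi, function(i) {
    fl <- w[setdiff(c(i - 1L, i + 1L), c(0L, length(w) + 1L))]
    fl <- fl[lab[setdiff(c(i - 1L, i + 1L), c(0L, length(w) + 1L))] == "fiber"]
    if (!length(fl)) return(NA_real_)
    w[i] / mean(fl)
  }, numeric(1))
  mean(ratios, na.rm = TRUE)
}

# ---- skeletonization (Zhang-Suen thinning) ----------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen binary thinning; returns a 1-px-wide 8-connected skeleton.
skeletonize <- function(mask) {
  m <- mask > 0
  # neighbor order P2..P9: N, NE, E, SE, S, SW, W, NW  (row-1 = up)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (!nb[[i]] & nb[[j]])
      }
      if (step == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Analyze one skeleton: junction nodes, limbs, and the Y-branch decision.
# A junction qualifies as a branch point when, after discarding limbs shorter
# than min_limb_px, at least 3 limbs remain and the two most nearly parallel
# limbs (the daughters) subtend <= max_pair_angle_deg.
skeleton_has_branch <- function(skel, min_limb_px, max_pair_angle_deg = 150,
                                dir_window_px = NULL) {
  if (is.null(dir_window_px)) dir_window_px <- max(12L, ceiling(min_limb_px))
  pts <- which(skel, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(FALSE)
  nr <- nrow(skel); nc <- ncol(skel)
  key <- function(r, c) (c - 1L) * nr + r
  skel_idx <- key(pts[, 1], pts[, 2])
  on <- logical(nr * nc); on[skel_idx] <- TRUE

  nbrs <- function(r, c) {
    rs <- pmax(1L, r - 1L):pmin(nr, r + 1L)
    cs <- pmax(1L, c - 1L):pmin(nc, c + 1L)
    g <- expand.grid(r = rs, c = cs)
    g <- g[!(g$r == r & g$c == c), , drop = FALSE]
    g[on[key(g$r, g$c)], , drop = FALSE]
  }

  deg <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) deg[i] <- nrow(nbrs(pts[i, 1], pts[i, 2]))
  junc <- pts[deg >= 3L, , drop = FALSE]
  if (!nrow(junc)) return(FALSE)
  is_junc <- logical(nr * nc)
  is_junc[key(junc[, 1], junc[, 2])] <- TRUE

  # group nearby junction pixels into nodes (dilation bridges diagonal and
  # 2-px-apart junction pixels, which 4-connected labeling would split)
  jm <- matrix(FALSE, nr, nc); jm[junc] <- TRUE
  jd <- EBImage::dilate(EBImage::Image(jm * 1), EBImage::makeBrush(3, "box"))
  jl <- EBImage::bwlabel(jd)@.Data
  jl[!jm] <- 0L
  for (node in seq_len(max(jl))) {
    node_pts <- which(jl == node, arr.ind = TRUE)
    node_set <- key(node_pts[, 1], node_pts[, 2])
    cy <- mean(node_pts[, 1]); cx <- mean(node_pts[, 2])
    # limb seeds: skeleton neighbors of node pixels that are not junction px
    seeds <- unique(do.call(rbind, lapply(seq_len(nrow(node_pts)), function(i) {
      nb <- nbrs(node_pts[i, 1], node_pts[i, 2])
      nb[!is_junc[key(nb$r, nb$c)], , drop = FALSE]
    })))
    if (is.null(seeds) || nrow(seeds) < 3L) next
    limbs <- list()
    for (si in seq_len(nrow(seeds))) {
      prev <- c(cy, cx)
      cur <- c(seeds$r[si], seeds$c[si])
      visited <- c(node_set, key(cur[1], cur[2]))
      len <- sqrt(sum((cur - c(cy, cx))^2))
      dir_pt <- cur
      steps <- 0L
      repeat {
        steps <- steps + 1L
        nb <- nbrs(cur[1], cur[2])
        nb <- nb[!key(nb$r, nb$c) %in% visited, , drop = FALSE]
        if (!nrow(nb) || is_junc[key(cur[1], cur[2])]) break
        nxt <- c(nb$r[1], nb$c[1])
        visited <- c(visited, key(nxt[1], nxt[2]))
        len <- len + sqrt(sum((nxt - cur)^2))
        cur <- nxt
        if (steps <= dir_window_px) dir_pt <- cur
        if (steps > 10000L) break
      }
      limbs[[si]] <- list(len = len, dir = c(dir_pt[1] - cy, dir_pt[2] - cx))
    }
    lens <- vapply(limbs, `[[`, numeric(1), "len")
    keep <- lens >= min_limb_px
    if (sum(keep) < 3L) next
    dirs <- do.call(rbind, lapply(limbs[keep], `[[`, "dir"))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    np <- nrow(dirs)
    min_ang <- Inf
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      ca <- sum(dirs[i, ] * dirs[j, ])
      min_ang <- min(min_ang, acos(pmin(pmax(ca, -1), 1)) * 180 / pi)
    }
    if (min_ang <= max_pair_angle_deg) return(TRUE)
  }
  FALSE
}

#' Count Y-branched fibers in a longitudinal fiber mask
#'
#' Labels connected fiber components, skeletonizes each, and flags a fiber
#' as branched when its skeleton contains a junction with at least three
#' limbs each longer than `min_limb_um` whose daughter pair subtends at most
#' `max_pair_angle_deg` (limbs meeting nearly head-on, >150 degrees apart,
#' are through-going merges or crossings, not a "Y").
#'
#' @param mask Logical matrix or single-channel [calibrated_image()]
#'   (`TRUE`/bright = fiber).
#' @param pixel_size_um Calibration; ignored when `mask` is calibrated.
#' @param min_limb_um Minimum limb length for a limb to count (suppresses
#'   skeleton spurs from boundary noise).
#' @param max_pair_angle_deg Maximum angle between the two daughter limbs.
#' @param min_fiber_px Components smaller than this are ignored as debris.
#' @return A list of class `branch_report`: `n_fibers`, `n_branched`,
#'   `percent_branched`, `branched_ids`.
#' @export
count_branched_fibers <- function(mask, pixel_size_um = NULL,
                                  min_limb_um = 5,
                                  max_pair_angle_deg = 150,
                                  min_fiber_px = 25L) {
  if (inherits(mask, "calibrated_image")) {
    pixel_size_um <- mask$pixel_size_um
    mask <- mask$data > 0.5
  }
  if (is.null(pixel_size_um)) {
    stop_dmq("dmq_calibration_error", "pixel_size_um is required for a bare mask")
  }
  mask <- mask > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))@.Data
  sizes <- tabulate(lab[lab > 0])
  ids <- which(sizes >= min_fiber_px)
  if (!length(ids)) {
    stop_dmq("dmq_zero_fibers", "no fibers found in mask")
  }
  min_limb_px <- min_limb_um / pixel_size_um
  branched <- logical(length(ids))
  for (i in seq_along(ids)) {
    pts <- which(lab == ids[i], arr.ind = TRUE)
    r0 <- max(1L, min(pts[, 1]) - 1L); r1 <- min(nrow(mask), max(pts[, 1]) + 1L)
    c0 <- max(1L, min(pts[, 2]) - 1L); c1 <- min(ncol(mask), max(pts[, 2]) + 1L)
    sub <- lab[r0:r1, c0:c1] == ids[i]
    skel <- skeletonize(sub)
    branched[i] <- skeleton_has_branch(skel, min_limb_px, max_pair_angle_deg)
  }
  structure(
    list(n_fibers = length(ids),
         n_branched = sum(branched),
         percent_branched = 100 * sum(branched) / length(ids),
         branched_ids = ids[branched]),
    class = "branch_report"
  )
}

#' @export
print.branch_report <- function(x, ...) {
  cat(sprintf("<branch_report> %d / %d fibers branched (%.1f%%)\n",
              x$n_branched, x$n_fibers, x$percent_branched))
  invisible(x)
}

#' All longitudinal metrics for one image
#'
#' Convenience wrapper: recovers the fiber mask, estimates the fiber axis
#' (from the spectral peak when available, else the structure tensor),
#' profiles an orthogonal reference line, and counts branches.
#'
#' @param image A single-channel [calibrated_image()].
#' @param band A [sarcomere_band()] used for the orientation estimate.
#' @param ratio_mode Passed to [interstitial_ratio()].
#' @param ... Passed to [count_branched_fibers()].
#' @return A tibble with one row: `interstitial_ratio`, `n_fibers`,
#'   `n_branched`, `percent_branched`.
#' @export
longitudinal_metrics <- function(image, band = sarcomere_band(),
                                 ratio_mode = "mean_widths", ...) {
  ori <- tryCatch(
    estimate_sarcomere_length(image, band)$peak_orientation_deg,
    dmq_error = function(e) NULL
  )
  mask <- fiber_mask(image, orientation_deg = ori)
  if (is.null(ori)) ori <- structure_tensor_axis(mask * 1, across = TRUE)
  prof <- profile_along_line(mask, image$pixel_size_um, orientation_deg = ori)
  br <- count_branched_fibers(mask, image$pixel_size_um, ...)
  tibble::tibble(
    interstitial_ratio = interstitial_ratio(prof, mode = ratio_mode),
    n_fibers = br$n_fibers,
    n_branched = br$n_branched,
    percent_branched = br$percent_branched
  )
}
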