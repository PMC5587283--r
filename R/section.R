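#' Segment fiber profiles from a laminin boundary channel
#'
#' Fiber interiors are the connected dark regions enclosed by the bright
#' laminin boundary. Components touching the image border (the extracellular
#' background and any fiber cut by the frame) are discarded or flagged.
#' Boundary-band pixels contested by two fibers are then split between them
#' with a near-Euclidean region growing ([EBImage::propagate()]), so a
#' fiber's area extends to the midline of its shared walls; boundary pixels
#' with no competing neighbor (the outer tissue perimeter) are credited to
#' no fiber. Areas are pixel counts times the pixel area.
#'
#' @param boundary A single-channel [calibrated_image()] with bright fiber
#'   borders, or a 3-channel image with a `laminin` channel role.
#' @param exclude_border Flag fibers touching the image border and exclude
#'   them from area statistics (standard morphometry practice).
#' @param min_area_px Interior components smaller than this are treated as
#'   boundary specks.
#' @return A list of class `fiber_segmentation`: `labels` (integer matrix,
#'   0 = unassigned), `fibers` (tibble: `fiber_id`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `border`), `pixel_size_um`.
#' @export
segment_fibers <- function(boundary, exclude_border = TRUE, min_area_px = 9L) {
  if (inherits(boundary, "calibrated_image") && !is.matrix(boundary$data)) {
    boundary <- get_channel(boundary, "laminin")
  }
  stopifnot(inherits(boundary, "calibrated_image"))
  px <- boundary$pixel_size_um
  m <- pmin(pmax(boundary$data, 0), 1)
  rng <- range(m)
  if (diff(rng) < 1e-9) {
    stop_dmq("dmq_segmentation_failure",
             "boundary channel is constant; no closed interiors found")
  }
  bin <- m > EBImage::otsu(EBImage::Image(m), range = c(0, 1))
  interior <- !bin
  lab <- EBImage::bwlabel(EBImage::Image(interior * 1))@.Data
  nr <- nrow(m); nc <- ncol(m)

  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border_labels <- setdiff(border_labels, 0L)
  sizes <- tabulate(lab[lab > 0L])
  tiny <- which(sizes < min_area_px)
  lab[lab %in% tiny] <- 0L
  lab[lab %in% border_labels] <- 0L   # background + border-cut interiors

  keep_ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(keep_ids) && !length(setdiff(border_labels, tiny))) {
    stop_dmq("dmq_segmentation_failure", "no closed interiors found")
  }
  if (!exclude_border) {
    # re-admit border-touching interiors (still dropping the one true
    # background component: the largest border-touching region)
    bg <- border_labels[which.max(sizes[border_labels])]
    lab2 <- EBImage::bwlabel(EBImage::Image(interior * 1))@.Data
    lab2[lab2 %in% tiny] <- 0L
    lab2[lab2 == bg] <- 0L
    lab <- lab2
    keep_ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  }
  if (!length(keep_ids)) {
    stop_dmq("dmq_segmentation_failure", "no closed interiors found")
  }
  relab <- matrix(0L, nr, nc)
  for (i in seq_along(keep_ids)) relab[lab == keep_ids[i]] <- i
  lab <- relab

  mask <- lab > 0L | bin
  prop <- EBImage::propagate(EBImage::Image(m), EBImage::Image(lab),
                             mask = mask, lambda = 1e8)
  prop <- matrix(as.integer(prop@.Data), nr, nc)

  # keep a propagated boundary pixel only where contested by another fiber
  # (radius-2 neighborhood so 3-px-wide wall stretches split cleanly)
  contested <- matrix(FALSE, nr, nc)
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- prop[rs - dr, cs - dc]
    contested <- contested | (sh != 0L & sh != prop)
  }
  final <- lab
  band_keep <- bin & prop > 0L & contested
  final[band_keep] <- prop[band_keep]

  ids <- seq_len(max(final))
  counts <- tabulate(final[final > 0L], nbins = max(final))
  rows <- vapply(ids, function(i) mean(which(final == i, arr.ind = TRUE)[, 1]), numeric(1))
  cols <- vapply(ids, function(i) mean(which(final == i, arr.ind = TRUE)[, 2]), numeric(1))
  on_border <- vapply(ids, function(i) {
    any(final[1, ] == i) || any(final[nr, ] == i) ||
      any(final[, 1] == i) || any(final[, nc] == i)
  }, logical(1))

  structure(
    list(labels = final,
         fibers = tibble::tibble(
           fiber_id = ids,
           area_um2 = counts * px^2,
           centroid_row = rows,
           centroid_col = cols,
           border = on_border
         ),
         pixel_size_um = px),
    class = "fiber_segmentation"
  )
}

#' @export
print.fiber_segmentation <- function(x, ...) {
  cat(sprintf("<fiber_segmentation> %d fibers, mean CSA %.1f um^2 (%d border-touching)\n",
              nrow(x$fibers), mean(x$fibers$area_um2[!x$fibers$border]),
              sum(x$fibers$border)))
  invisible(x)
}

#' Classify fibers as centrally nucleated (regenerating)
#'
#' A fiber is centrally nucleated when it contains a nucleus whose centroid
#' sits at a normalized boundary distance of at least `threshold`: distance
#' to the fiber boundary divided by the fiber's maximum interior distance.
#' Nuclei whose centroid falls in no fiber are reported unassigned.
#'
#' @param seg A [segment_fibers()] result.
#' @param nuclei A single-channel [calibrated_image()] (or 3-channel with a
#'   `nuclei` role) of the nuclear stain.
#' @param threshold Normalized boundary distance for a central call.
#' @return `seg` with `fibers` gaining columns `n_nuclei` and
#'   `central_nucleus`, plus attribute `unassigned_nuclei` (count).
#' @export
classify_central_nuclei <- function(seg, nuclei, threshold = 0.4) {
  stopifnot(inherits(seg, "fiber_segmentation"))
  if (inherits(nuclei, "calibrated_image") && !is.matrix(nuclei$data)) {
    nuclei <- get_channel(nuclei, "nuclei")
  }
  m <- pmin(pmax(nuclei$data, 0), 1)
  lab <- seg$labels
  nr <- nrow(lab); nc <- ncol(lab)
  if (any(dim(m) != dim(lab))) {
    stop_dmq("dmq_registration_error", "nuclei channel shape does not match segmentation")
  }

  nfib <- nrow(seg$fibers)
  central <- rep(FALSE, nfib)
  n_nuc <- integer(nfib)
  unassigned <- 0L

  if (diff(range(m)) > 1e-9) {
    nb <- m > EBImage::otsu(EBImage::Image(m), range = c(0, 1))
    nl <- EBImage::bwlabel(EBImage::Image(nb * 1))@.Data
    if (max(nl) > 0L) {
      # interior distance: to a pixel of another label or background
      edge <- matrix(FALSE, nr, nc)
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        sh <- matrix(-1L, nr, nc)
        rs <- max(1, 1 + o[1]):min(nr, nr + o[1])
        cs <- max(1, 1 + o[2]):min(nc, nc + o[2])
        sh[rs, cs] <- lab[rs - o[1], cs - o[2]]
        edge <- edge | (sh != lab & sh != -1L)
      }
      D <- EBImage::distmap(EBImage::Image((lab > 0L & !edge) * 1))@.Data
      maxD <- vapply(seq_len(nfib), function(i) {
        v <- D[lab == i]
        if (length(v)) max(v) else 0
      }, numeric(1))
      for (k in seq_len(max(nl))) {
        pts <- which(nl == k, arr.ind = TRUE)
        ci <- round(mean(pts[, 1])); cj <- round(mean(pts[, 2]))
        fib <- lab[ci, cj]
        if (fib == 0L) {
          unassigned <- unassigned + 1L
          next
        }
        n_nuc[fib] <- n_nuc[fib] + 1L
        if (maxD[fib] > 0 && D[ci, cj] / maxD[fib] >= threshold) {
          central[fib] <- TRUE
        }
      }
      if (unassigned > 0L) {
        message(sprintf("%d nucleus centroid(s) fell in no fiber; unassigned", unassigned))
      }
    }
  }
  seg$fibers$n_nuclei <- n_nuc
  seg$fibers$central_nucleus <- central
  attr(seg, "unassigned_nuclei") <- unassigned
  seg
}

#' Count macrophages by nucleus/CD68 colocalization
#'
#' A macrophage is a CD68-positive connected component overlapping a nucleus
#' component by at least `min_overlap_frac` of the smaller of the two
#' (`min_overlap_frac = 0` reduces to the any-pixel-overlap alternative).
#' Density is the count divided by the full field-of-view area.
#'
#' @param nuclei,cd68 Single-channel [calibrated_image()]s (registered).
#' @param min_overlap_frac Minimum overlap as a fraction of the smaller
#'   component.
#' @return A list: `macrophage_count`, `macrophage_density_per_mm2`,
#'   `field_area_mm2`.
#' @export
count_macrophages <- function(nuclei, cd68, min_overlap_frac = 0.3) {
  if (inherits(nuclei, "calibrated_image") && !is.matrix(nuclei$data)) {
    nuclei <- get_channel(nuclei, "nuclei")
  }
  if (inherits(cd68, "calibrated_image") && !is.matrix(cd68$data)) {
    cd68 <- get_channel(cd68, "cd68")
  }
  stopifnot(inherits(nuclei, "calibrated_image"), inherits(cd68, "calibrated_image"))
  if (any(dim(nuclei$data) != dim(cd68$data)) ||
      abs(nuclei$pixel_size_um - cd68$pixel_size_um) > 1e-9) {
    stop_dmq("dmq_registration_error",
             "nuclei and CD68 channels differ in shape or calibration")
  }
  px <- nuclei$pixel_size_um
  field_area_mm2 <- prod(dim(nuclei$data)) * px^2 / 1e6

  binarize_or_empty <- function(m) {
    m <- pmin(pmax(m, 0), 1)
    if (diff(range(m)) < 1e-9) return(matrix(FALSE, nrow(m), ncol(m)))
    m > EBImage::otsu(EBImage::Image(m), range = c(0, 1))
  }
  nb <- binarize_or_empty(nuclei$data)
  cb <- binarize_or_empty(cd68$data)
  if (!any(cb) || !any(nb)) {
    return(list(macrophage_count = 0L,
                macrophage_density_per_mm2 = 0,
                field_area_mm2 = field_area_mm2))
  }
  nl <- EBImage::bwlabel(EBImage::Image(nb * 1))@.Data
  cl <- EBImage::bwlabel(EBImage::Image(cb * 1))@.Data
  n_sizes <- tabulate(nl[nl > 0L])
  c_sizes <- tabulate(cl[cl > 0L])

  both <- nl > 0L & cl > 0L
  count <- 0L
  if (any(both)) {
    ov <- table(cd = cl[both], nuc = nl[both])
    for (j in seq_len(nrow(ov))) {
      cid <- as.integer(rownames(ov)[j])
      best <- which.max(ov[j, ])
      nid <- as.integer(colnames(ov)[best])
      overlap <- ov[j, best]
      if (overlap >= min_overlap_frac * min(c_sizes[cid], n_sizes[nid]) &&
          overlap > 0) {
        count <- count + 1L
      }
    }
  }
  list(macrophage_count = count,
       macrophage_density_per_mm2 = count / field_area_mm2,
       field_area_mm2 = field_area_mm2)
}

#' All cross-section metrics for one 3-channel image
#'
#' Runs segmentation on the laminin channel, central-nucleus classification
#' on the nuclei channel, and macrophage colocalization on nuclei + CD68.
#' Border-touching fibers are excluded from CSA statistics but counted in
#' the regeneration percentage denominator.
#'
#' @param image A 3-channel [calibrated_image()] with roles
#'   `laminin`, `nuclei`, `cd68`.
#' @param central_threshold Passed to [classify_central_nuclei()].
#' @param min_overlap_frac Passed to [count_macrophages()].
#' @return A list of class `section_report`: `fibers` (per-fiber tibble),
#'   `mean_csa_um2`, `percent_regenerating`, `macrophage_count`,
#'   `macrophage_density_per_mm2`, `field_area_mm2`.
#' @export
section_report <- function(image, central_threshold = 0.4,
                           min_overlap_frac = 0.3) {
  stopifnot(inherits(image, "calibrated_image"))
  seg <- segment_fibers(get_channel(image, "laminin"))
  seg <- classify_central_nuclei(seg, get_channel(image, "nuclei"),
                                 threshold = central_threshold)
  mac <- count_macrophages(get_channel(image, "nuclei"),
                           get_channel(image, "cd68"),
                           min_overlap_frac = min_overlap_frac)
  fib <- seg$fibers
  structure(
    list(fibers = fib,
         mean_csa_um2 = mean(fib$area_um2[!fib$border]),
         percent_regenerating = 100 * mean(fib$central_nucleus),
         macrophage_count = mac$macrophage_count,
         macrophage_density_per_mm2 = mac$macrophage_density_per_mm2,
         field_area_mm2 = mac$field_area_mm2),
    class = "section_report"
  )
}

#' @export
print.section_report <- function(x, ...) {
  cat(sprintf(
    "<section_report> %d fibers, mean CSA %.1f um^2, %.1f%% regenerating, %d macrophages (%.1f / mm^2)\n",
    nrow(x$fibers), x$mean_csa_um2, x$percent_regenerating,
    x$macrophage_count, x$macrophage_density_per_mm2))
  invisible(x)
}
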