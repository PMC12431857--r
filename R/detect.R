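## Detection of condensates in cell images. Cells are segmented by Otsu
## thresholding; condensates by local background subtraction (grayscale
## opening) followed by a robust-sigma threshold and morphological
## filtering on area and circularity.

#' Segment cells by Otsu thresholding
#'
#' Foreground pixels are those above the Otsu threshold of the intensity
#' histogram; holes are filled, components smaller than
#' `min_cell_area_um2` are removed and the remaining components are
#' relabelled contiguously from 1.
#'
#' @param image An [image_frame()].
#' @param min_cell_area_um2 Minimum cell area in square micrometres.
#' @return A `cell_mask`: an integer label matrix (0 = background) with
#'   attribute `pixel_size_um`.
#' @export
segment_cells <- function(image, min_cell_area_um2 = 20) {
  stopifnot_frame(image)
  m <- image$intensity
  rng <- range(m)
  if (diff(rng) <= 0)
    stop("degenerate histogram: image is constant")
  scaled <- (m - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  fg <- EBImage::fillHull(EBImage::Image(scaled > thr))
  lab <- EBImage::bwlabel(fg)
  labm <- EBImage::imageData(lab)
  px_area <- image$pixel_size_um^2
  keep <- which(tabulate(labm[labm > 0]) * px_area >= min_cell_area_um2)
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_along(keep)) out[labm == keep[i]] <- i
  structure(out, class = "cell_mask", pixel_size_um = image$pixel_size_um)
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px, %d cell(s)\n",
              nrow(x), ncol(x), max(x)))
  invisible(x)
}

## Crofton 4-direction perimeter estimate of a binary mask. Counts value
## transitions along rows, columns and both diagonals; the discretized
## Cauchy-Crofton formula P = (pi/8) * (C0 + C90 + (C45 + C135)/sqrt(2))
## corrects the overestimation of raw pixel-boundary perimeters for small
## near-circular objects.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  c0 <- sum(abs(m[, -1] - m[, -ncol(m)]))                     # along rows
  c90 <- sum(abs(m[-1, ] - m[-nrow(m), ]))                    # along cols
  c45 <- sum(abs(m[-1, -1] - m[-nrow(m), -ncol(m)]))
  c135 <- sum(abs(m[-1, -ncol(m)] - m[-nrow(m), -1]))
  (pi / 8) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

shape_features <- function(labm, img, px) {
  ids <- seq_len(max(labm))
  if (length(ids) == 0)
    return(data.frame(label = integer(0), centroid_row_px = numeric(0),
                      centroid_col_px = numeric(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      mean_intensity = numeric(0)))
  idx <- which(labm > 0)
  lab <- labm[idx]
  rows <- (idx - 1) %% nrow(labm) + 1
  cols <- (idx - 1) %/% nrow(labm) + 1
  area_px <- tabulate(lab, nbins = max(labm))
  cr <- vapply(split(rows, lab), mean, numeric(1))
  cc <- vapply(split(cols, lab), mean, numeric(1))
  mi <- vapply(split(img[idx], lab), mean, numeric(1))
  per <- vapply(ids, function(i) {
    sel <- lab == i
    r <- range(rows[sel]); c <- range(cols[sel])
    sub <- matrix(0L, diff(r) + 1L, diff(c) + 1L)
    sub[cbind(rows[sel] - r[1] + 1L, cols[sel] - c[1] + 1L)] <- 1L
    crofton_perimeter(sub)
  }, numeric(1))
  circ <- pmin(1, 4 * pi * area_px / per^2)
  data.frame(label = ids,
             centroid_row_px = cr - 1,   # 0-based
             centroid_col_px = cc - 1,
             area_um2 = area_px * px^2,
             perimeter_um = per * px,
             circularity = circ,
             mean_intensity = mi)
}

#' Default condensate-detection parameters
#'
#' Morphological defaults for [detect_condensates()]: local background by
#' grayscale opening with a 1-um structuring radius, a 3-sigma robust
#' threshold on the residual, and size/shape gates of 0.05-20 um2 and
#' circularity >= 0.4. Permissive enough for sub-micrometre foci, strict
#' enough to reject elongated tubule fragments.
#'
#' @param local_bg_radius_um Structuring-element radius for background
#'   estimation (um).
#' @param k_sigma Threshold in robust standard deviations of the
#'   background-subtracted residual.
#' @param min_area_um2,max_area_um2 Area gate (um2).
#' @param min_circularity Circularity gate (4*pi*A/P^2, clipped to 1).
#' @return A named list of parameters.
#' @export
condensate_params <- function(local_bg_radius_um = 1, k_sigma = 3,
                              min_area_um2 = 0.05, max_area_um2 = 20,
                              min_circularity = 0.4) {
  p <- list(local_bg_radius_um = local_bg_radius_um, k_sigma = k_sigma,
            min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
            min_circularity = min_circularity)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1))))
    stop("all detection parameters must be single finite numbers")
  if (p$local_bg_radius_um <= 0 || p$k_sigma < 0 || p$min_area_um2 < 0 ||
      p$max_area_um2 < p$min_area_um2)
    stop("invalid detection parameters")
  p
}

#' Detect condensates within segmented cells
#'
#' Within each cell, the local background is estimated by grayscale
#' morphological opening with a disc of radius `local_bg_radius_um`;
#' candidate pixels are those whose background-subtracted residual
#' exceeds `k_sigma` times the robust sigma (MAD) of the in-cell
#' residual. Connected candidate components are filtered by area and
#' circularity and measured in physical units. Thresholding is per cell.
#'
#' @param image An [image_frame()].
#' @param mask A `cell_mask` from [segment_cells()], congruent with
#'   `image`.
#' @param params Parameter list from [condensate_params()].
#' @return A `condensate_set`: list with `objects` (one row per
#'   condensate: `id`, `parent_cell_label`, 0-based centroid,
#'   `area_um2`, `perimeter_um`, `circularity`, `mean_intensity`),
#'   `label_mask` (integer matrix of condensate ids), `background`
#'   (estimated background image), and `pixel_size_um`. An empty mask
#'   yields an empty set.
#' @export
detect_condensates <- function(image, mask, params = condensate_params()) {
  stopifnot_frame(image)
  if (!inherits(mask, "cell_mask") || !all(dim(mask) == dim(image)))
    stop("`mask` must be a cell_mask congruent with `image`")
  params <- do.call(condensate_params, params)
  px <- image$pixel_size_um
  img <- image$intensity
  r_px <- max(1, round(params$local_bg_radius_um / px))
  brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  scale <- max(img, 1e-12)
  ## fill out-of-cell pixels with the in-cell median before the opening:
  ## otherwise the structuring element cannot fit into high-curvature
  ## cell tips and the clipped background masquerades as objects there
  fill <- if (any(mask > 0)) median(img[mask > 0]) else 0
  padded <- img
  padded[mask == 0] <- pmax(fill, padded[mask == 0])
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(padded / scale),
                                            brush)) * scale
  resid <- img - bg
  cand <- matrix(FALSE, nrow(img), ncol(img))
  ## noiseless floor: 2% of the image-wide in-mask residual maximum keeps
  ## object supports from bleeding along faint smooth skirts (and empty
  ## cells from yielding numeric-noise components) when sigma is exactly 0
  floor_thr <- 0.02 * max(resid[mask > 0], 0)
  for (cl in seq_len(max(mask))) {
    in_cell <- mask == cl
    if (!any(in_cell)) next
    ## the opening residual is non-negative with a textured-background
    ## pedestal, so threshold k_sigma robust deviations above its median
    med <- median(resid[in_cell])
    sigma <- mad(resid[in_cell])
    thr <- med + max(params$k_sigma * sigma, floor_thr)
    cand[in_cell & resid > thr] <- TRUE
  }
  labm <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand)))
  feats <- shape_features(labm, img, px)
  keep <- feats$area_um2 >= params$min_area_um2 &
    feats$area_um2 <= params$max_area_um2 &
    feats$circularity >= params$min_circularity
  feats <- feats[keep, , drop = FALSE]
  out_lab <- matrix(0L, nrow(img), ncol(img))
  objects <- NULL
  new_id <- 0L
  for (old in feats$label) {
    new_id <- new_id + 1L
    out_lab[labm == old] <- new_id
  }
  if (nrow(feats) > 0) {
    cent_idx <- cbind(round(feats$centroid_row_px) + 1,
                      round(feats$centroid_col_px) + 1)
    parent <- mask[cent_idx]
    objects <- data.frame(id = seq_len(nrow(feats)),
                          parent_cell_label = as.integer(parent),
                          feats[, c("centroid_row_px", "centroid_col_px",
                                    "area_um2", "perimeter_um",
                                    "circularity", "mean_intensity")],
                          row.names = NULL)
  } else {
    objects <- data.frame(id = integer(0), parent_cell_label = integer(0),
                          centroid_row_px = numeric(0),
                          centroid_col_px = numeric(0),
                          area_um2 = numeric(0), perimeter_um = numeric(0),
                          circularity = numeric(0),
                          mean_intensity = numeric(0))
  }
  structure(list(objects = objects, label_mask = out_lab, background = bg,
                 pixel_size_um = px, params = params),
            class = "condensate_set")
}

#' @export
print.condensate_set <- function(x, ...) {
  cat(sprintf("<condensate_set> %d object(s)\n", nrow(x$objects)))
  invisible(x)
}

#' Per-cell condensate counts and mean areas
#'
#' Cells with zero detections appear with count 0, so downstream group
#' statistics see every cell.
#'
#' @param set A `condensate_set` from [detect_condensates()].
#' @param mask The `cell_mask` used for detection.
#' @return Data frame with columns `cell_label`, `n_condensates`,
#'   `mean_area_um2` (NA where the count is 0).
#' @export
count_per_cell <- function(set, mask) {
  stopifnot(inherits(set, "condensate_set"), inherits(mask, "cell_mask"))
  labs <- seq_len(max(mask))
  obj <- set$objects
  n <- vapply(labs, function(l) sum(obj$parent_cell_label == l), integer(1))
  ma <- vapply(labs, function(l) {
    a <- obj$area_um2[obj$parent_cell_label == l]
    if (length(a)) mean(a) else NA_real_
  }, numeric(1))
  data.frame(cell_label = labs, n_condensates = n, mean_area_um2 = ma)
}
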