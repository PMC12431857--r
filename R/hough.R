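## Gradient-vote circular Hough transform for droplet fields. Each edge
## pixel casts one vote per candidate radius at the position `r` pixels
## along its intensity gradient (which points toward the centre of a
## bright droplet). Vote counts are absolute, so the detection threshold
## is reproducible across images of different sizes.

sobel_gradients <- function(img) {
  ## EBImage::filter2 correlates with the spatially flipped kernel, so the
  ## raw responses carry the opposite sign of the intensity derivative.
  k <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- -EBImage::imageData(EBImage::filter2(EBImage::Image(img), k))
  gy <- -EBImage::imageData(EBImage::filter2(EBImage::Image(img), t(k)))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Detect circular droplets by Hough transform
#'
#' Gradient-based circular Hough transform: Sobel edge pixels vote for
#' circle centres along their gradient direction at every candidate
#' radius; per-radius accumulators are pooled over 3x3 neighbourhoods,
#' thresholded in absolute votes, and reduced by non-maximum suppression
#' on the centre distance.
#'
#' @param image An [image_frame()].
#' @param radius_px_range Length-2 radius range in pixels (searched on an
#'   integer grid).
#' @param accumulator_threshold Minimum absolute vote count (3x3-pooled)
#'   for a centre candidate. Default: the circumference (in pixels) of
#'   the smallest searched radius, `ceiling(2 * pi * r_min)` — a true
#'   circle contributes several times that many pooled votes.
#' @param min_center_distance_px Minimum distance between accepted
#'   centres; defaults to the mean of the searched radius range.
#' @param smoothing_sigma_px Gaussian presmoothing of the image (px);
#'   0 disables.
#' @param edge_threshold_frac Edge pixels are those whose gradient
#'   magnitude exceeds this fraction of the maximum magnitude.
#' @return A `droplet_set` data frame with 0-based `center_row_px`,
#'   `center_col_px`, `radius_px` and `score` (votes), ordered by score.
#' @export
detect_droplets <- function(image, radius_px_range = c(4, 10),
                            accumulator_threshold = NULL,
                            min_center_distance_px = NULL,
                            smoothing_sigma_px = 1,
                            edge_threshold_frac = 0.2) {
  stopifnot_frame(image)
  if (length(radius_px_range) != 2 || diff(radius_px_range) < 0 ||
      radius_px_range[1] <= 0)
    stop("`radius_px_range` must be an increasing positive pair")
  if (radius_px_range[2] >= min(dim(image)) / 2)
    stop("radius range exceeds the image")
  radii <- seq(floor(radius_px_range[1]), ceiling(radius_px_range[2]))
  if (is.null(accumulator_threshold))
    accumulator_threshold <- ceiling(2 * pi * radii[1])
  if (is.null(min_center_distance_px))
    min_center_distance_px <- mean(radius_px_range)
  img <- image$intensity
  if (diff(range(img)) == 0)
    return(empty_droplet_set(image$pixel_size_um))
  if (smoothing_sigma_px > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = smoothing_sigma_px))
  g <- sobel_gradients(img)
  nr <- nrow(img); nc <- ncol(img)
  thr <- edge_threshold_frac * max(g$mag)
  edge <- which(g$mag > thr)
  if (length(edge) == 0) return(empty_droplet_set(image$pixel_size_um))
  er <- (edge - 1) %% nr + 1
  ec <- (edge - 1) %/% nr + 1
  ur <- g$gy[edge] / g$mag[edge]
  uc <- g$gx[edge] / g$mag[edge]
  box <- matrix(1, 3, 3)
  peaks <- NULL
  pooled_by_r <- vector("list", length(radii))
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    vr <- round(er + r * ur)
    vc <- round(ec + r * uc)
    ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    if (!any(ok)) {
      pooled_by_r[[ri]] <- matrix(0, nr, nc)
      next
    }
    acc <- matrix(0, nr, nc)
    tab <- tabulate((vc[ok] - 1L) * nr + vr[ok], nbins = nr * nc)
    acc[] <- tab
    pooled <- EBImage::imageData(EBImage::filter2(EBImage::Image(acc), box))
    pooled_by_r[[ri]] <- pooled
    hits <- which(pooled >= accumulator_threshold)
    if (length(hits) == 0) next
    peaks <- rbind(peaks, data.frame(
      row = (hits - 1) %% nr + 1, col = (hits - 1) %/% nr + 1,
      radius = r, score = pooled[hits]))
  }
  if (is.null(peaks)) return(empty_droplet_set(image$pixel_size_um))
  peaks <- peaks[order(-peaks$score), ]
  acc_rows <- numeric(0); acc_cols <- numeric(0)
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (length(acc_rows) == 0 ||
        all(sqrt((acc_rows - peaks$row[i])^2 +
                 (acc_cols - peaks$col[i])^2) >= min_center_distance_px)) {
      keep[i] <- TRUE
      acc_rows <- c(acc_rows, peaks$row[i])
      acc_cols <- c(acc_cols, peaks$col[i])
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  ## sub-bin radius refinement: vote-weighted mean over the radius bins
  ## that score at least half the best bin at this centre
  radius_ref <- vapply(seq_len(nrow(peaks)), function(i) {
    v <- vapply(pooled_by_r, function(p) p[peaks$row[i], peaks$col[i]],
                numeric(1))
    use <- v >= max(v) / 2
    sum(radii[use] * v[use]) / sum(v[use])
  }, numeric(1))
  structure(data.frame(center_row_px = peaks$row - 1,
                       center_col_px = peaks$col - 1,
                       radius_px = radius_ref,
                       score = peaks$score, row.names = NULL),
            class = c("droplet_set", "data.frame"),
            pixel_size_um = image$pixel_size_um)
}

empty_droplet_set <- function(px) {
  structure(data.frame(center_row_px = numeric(0),
                       center_col_px = numeric(0),
                       radius_px = numeric(0), score = numeric(0)),
            class = c("droplet_set", "data.frame"), pixel_size_um = px)
}

#' Count droplets in a list of fields
#'
#' Applies [detect_droplets()] with shared parameters to every field and
#' returns one count per image.
#'
#' @param images List of [image_frame()]s.
#' @param ... Parameters passed on to [detect_droplets()].
#' @return Data frame with columns `field_id` and `n_droplets`.
#' @export
droplets_per_field <- function(images, ...) {
  counts <- vapply(images, function(im) nrow(detect_droplets(im, ...)),
                   integer(1))
  data.frame(field_id = seq_along(images), n_droplets = counts)
}
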