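## Enrichment, co-localization and line profiles.

#' Condensed vs dispersed intensity fractions
#'
#' For each cell, the condensed fraction is the integrated (background-
#' subtracted, if the image was prepared that way) intensity inside
#' detected condensate pixels divided by the integrated intensity over
#' all in-cell pixels; the dispersed fraction is its complement, so the
#' two always sum to 1. Cells with zero total intensity are excluded
#' with a warning.
#'
#' @param image An [image_frame()] of the channel to quantify.
#' @param mask A `cell_mask` congruent with `image`.
#' @param condensates A `condensate_set` from [detect_condensates()]
#'   (its `label_mask` defines the condensate pixels).
#' @return An `enrichment_result`: list with `pooled` (named vector
#'   `condensed_fraction`, `dispersed_fraction`) and `per_cell` data
#'   frame (`cell_label`, `condensed_fraction`, `dispersed_fraction`,
#'   `total_intensity`).
#' @export
enrichment <- function(image, mask, condensates) {
  stopifnot_frame(image)
  stopifnot(inherits(mask, "cell_mask"),
            inherits(condensates, "condensate_set"),
            all(dim(mask) == dim(image)))
  img <- image$intensity
  in_cond <- condensates$label_mask > 0
  labs <- seq_len(max(mask))
  rows <- lapply(labs, function(l) {
    cell_px <- mask == l
    tot <- sum(img[cell_px])
    if (tot <= 0) {
      warning(sprintf("cell %d has zero total intensity; excluded", l))
      return(NULL)
    }
    cond <- sum(img[cell_px & in_cond])
    data.frame(cell_label = l, condensed_fraction = cond / tot,
               dispersed_fraction = 1 - cond / tot, total_intensity = tot)
  })
  per_cell <- do.call(rbind, rows)
  if (is.null(per_cell))
    per_cell <- data.frame(cell_label = integer(0),
                           condensed_fraction = numeric(0),
                           dispersed_fraction = numeric(0),
                           total_intensity = numeric(0))
  all_cell <- mask > 0
  tot <- sum(img[all_cell])
  pooled <- c(condensed_fraction = if (tot > 0)
    sum(img[all_cell & in_cond]) / tot else NA_real_)
  pooled["dispersed_fraction"] <- 1 - pooled["condensed_fraction"]
  structure(list(pooled = pooled, per_cell = per_cell),
            class = "enrichment_result")
}

#' Pearson co-localization over in-mask pixels
#'
#' The standard Pearson correlation coefficient (PCC) between the pixel
#' intensities of two channels, computed over the pixels of each cell
#' and pooled over all in-mask pixels. A channel that is constant within
#' a cell has an undefined correlation; that cell is reported as `NA`
#' with a warning.
#'
#' @param ch1,ch2 Congruent [image_frame()]s.
#' @param mask A `cell_mask`; only in-mask pixels enter the correlation.
#' @return A `coloc_result`: list with `pcc` (pooled), `n_pixels` and
#'   `per_cell` data frame (`cell_label`, `pcc`, `n_pixels`).
#' @export
pearson_coloc <- function(ch1, ch2, mask) {
  stopifnot_frame(ch1); stopifnot_frame(ch2)
  stopifnot(all(dim(ch1) == dim(ch2)), inherits(mask, "cell_mask"),
            all(dim(mask) == dim(ch1)))
  if (!any(mask > 0)) stop("mask is empty")
  pcc_of <- function(a, b, where) {
    x <- a[where]; y <- b[where]
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant channel within mask: PCC undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  labs <- seq_len(max(mask))
  per_cell <- do.call(rbind, lapply(labs, function(l) {
    sel <- mask == l
    data.frame(cell_label = l,
               pcc = pcc_of(ch1$intensity, ch2$intensity, sel),
               n_pixels = sum(sel))
  }))
  structure(list(pcc = pcc_of(ch1$intensity, ch2$intensity, mask > 0),
                 n_pixels = sum(mask > 0), per_cell = per_cell),
            class = "coloc_result")
}

#' Intensity profile along a line segment
#'
#' Samples each channel by bilinear interpolation along the segment from
#' `p0` to `p1`, averaging over `width_px` parallel lines offset
#' perpendicular to the segment. Distances are reported in micrometres.
#'
#' @param images A single [image_frame()] or a list of them (channels).
#' @param p0,p1 Endpoints as 0-based `(row, col)` pixel pairs.
#' @param width_px Integer width (number of parallel sampling lines).
#' @param n Number of samples along the segment (default: one per pixel
#'   of segment length).
#' @return Data frame with `distance_um` and one intensity column per
#'   channel.
#' @export
line_profile <- function(images, p0, p1, width_px = 1L, n = NULL) {
  if (is_image_frame(images)) images <- list(images)
  stopifnot(length(p0) == 2, length(p1) == 2, width_px >= 1)
  len_px <- sqrt(sum((p1 - p0)^2))
  if (len_px == 0) stop("zero-length line")
  px <- images[[1]]$pixel_size_um
  d <- dim(images[[1]])
  for (pt in list(p0, p1))
    if (any(pt < 0) || pt[1] > d[1] - 1 || pt[2] > d[2] - 1)
      stop("endpoints must lie inside the image")
  if (is.null(n)) n <- max(2L, ceiling(len_px) + 1L)
  tt <- seq(0, 1, length.out = n)
  dir <- (p1 - p0) / len_px
  perp <- c(-dir[2], dir[1])
  offs <- seq_len(width_px) - (width_px + 1) / 2
  bilinear <- function(m, r, c) {
    ## r, c are 0-based fractional pixel coordinates
    r0 <- pmin(pmax(floor(r), 0), nrow(m) - 2)
    c0 <- pmin(pmax(floor(c), 0), ncol(m) - 2)
    fr <- r - r0; fc <- c - c0
    i00 <- m[cbind(r0 + 1, c0 + 1)]; i01 <- m[cbind(r0 + 1, c0 + 2)]
    i10 <- m[cbind(r0 + 2, c0 + 1)]; i11 <- m[cbind(r0 + 2, c0 + 2)]
    i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
      i10 * fr * (1 - fc) + i11 * fr * fc
  }
  out <- data.frame(distance_um = tt * len_px * px)
  for (k in seq_along(images)) {
    m <- images[[k]]$intensity
    prof <- rowMeans(vapply(offs, function(o) {
      r <- p0[1] + tt * (p1[1] - p0[1]) + o * perp[1]
      c <- p0[2] + tt * (p1[2] - p0[2]) + o * perp[2]
      bilinear(m, r, c)
    }, numeric(n)))
    lab <- images[[k]]$channel
    out[[if (is.na(lab)) sprintf("intensity_ch%d", k) else lab]] <- prof
  }
  out
}
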