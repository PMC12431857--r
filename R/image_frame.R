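#' Calibrated fluorescence image frame
#'
#' An `image_frame` bundles a 2D intensity matrix with its physical pixel
#' size and an optional channel label. All detection and quantification
#' functions in the package consume this container so that physical units
#' (areas in square micrometres, distances in micrometres) can be computed
#' without carrying calibration separately.
#'
#' @param intensity Numeric matrix of non-negative, finite intensities,
#'   indexed `(row, col)`.
#' @param pixel_size_um Pixel size in micrometres per pixel (scalar > 0).
#' @param channel Optional channel label (e.g. `"GFP"`).
#' @return An object of class `image_frame`.
#' @examples
#' img <- image_frame(matrix(runif(100), 10, 10), pixel_size_um = 0.1)
#' dim(img)
#' @export
image_frame <- function(intensity, pixel_size_um, channel = NA_character_) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must be finite and non-missing")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(intensity = intensity,
         pixel_size_um = as.numeric(pixel_size_um),
         channel = as.character(channel)),
    class = "image_frame")
}

#' @export
dim.image_frame <- function(x) dim(x$intensity)

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<image_frame> %d x %d px, %.4g um/px, channel: %s\n",
              d[1], d[2], x$pixel_size_um,
              ifelse(is.na(x$channel), "<none>", x$channel)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

is_image_frame <- function(x) inherits(x, "image_frame")

stopifnot_frame <- function(x, arg = deparse(substitute(x))) {
  if (!is_image_frame(x))
    stop(sprintf("`%s` must be an image_frame (see image_frame())", arg))
  invisible(x)
}

#' Write an image (or stack) to TIFF with a JSON calibration sidecar
#'
#' Intensities are quantized to 16-bit integers; the quantization step is
#' recorded in the sidecar so that integer-valued data round-trip exactly.
#' A list of frames is written as a multi-page TIFF.
#'
#' @param x An `image_frame`, or a list of `image_frame`s (a stack).
#' @param path Output TIFF path. The sidecar is written to `paste0(path,
#'   ".json")`.
#' @param frame_interval_s Optional frame interval (seconds) stored in the
#'   sidecar for stacks.
#' @param bits Bits per sample: 16 (integer, default) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, frame_interval_s = NULL, bits = 16L) {
  frames <- if (is_image_frame(x)) list(x) else x
  if (!all(vapply(frames, is_image_frame, logical(1))))
    stop("`x` must be an image_frame or a list of image_frames")
  px <- unique(vapply(frames, function(f) f$pixel_size_um, numeric(1)))
  if (length(px) != 1L) stop("all frames must share one pixel size")
  mats <- lapply(frames, function(f) f$intensity)
  mx <- max(vapply(mats, max, numeric(1)), 1e-12)
  if (bits == 16L) {
    quant <- if (mx <= 65535 && all(vapply(mats, function(m)
      all(m == round(m)), logical(1)))) 1 else mx / 65535
    stored <- lapply(mats, function(m) round(m / quant) / 65535)
    tiff::writeTIFF(if (length(stored) == 1L) stored[[1]] else stored,
                    path, bits.per.sample = 16L)
  } else if (bits == 32L) {
    quant <- mx
    stored <- lapply(mats, function(m) m / quant)
    tiff::writeTIFF(if (length(stored) == 1L) stored[[1]] else stored,
                    path, bits.per.sample = 32L)
  } else stop("`bits` must be 16 or 32")
  side <- list(pixel_size_um = px,
               intensity_scale = quant,
               bits = as.integer(bits),
               n_frames = length(frames),
               channel = frames[[1]]$channel)
  if (!is.null(frame_interval_s)) side$frame_interval_s <- frame_interval_s
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF image (or stack) written with [write_image()]
#'
#' @param path TIFF path; the JSON sidecar `paste0(path, ".json")` must
#'   exist unless `pixel_size_um` is supplied.
#' @param pixel_size_um Pixel size override when no sidecar is present.
#' @return An `image_frame` for single-page files, otherwise a list of
#'   `image_frame`s with attribute `frame_interval_s` when recorded.
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  px <- if (!is.null(side$pixel_size_um)) side$pixel_size_um else pixel_size_um
  if (is.null(px))
    stop("pixel size unknown: supply `pixel_size_um` or provide the sidecar")
  quant <- if (!is.null(side$intensity_scale))
    as.numeric(side$intensity_scale) else 1
  bits <- if (!is.null(side$bits)) side$bits else 16L
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (bits == 16L))
  chan <- if (!is.null(side$channel)) side$channel else NA_character_
  frames <- lapply(pages, function(m) {
    v <- if (bits == 16L) m * quant else m * quant
    image_frame(v, pixel_size_um = px, channel = chan)
  })
  if (length(frames) == 1L) return(frames[[1]])
  if (!is.null(side$frame_interval_s))
    attr(frames, "frame_interval_s") <- side$frame_interval_s
  frames
}
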