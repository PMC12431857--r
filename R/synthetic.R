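## Synthetic-data generators. Every generator is deterministic under its
## spec seed and returns ground truth alongside the data, so downstream
## detection/fitting stages can be tested without any raw microscopy or
## spectroscopy data.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

## Smooth radially symmetric disk: peak * pnorm((R - r) / sigma). Its exact
## 2D integral is peak * pi * (R^2 + sigma^2) (Gaussian-smoothed top-hat),
## which is recorded per object as the analytic ground-truth integral.
render_disk <- function(img, row0, col0, radius, peak, edge_sigma) {
  halfw <- ceiling(radius + 5 * edge_sigma)
  rows <- max(1, floor(row0 - halfw)):min(nrow(img), ceiling(row0 + halfw))
  cols <- max(1, floor(col0 - halfw)):min(ncol(img), ceiling(col0 + halfw))
  rr <- outer(rows - row0, cols - col0, function(dr, dc) sqrt(dr^2 + dc^2))
  img[rows, cols] <- img[rows, cols] + peak * pnorm((radius - rr) / edge_sigma)
  img
}

disk_integral <- function(radius, peak, edge_sigma)
  peak * pi * (radius^2 + edge_sigma^2)

## Smooth random field for ER-like texture: white noise blurred to a
## correlation length of a few hundred nanometres, rescaled to unit s.d.
texture_field <- function(nr, nc, corr_px = 8) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  sm <- EBImage::gblur(EBImage::Image(w), sigma = corr_px)
  m <- EBImage::imageData(sm)
  (m - mean(m)) / max(sd(m), 1e-12)
}

place_nonoverlapping <- function(n, sampler, min_dist_fun, max_tries) {
  pts <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- sampler()
      if (nrow(pts) == 0 ||
          all(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >
              min_dist_fun(radii, cand[3]))) {
        pts <- rbind(pts, cand[1:2]); radii <- c(radii, cand[3])
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not place object %d without overlap after %d tries", i,
        max_tries))
  }
  cbind(pts, radii)
}

#' Generate a synthetic cell field with ground truth
#'
#' Renders `n_cells` elliptical cells with ER-like textured interiors and
#' bright near-circular condensates (Gaussian-smoothed disks), plus
#' additive Gaussian camera noise. Every rendered condensate is recorded
#' in the ground truth together with its exact analytic integral, so
#' noiseless renders satisfy: total intensity = background integral +
#' sum of object integrals.
#'
#' @param spec A [cell_field_spec()].
#' @return A list with elements `image` (an [image_frame()]) and `truth`,
#'   where `truth` contains `objects` (one row per condensate: `id`,
#'   `cell`, 0-based `center_row_px`/`center_col_px`, `radius_px`,
#'   `peak_intensity`, `integral`), `cell_mask` (label matrix, 0 =
#'   background), `per_cell_counts`, and the spec echo.
#' @examples
#' f <- sim_cell_field(cell_field_spec(image_size_px = c(128, 128),
#'                                     n_cells = 1, seed = 7))
#' nrow(f$truth$objects)
#' @export
sim_cell_field <- function(spec) {
  stopifnot(inherits(spec, "cell_field_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    px <- spec$pixel_size_um
    r_px <- spec$condensate_radius_um / px
    img <- matrix(0, nr, nc)
    cell_mask <- matrix(0L, nr, nc)

    ## one cell per jittered grid block, elliptical, axis-aligned blocks
    gb <- ceiling(sqrt(max(spec$n_cells, 1)))
    blocks <- expand.grid(gr = seq_len(gb), gc = seq_len(gb))
    blocks <- blocks[seq_len(spec$n_cells), , drop = FALSE]
    bh <- nr / gb; bw <- nc / gb
    cells <- data.frame(cell = integer(0), row0 = numeric(0),
                        col0 = numeric(0), a = numeric(0), b = numeric(0),
                        phi = numeric(0))
    for (i in seq_len(spec$n_cells)) {
      row0 <- (blocks$gr[i] - 0.5) * bh + runif(1, -0.05, 0.05) * bh
      col0 <- (blocks$gc[i] - 0.5) * bw + runif(1, -0.05, 0.05) * bw
      a <- runif(1, 0.30, 0.42) * bh
      b <- runif(1, 0.30, 0.42) * bw
      phi <- runif(1, 0, pi)
      if (max(r_px) >= min(a, b))
        stop("condensate radius larger than cell: reject spec")
      cells <- rbind(cells, data.frame(cell = i, row0 = row0, col0 = col0,
                                       a = a, b = b, phi = phi))
    }
    ## rasterize cells
    rows <- matrix(seq_len(nr), nr, nc)
    colsm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(spec$n_cells)) {
      ce <- cells[i, ]
      dr <- rows - ce$row0; dc <- colsm - ce$col0
      u <- (dr * cos(ce$phi) + dc * sin(ce$phi)) / ce$a
      v <- (-dr * sin(ce$phi) + dc * cos(ce$phi)) / ce$b
      inside <- u^2 + v^2 <= 1
      cell_mask[inside] <- i
    }
    bg <- matrix(0, nr, nc)
    if (spec$er_texture_amplitude > 0 && spec$n_cells > 0) {
      tx <- texture_field(nr, nc)
      bg[cell_mask > 0] <- spec$er_background_intensity *
        pmax(0, 1 + spec$er_texture_amplitude * tx[cell_mask > 0])
    } else {
      bg[cell_mask > 0] <- spec$er_background_intensity
    }
    img <- bg
    background_integral <- sum(bg)

    ## condensates per cell
    objects <- NULL
    next_id <- 1L
    per_cell <- integer(spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      ce <- cells[i, ]
      n_i <- if (spec$exact_counts)
        as.integer(rep_len(spec$condensates_per_cell, spec$n_cells)[i])
      else stats::rnbinom(1, size = spec$condensate_dispersion,
                          mu = spec$condensates_per_cell)
      per_cell[i] <- n_i
      if (n_i == 0) next
      margin <- max(r_px) + 3 * spec$edge_sigma_px
      shrink_a <- (ce$a - margin) / ce$a
      shrink_b <- (ce$b - margin) / ce$b
      if (shrink_a <= 0 || shrink_b <= 0)
        stop("condensate radius larger than cell: reject spec")
      sampler <- function() {
        repeat {
          u <- runif(1, -1, 1); v <- runif(1, -1, 1)
          if (u^2 + v^2 <= 1) break
        }
        ua <- u * ce$a * shrink_a; vb <- v * ce$b * shrink_b
        dr <- ua * cos(ce$phi) - vb * sin(ce$phi)
        dc <- ua * sin(ce$phi) + vb * cos(ce$phi)
        c(ce$row0 + dr, ce$col0 + dc,
          runif(1, r_px[1], r_px[2]))
      }
      placed <- place_nonoverlapping(
        n_i, sampler,
        min_dist_fun = function(radii, r_new)
          radii + r_new + 6 * spec$edge_sigma_px,
        max_tries = 2000)
      for (k in seq_len(nrow(placed))) {
        img <- render_disk(img, placed[k, 1], placed[k, 2], placed[k, 3],
                           spec$condensate_peak_intensity,
                           spec$edge_sigma_px)
        objects <- rbind(objects, data.frame(
          id = next_id, cell = i,
          center_row_px = placed[k, 1] - 1,   # 0-based export
          center_col_px = placed[k, 2] - 1,
          radius_px = placed[k, 3],
          peak_intensity = spec$condensate_peak_intensity,
          integral = disk_integral(placed[k, 3],
                                   spec$condensate_peak_intensity,
                                   spec$edge_sigma_px)))
        next_id <- next_id + 1L
      }
    }
    if (is.null(objects))
      objects <- data.frame(id = integer(0), cell = integer(0),
                            center_row_px = numeric(0),
                            center_col_px = numeric(0),
                            radius_px = numeric(0),
                            peak_intensity = numeric(0),
                            integral = numeric(0))
    if (spec$camera_noise_sigma > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$camera_noise_sigma),
                          nr, nc)
    img[img < 0] <- 0
    list(image = image_frame(img, pixel_size_um = px, channel = "sim"),
         truth = list(objects = objects, cell_mask = cell_mask,
                      per_cell_counts = per_cell,
                      background_integral = background_integral,
                      spec = spec, seed = spec$seed))
  })
}

#' Generate a field of non-overlapping in vitro droplets
#'
#' Bright smooth-edged circles on a dark background, emulating fields of
#' phase-separated protein droplets. Droplets are placed by rejection
#' sampling; an error names the retry cap if the requested packing is
#' infeasible.
#'
#' @param n_droplets Number of droplets (>= 0).
#' @param radius_px Length-2 radius range in pixels.
#' @param image_size Integer pair `(rows, cols)`.
#' @param peak_intensity Droplet intensity above background (a.u.).
#' @param background Background level (a.u.).
#' @param noise_sigma Additive Gaussian noise s.d. (a.u.).
#' @param edge_sigma_px Edge softness (px).
#' @param pixel_size_um Pixel size (um/px).
#' @param min_separation_px Extra clearance between droplet rims (px).
#' @param max_tries Placement retries per droplet before giving up.
#' @param seed Integer RNG seed.
#' @return A list `image` (an [image_frame()]) and `truth` (`objects`
#'   data frame with 0-based centers and radii).
#' @export
sim_droplet_field <- function(n_droplets, radius_px = c(5, 8),
                              image_size = c(512L, 512L),
                              peak_intensity = 200, background = 10,
                              noise_sigma = 0, edge_sigma_px = 1,
                              pixel_size_um = 0.1,
                              min_separation_px = 4, max_tries = 2000,
                              seed = 1L) {
  stopifnot(n_droplets >= 0, length(radius_px) == 2L, all(radius_px > 0),
            radius_px[2] < min(image_size) / 2, peak_intensity > 0,
            background >= 0, noise_sigma >= 0)
  with_seed(seed, {
    nr <- image_size[1]; nc <- image_size[2]
    img <- matrix(background, nr, nc)
    margin <- radius_px[2] + 3 * edge_sigma_px + 1
    sampler <- function()
      c(runif(1, margin, nr - margin), runif(1, margin, nc - margin),
        runif(1, radius_px[1], radius_px[2]))
    objects <- data.frame(id = integer(0), center_row_px = numeric(0),
                          center_col_px = numeric(0), radius_px = numeric(0),
                          peak_intensity = numeric(0))
    if (n_droplets > 0) {
      placed <- place_nonoverlapping(
        n_droplets, sampler,
        min_dist_fun = function(radii, r_new)
          radii + r_new + min_separation_px,
        max_tries = max_tries)
      for (k in seq_len(nrow(placed)))
        img <- render_disk(img, placed[k, 1], placed[k, 2], placed[k, 3],
                           peak_intensity, edge_sigma_px)
      objects <- data.frame(id = seq_len(n_droplets),
                            center_row_px = placed[, 1] - 1,
                            center_col_px = placed[, 2] - 1,
                            radius_px = placed[, 3],
                            peak_intensity = peak_intensity)
    }
    if (noise_sigma > 0)
      img <- img + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
    img[img < 0] <- 0
    list(image = image_frame(img, pixel_size_um = pixel_size_um,
                             channel = "sim"),
         truth = list(objects = objects, seed = seed))
  })
}

#' Generate a droplet-count titration from the Hill model
#'
#' Per concentration, draws `fields_per_conc` integer counts from a
#' Poisson distribution whose mean is the Hill curve evaluated at that
#' concentration.
#'
#' @param spec A [titration_spec()].
#' @return A `titration_series` data frame with columns `conc_uM`,
#'   `field_id`, `count`, and the generating spec as attribute `"truth"`.
#' @export
sim_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  with_seed(spec$seed, {
    mu <- hill_model(spec$conc_grid_uM, spec$hill)
    if (any(mu < 0)) stop("invalid Hill parameters: negative mean count")
    rows <- do.call(rbind, lapply(seq_along(spec$conc_grid_uM), function(i)
      data.frame(conc_uM = spec$conc_grid_uM[i],
                 field_id = seq_len(spec$fields_per_conc[i]),
                 count = rpois(spec$fields_per_conc[i], mu[i]))))
    structure(rows, class = c("titration_series", "data.frame"),
              truth = spec)
  })
}

#' Generate a synthetic FRAP trace
#'
#' A prebleach plateau, an instantaneous bleach at a frame boundary, and
#' exchange-limited recovery. The recovery clock is zero at the first
#' postbleach frame, which therefore reads exactly `postbleach_level`
#' (plus noise):
#' `I(t) = post + m * (pre - post) * (1 - 2^(-t / t_half))`.
#' With two half-times, the mobile amplitude is split between a fast and
#' a slow exponential phase by `fast_fraction`.
#'
#' @param spec A [frap_spec()].
#' @return A [frap_trace()] with attribute `"truth"` carrying the spec.
#' @export
sim_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  with_seed(spec$seed, {
    dt <- spec$frame_interval_s
    npre <- spec$n_prebleach_frames
    time_s <- (seq_len(npre + spec$n_frames) - 1) * dt
    t_rec <- (seq_len(spec$n_frames) - 1) * dt
    depth <- spec$prebleach_level - spec$postbleach_level
    amp <- spec$mobile_fraction * depth
    if (length(spec$t_half_s) == 1L) {
      rec <- amp * (1 - 2^(-t_rec / spec$t_half_s))
    } else {
      rec <- amp * (spec$fast_fraction * (1 - 2^(-t_rec / spec$t_half_s[1])) +
                    (1 - spec$fast_fraction) *
                      (1 - 2^(-t_rec / spec$t_half_s[2])))
    }
    roi <- c(rep(spec$prebleach_level, npre), spec$postbleach_level + rec)
    if (spec$noise_sigma > 0)
      roi <- roi + rnorm(length(roi), 0, spec$noise_sigma)
    tr <- frap_trace(time_s = time_s, roi = roi,
                     background = rep(0, length(roi)),
                     bleach_frame = npre + 1L)
    attr(tr, "truth") <- spec
    tr
  })
}

#' Generate per-residue slow-exchange NMR doublets
#'
#' One 1D spectrum per residue: two Lorentzians of equal linewidth whose
#' areas are in the ratio `p_P : (1 - p_P)` (conformation P at positive
#' frequency), plus white noise at the stated SNR. The analytic area of a
#' Lorentzian of height `h` and FWHM `G` is `(pi / 2) * h * G`.
#'
#' @param spec An [nmr_spec()].
#' @return A list `spectra` (list of [spectrum1d()]) and `truth` (data
#'   frame with per-residue peak centres, heights, areas and noise s.d.).
#' @export
sim_nmr_doublets <- function(spec) {
  stopifnot(inherits(spec, "nmr_spec"))
  with_seed(spec$seed, {
    G <- spec$linewidth_hz
    half_span <- spec$peak_sep_hz / 2 + spec$span_linewidths * G
    axis <- seq(-half_span, half_span, length.out = spec$n_points)
    area_total <- 1000        # arbitrary amplitude; populations are ratios
    aP <- spec$p_P * area_total
    aO <- (1 - spec$p_P) * area_total
    hP <- 2 * aP / (pi * G)
    hO <- 2 * aO / (pi * G)
    cP <- spec$peak_sep_hz / 2
    cO <- -spec$peak_sep_hz / 2
    noise_sd <- if (is.finite(spec$snr)) max(hP, hO) / spec$snr else 0
    lor <- function(x, x0, h) h / (1 + (2 * (x - x0) / G)^2)
    spectra <- lapply(seq_len(spec$n_residues), function(i) {
      y <- lor(axis, cP, hP) + lor(axis, cO, hO)
      if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
      spectrum1d(axis_hz = axis, intensity = y,
                 residue_id = sprintf("res%02d", i))
    })
    truth <- data.frame(residue_id = sprintf("res%02d",
                                             seq_len(spec$n_residues)),
                        center_P_hz = cP, center_O_hz = cO,
                        height_P = hP, height_O = hO,
                        area_P = aP, area_O = aO,
                        linewidth_hz = G, noise_sd = noise_sd)
    list(spectra = spectra, truth = truth, spec = spec)
  })
}

#' Generate a one-site binding isotherm over a serial dilution
#'
#' Titrant concentrations form a strictly decreasing geometric dilution
#' series; the noiseless response follows the exact one-site bound
#' fraction in total concentrations (see [one_site_bound_fraction()]).
#'
#' @param spec An [isotherm_spec()].
#' @return A `binding_isotherm` data frame (`conc_uM`, `response`) with
#'   the spec as attribute `"truth"`.
#' @export
sim_isotherm <- function(spec) {
  stopifnot(inherits(spec, "isotherm_spec"))
  with_seed(spec$seed, {
    conc <- spec$titrant_top_uM / spec$dilution_factor^(0:(spec$n_points - 1))
    fb <- one_site_bound_fraction(conc, spec$labeled_conc_nM / 1000,
                                  spec$kd_uM)
    resp <- spec$response_free +
      (spec$response_bound - spec$response_free) * fb
    if (spec$noise_sigma > 0)
      resp <- resp + rnorm(length(resp), 0, spec$noise_sigma)
    structure(data.frame(conc_uM = conc, response = resp),
              class = c("binding_isotherm", "data.frame"), truth = spec)
  })
}
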