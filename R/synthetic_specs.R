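## Validated parameter bundles for the synthetic-data generators. Each
## constructor checks its invariants once so the generators can assume a
## sane spec.

#' Specification of a synthetic cell field
#'
#' Describes an image of `n_cells` elliptical cell regions on a dark
#' background, each containing bright, near-circular condensates rendered
#' as Gaussian-smoothed disks on an ER-like textured interior.
#'
#' @param image_size_px Integer pair `(rows, cols)`.
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @param n_cells Number of cells.
#' @param condensates_per_cell Mean of the per-cell condensate count.
#'   Counts are drawn from a negative binomial with this mean and
#'   `condensate_dispersion` (Poisson in the limit of large dispersion),
#'   or taken as exact when `exact_counts = TRUE`; in that case a vector
#'   of length `n_cells` prescribes each cell's count individually.
#' @param condensate_dispersion Negative-binomial size parameter.
#' @param exact_counts If `TRUE`, every cell receives exactly
#'   `condensates_per_cell` condensates (must then be a whole number).
#' @param condensate_radius_um Length-2 range of condensate radii (um).
#' @param condensate_peak_intensity Peak intensity above local background
#'   (arbitrary units).
#' @param er_background_intensity Mean in-cell background intensity (a.u.).
#' @param er_texture_amplitude Amplitude of the smooth multiplicative
#'   ER-like texture, as a fraction of the background (0 disables).
#' @param camera_noise_sigma Additive Gaussian camera noise s.d. (a.u.).
#' @param edge_sigma_px Softness (Gaussian s.d., px) of condensate edges.
#' @param seed Integer RNG seed.
#' @return A `cell_field_spec` list.
#' @export
cell_field_spec <- function(image_size_px = c(512L, 512L),
                            pixel_size_um = 0.1,
                            n_cells = 4L,
                            condensates_per_cell = 10,
                            condensate_dispersion = 5,
                            exact_counts = FALSE,
                            condensate_radius_um = c(0.2, 0.5),
                            condensate_peak_intensity = 400,
                            er_background_intensity = 100,
                            er_texture_amplitude = 0.15,
                            camera_noise_sigma = 10,
                            edge_sigma_px = 1,
                            seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px > 16),
            pixel_size_um > 0, n_cells >= 0,
            all(condensates_per_cell >= 0), condensate_dispersion > 0,
            length(condensates_per_cell) %in% c(1L, max(1L, n_cells)),
            length(condensate_radius_um) == 2L,
            all(condensate_radius_um > 0),
            diff(condensate_radius_um) >= 0,
            condensate_radius_um[2] < min(image_size_px) * pixel_size_um / 2,
            condensate_peak_intensity > 0, er_background_intensity >= 0,
            er_texture_amplitude >= 0, camera_noise_sigma >= 0,
            edge_sigma_px > 0)
  if (length(condensates_per_cell) > 1L && !exact_counts)
    stop("per-cell count vectors require exact_counts = TRUE")
  if (exact_counts && any(condensates_per_cell != round(condensates_per_cell)))
    stop("`condensates_per_cell` must be a whole number when exact_counts = TRUE")
  structure(as.list(environment()), class = "cell_field_spec")
}

#' Specification of a synthetic FRAP trace
#'
#' Parameters of a photobleach-recovery experiment: a prebleach plateau,
#' an instantaneous bleach at a frame boundary, and single-exponential
#' exchange-limited recovery (optionally two-phase).
#'
#' @param t_half_s Recovery half-time in seconds (> 0). For the two-phase
#'   model, a length-2 vector (fast, slow).
#' @param mobile_fraction Fraction of the bleached depth that recovers,
#'   in `[0, 1]`. For two-phase, the amplitude split is set by
#'   `fast_fraction`.
#' @param prebleach_level,postbleach_level Plateau and first-postbleach
#'   intensities (a.u.); `postbleach_level < prebleach_level`.
#' @param n_prebleach_frames Number of prebleach frames (>= 1).
#' @param n_frames Number of postbleach frames.
#' @param frame_interval_s Frame interval in seconds.
#' @param noise_sigma Additive Gaussian noise s.d. (a.u.).
#' @param fast_fraction For two-phase recovery, the fraction of the mobile
#'   amplitude carried by the fast component.
#' @param seed Integer RNG seed.
#' @return A `frap_spec` list.
#' @export
frap_spec <- function(t_half_s = 78, mobile_fraction = 0.9,
                      prebleach_level = 1, postbleach_level = 0.2,
                      n_prebleach_frames = 10L, n_frames = 200L,
                      frame_interval_s = 1, noise_sigma = 0.02,
                      fast_fraction = 0.5, seed = 1L) {
  stopifnot(all(t_half_s > 0), length(t_half_s) %in% 1:2,
            mobile_fraction >= 0, mobile_fraction <= 1,
            postbleach_level < prebleach_level,
            n_prebleach_frames >= 1, n_frames >= 2,
            frame_interval_s > 0, noise_sigma >= 0,
            fast_fraction >= 0, fast_fraction <= 1)
  structure(as.list(environment()), class = "frap_spec")
}

#' Specification of a synthetic Ca2+ droplet-count titration
#'
#' Droplet counts per field of view follow a Poisson distribution whose
#' mean is the Hill model [hill_model()] evaluated at each concentration.
#'
#' @param hill A [hill_params()] object (ground-truth curve).
#' @param conc_grid_uM Concentrations in micromolar (>= 0).
#' @param fields_per_conc Number of imaged fields per concentration;
#'   recycled to the grid length.
#' @param seed Integer RNG seed.
#' @return A `titration_spec` list.
#' @export
titration_spec <- function(hill,
                           conc_grid_uM = round(exp(seq(log(100), log(1000),
                                                        length.out = 12))),
                           fields_per_conc = ifelse(conc_grid_uM >= 500, 9L, 6L),
                           seed = 1L) {
  stopifnot(inherits(hill, "hill_params"), all(conc_grid_uM >= 0),
            length(conc_grid_uM) >= 1)
  fields_per_conc <- rep_len(as.integer(fields_per_conc),
                             length(conc_grid_uM))
  if (any(fields_per_conc < 1)) stop("fields_per_conc must be >= 1")
  structure(list(hill = hill, conc_grid_uM = conc_grid_uM,
                 fields_per_conc = fields_per_conc, seed = seed),
            class = "titration_spec")
}

#' Specification of synthetic slow-exchange NMR doublets
#'
#' One 1D spectrum per residue, each the sum of two Lorentzians whose
#' areas are in the ratio `p_P : (1 - p_P)`, plus white noise.
#'
#' @param n_residues Number of residues (spectra).
#' @param p_P Population of conformation P, in `[0, 1]`.
#' @param peak_sep_hz Separation of the two peak centres (Hz).
#' @param linewidth_hz Full width at half maximum of each peak (Hz).
#' @param snr Ratio of the tallest peak height to the noise s.d.
#'   (`Inf` for noiseless spectra).
#' @param n_points Number of spectral points.
#' @param span_linewidths Half-range of the axis, in linewidths, beyond
#'   the outer peak (controls how much flat baseline is available).
#' @param allow_overlap Permit `peak_sep_hz <= linewidth_hz` (only for
#'   deliberate overlap experiments).
#' @param seed Integer RNG seed.
#' @return An `nmr_spec` list.
#' @export
nmr_spec <- function(n_residues = 9L, p_P = 0.57, peak_sep_hz = 80,
                     linewidth_hz = 20, snr = 50, n_points = 2048L,
                     span_linewidths = 25, allow_overlap = FALSE,
                     seed = 1L) {
  stopifnot(n_residues >= 1, p_P >= 0, p_P <= 1, peak_sep_hz > 0,
            linewidth_hz > 0, snr > 0, n_points >= 64,
            span_linewidths > 2)
  if (!allow_overlap && peak_sep_hz <= linewidth_hz)
    stop("peaks not resolvable: separation must exceed the linewidth")
  structure(as.list(environment()), class = "nmr_spec")
}

#' Specification of a synthetic one-site binding isotherm
#'
#' A serial-dilution titration of an unlabeled titrant against a fixed
#' labeled partner; the response interpolates `response_free` to
#' `response_bound` by the exact one-site bound fraction (quadratic in
#' total concentrations).
#'
#' @param kd_uM Ground-truth dissociation constant (uM, > 0).
#' @param labeled_conc_nM Labeled-partner concentration (nM).
#' @param titrant_top_uM Highest titrant concentration (uM).
#' @param dilution_factor Serial-dilution factor (> 1).
#' @param n_points Number of titration points.
#' @param response_free,response_bound Responses of the free and bound
#'   states (a.u.).
#' @param noise_sigma Gaussian response noise s.d., in absolute response
#'   units.
#' @param seed Integer RNG seed.
#' @return An `isotherm_spec` list.
#' @export
isotherm_spec <- function(kd_uM = 50, labeled_conc_nM = 20,
                          titrant_top_uM = 2000, dilution_factor = 2,
                          n_points = 16L, response_free = 0,
                          response_bound = 1,
                          noise_sigma = 0.02, seed = 1L) {
  stopifnot(kd_uM > 0, labeled_conc_nM > 0, titrant_top_uM > 0,
            dilution_factor > 1, n_points >= 2, noise_sigma >= 0,
            response_bound != response_free)
  structure(as.list(environment()), class = "isotherm_spec")
}
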