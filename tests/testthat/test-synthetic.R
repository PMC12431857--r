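# Generators: determinism, ground-truth bookkeeping, and the analytic
# identities each synthetic model must satisfy.

test_that("cell field ground truth matches what is rendered", {
  f0 <- sim_cell_field(cell_field_spec(n_cells = 1,
                                       condensates_per_cell = 0,
                                       image_size_px = c(128, 128),
                                       seed = 2))
  expect_identical(nrow(f0$truth$objects), 0L)

  f <- noiseless_cell_field(counts = 20, seed = 5)
  expect_identical(nrow(f$truth$objects), 20L)
  cent <- cbind(round(f$truth$objects$center_row_px) + 1,
                round(f$truth$objects$center_col_px) + 1)
  expect_true(all(f$truth$cell_mask[cent] == f$truth$objects$cell))
})

test_that("noiseless render conserves intensity: background + analytic object integrals", {
  f <- noiseless_cell_field(counts = 15, seed = 9)
  expected <- f$truth$background_integral + sum(f$truth$objects$integral)
  expect_lt(abs(sum(f$image$intensity) - expected) / expected, 0.001)
})

test_that("generators are bit-identical under a fixed seed", {
  a <- sim_cell_field(cell_field_spec(seed = 42, image_size_px = c(128, 128),
                                      n_cells = 2, condensates_per_cell = 3,
                                      exact_counts = TRUE))
  b <- sim_cell_field(cell_field_spec(seed = 42, image_size_px = c(128, 128),
                                      n_cells = 2, condensates_per_cell = 3,
                                      exact_counts = TRUE))
  expect_identical(a$image$intensity, b$image$intensity)
  expect_identical(a$truth$objects, b$truth$objects)

  d1 <- sim_droplet_field(12, seed = 7, image_size = c(256, 256))
  d2 <- sim_droplet_field(12, seed = 7, image_size = c(256, 256))
  expect_identical(d1$image$intensity, d2$image$intensity)

  t1 <- sim_titration(titration_spec(hill_params(), seed = 11))
  t2 <- sim_titration(titration_spec(hill_params(), seed = 11))
  expect_identical(t1$count, t2$count)

  n1 <- sim_nmr_doublets(nmr_spec(seed = 3))
  n2 <- sim_nmr_doublets(nmr_spec(seed = 3))
  expect_identical(n1$spectra[[1]]$intensity, n2$spectra[[1]]$intensity)
})

test_that("droplet fields respect non-overlap and empty/packing edge cases", {
  e <- sim_droplet_field(0, seed = 1, image_size = c(128, 128))
  expect_identical(nrow(e$truth$objects), 0L)
  expect_true(all(e$image$intensity == 10))  # blank background

  f <- sim_droplet_field(12, radius_px = c(5, 8), image_size = c(512, 512),
                         seed = 2)
  tr <- f$truth$objects
  expect_identical(nrow(tr), 12L)
  d <- as.matrix(stats::dist(tr[, c("center_row_px", "center_col_px")]))
  rs <- outer(tr$radius_px, tr$radius_px, "+")
  diag(d) <- Inf
  expect_true(all(d > rs))

  expect_error(
    sim_droplet_field(500, radius_px = c(10, 12), image_size = c(64, 64),
                      max_tries = 50, seed = 1),
    "50 tries")
})

test_that("titration counts follow the Hill mean and Poisson dispersion", {
  hp <- hill_params(nc_min = 0, nc_max = 100, kd_uM = 420, n_hill = 7)
  # midpoint identity at conc = kd, for any Hill coefficient
  expect_equal(hill_model(420, hp), 50)
  expect_equal(hill_model(0, hp), 0)

  ser <- sim_titration(titration_spec(hill_params(5, 45, 300, 2),
                                      conc_grid_uM = 300,
                                      fields_per_conc = 10000, seed = 8))
  expect_true(all(ser$count == round(ser$count)) && all(ser$count >= 0))
  expect_lt(abs(var(ser$count) / mean(ser$count) - 1), 0.05)
  expect_lt(abs(mean(ser$count) - 25) / 25, 0.05)
})

test_that("FRAP traces obey the half-time, immobile and saturation identities", {
  sp <- frap_spec(t_half_s = 50, mobile_fraction = 0.6, noise_sigma = 0,
                  prebleach_level = 1, postbleach_level = 0.2,
                  frame_interval_s = 1, n_frames = 300)
  tr <- sim_frap_trace(sp)
  bf <- attr(tr, "bleach_frame")
  t_rec <- tr$time_s[bf:nrow(tr)] - tr$time_s[bf]
  # at t = t_half the recovered fraction is exactly m/2 of the bleached depth
  i_half <- which(t_rec == 50)
  expect_equal(tr$roi[bf + i_half - 1] - 0.2, 0.6 * 0.8 / 2)

  flat <- sim_frap_trace(frap_spec(t_half_s = 50, mobile_fraction = 0,
                                   noise_sigma = 0))
  post <- flat$roi[attr(flat, "bleach_frame"):nrow(flat)]
  expect_true(all(post == post[1]))

  full <- sim_frap_trace(frap_spec(t_half_s = 2, mobile_fraction = 1,
                                   noise_sigma = 0, n_frames = 5000))
  expect_lt(abs(tail(full$roi, 1) - 1), 1e-6)
})

test_that("doublet spectra have Lorentzian areas in the prescribed ratio", {
  sim <- sim_nmr_doublets(nmr_spec(p_P = 0.5, snr = Inf, seed = 1))
  sp <- sim$spectra[[1]]
  tr <- sim$truth[1, ]
  # numeric trapezoid over each half-axis: equal-area peaks
  x <- sp$axis_hz; y <- sp$intensity
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  aO <- trapz(x[x < 0], y[x < 0]); aP <- trapz(x[x > 0], y[x > 0])
  expect_lt(abs(aP - aO) / aP, 0.01)

  one <- sim_nmr_doublets(nmr_spec(p_P = 1, snr = Inf, seed = 1))
  expect_equal(one$truth$area_O[1], 0)

  # closed-form Lorentzian window integral h * G * atan(2w / G): the
  # trapezoid over +-20 FWHM matches it sharply, and the truncated
  # window carries 98.4% of the full area (pi / 2) h G
  G <- 20; h <- 3
  xx <- seq(-20 * G, 20 * G, length.out = 40001)
  yy <- h / (1 + (2 * xx / G)^2)
  expect_lt(abs(trapz(xx, yy) - h * G * atan(40)) / (h * G * atan(40)),
            1e-4)
  expect_lt(abs(trapz(xx, yy) - pi / 2 * h * G) / (pi / 2 * h * G), 0.02)
})

test_that("isotherm generator follows the exact one-site bound fraction", {
  # midpoint in the ligand-excess limit
  fb <- one_site_bound_fraction(50, 0.02, 50)
  expect_lt(abs(fb - 0.5), 0.005)
  expect_equal(one_site_bound_fraction(0, 0.02, 50), 0)

  # binding depletes free titrant, so the exact (total-concentration)
  # bound fraction lies below the hyperbola in total titrant, reaching
  # it in the limit of vanishing labeled concentration
  tt <- 10^seq(-1, 4, length.out = 50)
  for (L in c(5, 0.5, 1e-6)) {
    quad <- one_site_bound_fraction(tt, L, 50)
    hyper <- tt / (tt + 50)
    # 1e-6 slack absorbs sqrt cancellation error at vanishing L
    expect_true(all(quad <= hyper + 1e-6))
    if (L == 1e-6) expect_lt(max(abs(quad - hyper)), 1e-5)
    if (L == 5) expect_gt(max(hyper - quad), 0.01)
  }

  iso <- sim_isotherm(isotherm_spec(noise_sigma = 0, seed = 1))
  expect_true(all(diff(iso$conc_uM) < 0))  # strictly decreasing dilution
  expect_identical(nrow(iso), 16L)
})

test_that("invalid specs are rejected", {
  expect_error(frap_spec(postbleach_level = 2, prebleach_level = 1))
  expect_error(frap_spec(mobile_fraction = 1.5))
  expect_error(nmr_spec(peak_sep_hz = 10, linewidth_hz = 20),
               "resolvable")
  expect_error(isotherm_spec(dilution_factor = 1))
  expect_error(cell_field_spec(condensate_radius_um = c(5, 50),
                               image_size_px = c(64, 64)))
  # condensate radius larger than the cell interior
  expect_error(
    sim_cell_field(cell_field_spec(image_size_px = c(64, 64), n_cells = 4,
                                   condensate_radius_um = c(0.9, 0.9),
                                   condensates_per_cell = 1,
                                   exact_counts = TRUE, seed = 1)),
    "reject spec")
})
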