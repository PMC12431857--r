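# Cell segmentation and condensate/droplet detection against generator
# ground truth.

test_that("Otsu segmentation is exact on a two-level image and rejects blanks", {
  m <- matrix(10, 64, 64)
  m[20:40, 25:45] <- 100
  img <- image_frame(m, pixel_size_um = 0.2)
  mask <- segment_cells(img, min_cell_area_um2 = 1)
  expect_identical(unname(mask == 1), unname(m == 100))
  expect_error(segment_cells(flat_frame(5)), "degenerate histogram")
})

test_that("segmentation covers the generated cell mask on noiseless fields", {
  f <- noiseless_cell_field(n_cells = 2, counts = 5, seed = 21)
  mask <- segment_cells(f$image)
  truth_px <- f$truth$cell_mask > 0
  expect_gt(sum(mask > 0 & truth_px) / sum(truth_px), 0.99)
})

test_that("noiseless condensates are recovered exactly, 1:1, within 1 px", {
  f <- noiseless_cell_field(counts = 20, seed = 5)
  mask <- segment_cells(f$image)
  det <- detect_condensates(f$image, mask)
  expect_identical(nrow(det$objects), 20L)
  d <- nearest_detection_dist(det$objects$centroid_row_px,
                              det$objects$centroid_col_px,
                              f$truth$objects)
  expect_true(all(d < 1))
})

test_that("rendered disks measure as near-circular (Crofton perimeter)", {
  f <- noiseless_cell_field(counts = 10, seed = 13)
  det <- detect_condensates(f$image, segment_cells(f$image))
  expect_true(all(det$objects$circularity >= 0.9))
  expect_true(all(det$objects$circularity <= 1))
})

test_that("filters dominate and are monotone in the detection count", {
  f <- sim_cell_field(cell_field_spec(image_size_px = c(256, 256),
                                      n_cells = 1,
                                      condensates_per_cell = 15,
                                      exact_counts = TRUE, seed = 17))
  mask <- segment_cells(f$image)
  # impossible circularity -> empty set
  none <- detect_condensates(f$image, mask,
                             condensate_params(min_circularity = 1.01))
  expect_identical(nrow(none$objects), 0L)
  # raising min_circularity or min_area never increases the count
  circ_ladder <- c(0, 0.4, 0.7, 0.9, 0.99)
  n_circ <- vapply(circ_ladder, function(mc)
    nrow(detect_condensates(f$image, mask,
                            condensate_params(min_circularity = mc))$objects),
    integer(1))
  expect_true(all(diff(n_circ) <= 0))
  area_ladder <- c(0.02, 0.1, 0.3, 1, 5)
  n_area <- vapply(area_ladder, function(ma)
    nrow(detect_condensates(f$image, mask,
                            condensate_params(min_area_um2 = ma))$objects),
    integer(1))
  expect_true(all(diff(n_area) <= 0))
})

test_that("per-cell aggregation recovers known counts and conserves totals", {
  f <- sim_cell_field(cell_field_spec(image_size_px = c(384, 384),
                                      n_cells = 3,
                                      condensates_per_cell = c(5, 10, 0),
                                      exact_counts = TRUE,
                                      camera_noise_sigma = 0,
                                      er_texture_amplitude = 0, seed = 31))
  # use the generator's cell mask so cell labels match the truth exactly
  mask <- structure(f$truth$cell_mask, class = "cell_mask",
                    pixel_size_um = f$image$pixel_size_um)
  det <- detect_condensates(f$image, mask)
  tab <- count_per_cell(det, mask)
  expect_identical(tab$n_condensates, c(5L, 10L, 0L))
  expect_identical(sum(tab$n_condensates), nrow(det$objects))
  expect_true(is.na(tab$mean_area_um2[3]))
})

test_that("empty mask yields an empty set, bad params an error", {
  img <- flat_frame(7, 64, 64)
  img$intensity[10, 10] <- 100
  empty_mask <- structure(matrix(0L, 64, 64), class = "cell_mask",
                          pixel_size_um = 0.1)
  det <- detect_condensates(img, empty_mask)
  expect_identical(nrow(det$objects), 0L)
  full_mask <- structure(matrix(1L, 64, 64), class = "cell_mask",
                         pixel_size_um = 0.1)
  expect_error(detect_condensates(img, full_mask,
                                  condensate_params(k_sigma = NaN)))
})

test_that("Hough detection is exact on noiseless droplet fields", {
  blank <- flat_frame(3, 128, 128)
  expect_identical(nrow(detect_droplets(blank, c(4, 10))), 0L)

  f <- sim_droplet_field(12, radius_px = c(6, 6), image_size = c(512, 512),
                         seed = 3)
  d <- detect_droplets(f$image, radius_px_range = c(4, 10))
  expect_identical(nrow(d), 12L)
  dist <- nearest_detection_dist(d$center_row_px, d$center_col_px,
                                 f$truth$objects)
  expect_true(all(dist <= 1))
  expect_true(all(abs(d$radius_px - 6) <= 1))
  expect_error(detect_droplets(f$image, c(300, 400)), "radius")
})

test_that("droplet recall and precision reach 0.95 at SNR 10", {
  perf <- vapply(1:9, function(s) {
    f <- sim_droplet_field(30, radius_px = c(5, 8),
                           image_size = c(512, 512),
                           noise_sigma = 20, seed = s)  # peak 200 -> SNR 10
    d <- detect_droplets(f$image, radius_px_range = c(4, 10))
    tr <- f$truth$objects
    matched <- vapply(seq_len(nrow(tr)), function(i)
      any(sqrt((d$center_row_px - tr$center_row_px[i])^2 +
               (d$center_col_px - tr$center_col_px[i])^2) < 4),
      logical(1))
    c(recall = sum(matched) / nrow(tr),
      precision = sum(matched) / max(nrow(d), 1))
  }, numeric(2))
  expect_gte(mean(perf["recall", ]), 0.95)
  expect_gte(mean(perf["precision", ]), 0.95)
})

test_that("detection is equivariant under whole-pixel translations", {
  f <- sim_droplet_field(8, radius_px = c(5, 7), image_size = c(200, 200),
                         seed = 6)
  img <- f$image$intensity
  # small shift keeps every droplet fully inside the image (borders excluded)
  dr <- 3L; dc <- 4L
  shifted <- matrix(10, 200, 200)  # background level of the generator
  shifted[(1 + dr):200, (1 + dc):200] <-
    img[1:(200 - dr), 1:(200 - dc)]
  d0 <- detect_droplets(f$image, c(4, 9))
  d1 <- detect_droplets(image_frame(shifted, 0.1), c(4, 9))
  expect_identical(nrow(d1), nrow(d0))
  o0 <- order(d0$center_row_px, d0$center_col_px)
  o1 <- order(d1$center_row_px, d1$center_col_px)
  expect_equal(d1$center_row_px[o1], d0$center_row_px[o0] + dr)
  expect_equal(d1$center_col_px[o1], d0$center_col_px[o0] + dc)
})

test_that("per-field droplet counting matches ground truth", {
  imgs <- lapply(1:3, function(s)
    sim_droplet_field(10, radius_px = c(5, 7), image_size = c(256, 256),
                      seed = s)$image)
  tab <- droplets_per_field(imgs, radius_px_range = c(4, 9))
  expect_identical(tab$n_droplets, rep(10L, 3))
  same <- droplets_per_field(rep(imgs[1], 3), radius_px_range = c(4, 9))
  expect_identical(length(unique(same$n_droplets)), 1L)
})
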