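# Shared fixture builders. Everything is generated in code so tests run
# without any stored data.

noiseless_cell_field <- function(n_cells = 1, counts = 20, seed = 5,
                                 size = c(256, 256), peak = 400) {
  sim_cell_field(cell_field_spec(
    image_size_px = size, n_cells = n_cells,
    condensates_per_cell = counts, exact_counts = TRUE,
    condensate_peak_intensity = peak,
    camera_noise_sigma = 0, er_texture_amplitude = 0, seed = seed))
}

# match detections to ground-truth objects by nearest centre; returns
# per-truth-object distance of its nearest detection
nearest_detection_dist <- function(det_rows, det_cols, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((det_rows - truth$center_row_px[i])^2 +
             (det_cols - truth$center_col_px[i])^2)),
    numeric(1))
}

flat_frame <- function(value, nr = 32, nc = 32, px = 0.1)
  image_frame(matrix(value, nr, nc), pixel_size_um = px)
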