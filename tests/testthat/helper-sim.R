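# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Small single-class configuration: every cell responds to "SE" with the
# given amplitude.
tiny_config <- function(n_cells = 4, amplitude = 0.5, noise_sigma = 0,
                        seed = 2, image_shape = c(64, 64),
                        radius = c(3, 5), ...) {
  sim_config(image_shape = image_shape, n_cells = n_cells,
             noise_sigma = noise_sigma, cell_radius_range = radius,
             seed = seed,
             tuning_classes = list(list(label = "resp", fraction = 1,
                                        response_prob = c(SE = 1),
                                        amplitude = amplitude)),
             ...)
}

tiny_schedule <- function(cfg, labels = "SE", conc = NA_real_,
                          epoch_s = 10, gap_s = 60, lead_in_s = 30) {
  generate_stimulus_schedule(cfg,
                             data.frame(label = labels,
                                        concentration_M = conc),
                             epoch_s = epoch_s, gap_s = gap_s,
                             lead_in_s = lead_in_s)
}

# Hand-made ground truth -> movie via the forward model, bypassing random
# cell placement, for tests needing exact geometry/response layouts.
manual_movie <- function(centers, radii, b0, amplitudes, cfg, schedule) {
  gt <- structure(list(cell_centers = centers, cell_radii = radii,
                       baseline_intensity = b0,
                       class_of_cell = rep("manual", nrow(centers)),
                       true_responder = amplitudes > 0,
                       true_amplitude = amplitudes,
                       colabel_positive = rep(FALSE, nrow(centers)),
                       config = cfg, schedule = schedule),
                  class = "ground_truth")
  list(movie = reconstruct_movie(gt), ground_truth = gt)
}

# Ground-truth ROI for cell i (the rendered disk).
gt_roi <- function(gt, i) {
  H <- gt$config$image_shape[1]; W <- gt$config$image_shape[2]
  list(pixels = vnoca:::disk_pixels(gt$cell_centers[i, 1],
                                    gt$cell_centers[i, 2],
                                    gt$cell_radii[i], H, W))
}

# Match detected ROIs to ground-truth cells: a detection hits cell j when
# its centroid lies within one cell radius of center j.  Returns the
# matched cell index per ROI (NA = false positive).
match_rois <- function(rois, gt) {
  if (length(rois) == 0L) return(integer())
  vapply(rois, function(r) {
    d <- sqrt((gt$cell_centers[, 1] - r$centroid[1])^2 +
              (gt$cell_centers[, 2] - r$centroid[2])^2)
    j <- which.min(d)
    if (d[j] <= gt$cell_radii[j]) j else NA_integer_
  }, integer(1))
}

# Minimal response-matrix data.frame for profiling tests.
make_calls <- function(roi_id, stimulus, dff,
                       concentration_M = NA_real_, threshold = 0.30,
                       slice_id = "s1") {
  out <- data.frame(roi_id = roi_id, stimulus = stimulus,
                    concentration_M = concentration_M,
                    baseline_at_peak = 100, peak_value = 100 * (1 + dff),
                    peak_frame = 1L, dff = dff,
                    responder = dff >= threshold, slice_id = slice_id)
  class(out) <- c("response_matrix", "data.frame")
  out
}
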