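# Population summaries over the response matrix.

test_that("overlap summaries count conditional responders", {
  calls <- make_calls(roi_id = rep(c("c1", "c2", "c3", "c4"), each = 2),
                      stimulus = rep(c("A", "B"), 4),
                      dff = c(0.5, 0.6,   # c1: A+B
                              0.5, 0.4,   # c2: A+B
                              0.5, 0.1,   # c3: A only
                              0.1, 0.1))  # c4: neither
  ov <- overlap_summary(calls, "A", "B")
  expect_equal(ov$n_A, 3L)
  expect_equal(ov$n_AB, 2L)
  expect_equal(ov$pct_B_given_A, 100 * 2 / 3, tolerance = 1e-9)

  # disjoint responder sets and A = B
  calls2 <- make_calls(rep(c("c1", "c2"), each = 2),
                       rep(c("A", "B"), 2), c(0.5, 0.1, 0.1, 0.5))
  expect_equal(overlap_summary(calls2, "A", "B")$pct_B_given_A, 0)
  expect_equal(overlap_summary(calls, "A", "A")$pct_B_given_A, 100)

  # empty A set is flagged undefined
  none <- overlap_summary(calls2, "A", "B")
  none2 <- overlap_summary(make_calls("c1", "A", 0.1), "A", "A")
  expect_true(none2$undefined)
  expect_true(is.na(none2$pct_B_given_A))
  expect_error(overlap_summary(calls, "A", "Z"), "absent")
})

test_that("overlap is permutation invariant and symmetric in n_AB", {
  set.seed(8)
  ids <- sprintf("c%02d", 1:20)
  calls <- make_calls(rep(ids, each = 2), rep(c("A", "B"), 20),
                      runif(40, 0, 0.6))
  shuf <- calls[sample(nrow(calls)), ]
  class(shuf) <- class(calls)
  expect_equal(overlap_summary(shuf, "A", "B")$n_AB,
               overlap_summary(calls, "A", "B")$n_AB)
  expect_equal(overlap_summary(calls, "B", "A")$n_AB,
               overlap_summary(calls, "A", "B")$n_AB)
  tab <- overlap_table(calls, "A", "B")
  expect_equal(sum(tab), 20)
  expect_equal(tab["TRUE", "TRUE"],
               overlap_summary(calls, "A", "B")$n_AB,
               ignore_attr = TRUE)
})

test_that("percent responding handles both denominators", {
  ids <- sprintf("c%03d", 1:100)
  calls <- make_calls(ids, "S", c(rep(0.5, 10), rep(0.05, 90)))
  expect_equal(percent_responding(calls, "S")$percent, 10)
  none <- make_calls(ids, "S", rep(0.05, 100))
  expect_equal(percent_responding(none, "S")$percent, 0)
  mask <- setNames(rep(c(TRUE, FALSE), 50), ids)
  p <- percent_responding(calls, "S", "colabel_positive",
                          colabel_mask = mask)
  expect_equal(p$n_denominator, 50L)
  expect_error(percent_responding(calls, "S", "colabel_positive"),
               "colabel_mask")
  bad <- setNames(rep(FALSE, 100), ids)
  expect_error(percent_responding(calls, "S", "colabel_positive",
                                  colabel_mask = bad), "empty denominator")
})

test_that("normalized tuning panels divide by each cell's maximum", {
  calls <- make_calls(rep("c1", 3), c("P1", "P2", "P3"), c(0.8, 0.4, 0))
  na <- normalized_amplitudes(calls, c("P1", "P2", "P3"))
  expect_equal(na$summary$mean_norm_dff, c(1, 0.5, 0))
  expect_equal(na$n_excluded, 0L)

  silent <- make_calls(rep(c("c1", "c2"), each = 2),
                       rep(c("P1", "P2"), 2), c(0, -0.01, 0, 0))
  na2 <- normalized_amplitudes(silent, c("P1", "P2"))
  expect_equal(nrow(na2$summary), 0L)
  expect_equal(na2$n_excluded, 2L)
  expect_error(normalized_amplitudes(calls, character(0)), "empty")

  # invariance to a common per-cell rescale
  set.seed(3)
  ids <- rep(sprintf("c%d", 1:10), each = 3)
  stim <- rep(c("P1", "P2", "P3"), 10)
  base <- rep(runif(10, 0.5, 2), each = 3) * rep(c(1, 0.5, 0.2), 10)
  a <- normalized_amplitudes(make_calls(ids, stim, base),
                             c("P1", "P2", "P3"))
  b <- normalized_amplitudes(make_calls(ids, stim, base * 4.2),
                             c("P1", "P2", "P3"))
  expect_equal(a$summary$mean_norm_dff, b$summary$mean_norm_dff)
})

test_that("pipeline recovers class tuning ratios on a synthetic panel", {
  cfg <- sim_config(image_shape = c(128, 128), n_cells = 20,
                    cell_radius_range = c(3, 5), noise_sigma = 15,
                    seed = 31,
                    tuning_classes = list(list(
                      label = "cls", fraction = 1,
                      response_prob = c(P1 = 1, P2 = 1, P3 = 1),
                      amplitude = c(P1 = 1.0, P2 = 0.5, P3 = 0.1))))
  sch <- tiny_schedule(cfg, labels = c("P1", "P2", "P3"))
  sim <- generate_slice_movie(cfg, sch)
  rois <- lapply(seq_len(20), function(i) gt_roi(sim$ground_truth, i))
  mat <- build_response_matrix(sim$movie, rois, sch)
  na <- normalized_amplitudes(mat, c("P1", "P2", "P3"))
  s <- na$summary
  for (k in 1:3) {
    expect_lt(abs(s$mean_norm_dff[k] - c(1, 0.5, 0.1)[k]),
              max(3 * s$sem_norm_dff[k], 0.02))
  }
})

test_that("dose-response thresholds and Hill fits behave", {
  conc <- c(1e-10, 1e-9, 1e-8, 1e-7)
  ids <- sprintf("c%d", 1:5)
  zero <- make_calls(rep(ids, 4), "E",
                     rep(0, 20), rep(conc, each = 5))
  dr0 <- dose_response(zero, "E", conc)
  expect_true(is.na(dr0$threshold_concentration))
  expect_true(all(dr0$table$fraction_responding == 0))

  # noiseless Hill data: EC50 = 1 nM, coefficient 1
  hill <- function(c) 0.8 * c / (c + 1e-9)
  calls <- make_calls(rep(ids, 4), "E",
                      rep(hill(conc), each = 5), rep(conc, each = 5))
  dr <- dose_response(calls, "E", conc)
  expect_equal(dr$hill$ec50, 1e-9, tolerance = 0.05)
  expect_equal(dr$hill$coefficient, 1, tolerance = 0.05)

  # monotone amplitudes (0.05, 0.2, 0.5, 0.9) -> threshold at 10 nM
  amp <- c(0.05, 0.2, 0.5, 0.9)
  conc2 <- c(1e-10, 1e-9, 1e-8, 1e-7)
  calls2 <- make_calls(rep(ids, 4), "E",
                       rep(amp, each = 5), rep(conc2, each = 5))
  dr2 <- dose_response(calls2, "E", conc2)
  expect_equal(dr2$threshold_concentration, 1e-8)
  # configurable fraction-based criterion
  dr3 <- dose_response(calls2, "E", conc2, min_fraction = 1)
  expect_equal(dr3$threshold_concentration, 1e-8)
  expect_error(dose_response(calls2[1:3, ], "E", conc2), "missing calls")
})

test_that("colabel gating matches ground truth on the synthetic channel", {
  expect_false(any(colabel_gate(list(list(pixels = cbind(row = 1:3,
                                                         col = 1:3))),
                                matrix(0, 8, 8),
                                intensity_threshold = 10)))
  cfg <- sim_config(image_shape = c(128, 128), n_cells = 25,
                    cell_radius_range = c(3, 5), colabel_fraction = 0.4,
                    seed = 17)
  sch <- tiny_schedule(cfg)
  sim <- generate_slice_movie(cfg, sch)
  gt <- sim$ground_truth
  img <- generate_colabel_image(gt)
  rois <- lapply(seq_len(25), function(i) gt_roi(gt, i))
  gate <- colabel_gate(rois, img, image_shape = c(128, 128))
  expect_gte(mean(gate == gt$colabel_positive), 0.95)
  expect_error(colabel_gate(rois, img[1:64, ], image_shape = c(128, 128)),
               "shape")
})
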