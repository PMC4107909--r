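# Trace extraction, baseline fitting, peak detection, response calls.

const_movie <- function(value, H = 8, W = 8, Tn = 20) {
  ca_movie(array(value, c(H, W, Tn)), 0.5)
}

one_event_schedule <- function(onset, offset, n_frames, dt = 0.5) {
  stim_schedule(data.frame(label = "S", concentration_M = NA,
                           onset_frame = onset, offset_frame = offset),
                frame_interval = dt, n_frames = n_frames)
}

exp_trace <- function(B0, tau, Tn, dt = 0.5, roi_id = "t") {
  tv <- (seq_len(Tn) - 1) * dt
  structure(list(values = B0 * exp(-tv / tau), frame_interval = dt,
                 roi_id = roi_id), class = "ca_trace")
}

test_that("trace extraction averages the ROI pixels", {
  mv <- const_movie(7)
  roi <- list(pixels = cbind(row = c(2L, 3L), col = c(2L, 2L)))
  expect_equal(extract_trace(mv, roi)$values, rep(7, 20))
  # single-pixel ROI equals that pixel's series
  mv$frames[4, 5, ] <- seq_len(20)
  one <- list(pixels = cbind(row = 4L, col = 5L))
  expect_equal(extract_trace(mv, one)$values, as.numeric(1:20))
  expect_error(extract_trace(mv, list(pixels = cbind(row = integer(),
                                                     col = integer()))),
               "empty ROI")
  expect_error(extract_trace(mv, list(pixels = cbind(row = 9L, col = 1L))),
               "outside")
})

test_that("noiseless synthetic cell trace equals the forward model", {
  cfg <- tiny_config(n_cells = 1, amplitude = 0.4, noise_sigma = 0)
  sch <- tiny_schedule(cfg)
  sim <- generate_slice_movie(cfg, sch)
  gt <- sim$ground_truth
  tr <- extract_trace(sim$movie, gt_roi(gt, 1))$values
  tv <- (seq_along(tr) - 1) * cfg$frame_interval
  kern <- vnoca:::transient_kernel(tv - (sch$onset_frame[1] - 1) *
                                     cfg$frame_interval,
                                   cfg$transient_rise_tau,
                                   cfg$transient_decay_tau)
  expected <- gt$baseline_intensity[1] * exp(-tv / cfg$bleach_tau) *
    (1 + 0.4 * kern)
  expect_equal(tr, expected, tolerance = 1e-10)
})

test_that("exponential baseline parameters are recovered on clean traces", {
  tr <- exp_trace(200, 300, 400)
  sch <- one_event_schedule(100, 119, 400)
  bl <- fit_baseline(tr, sch)
  expect_equal(bl$model_kind, "exponential")
  expect_equal(unname(bl$parameters["B0"]), 200, tolerance = 0.01)
  expect_equal(unname(bl$parameters["tau"]), 300, tolerance = 0.01)
})

test_that("constant traces give a constant baseline model", {
  tr <- exp_trace(100, Inf, 60)
  sch <- one_event_schedule(20, 25, 60)
  bl <- fit_baseline(tr, sch)
  expect_equal(bl$model_kind, "constant")
  expect_equal(unname(bl$parameters["level"]), 100)
  expect_equal(predict_baseline(bl, c(1, 30)), c(100, 100))
})

test_that("a masked transient leaves the fitted tau unchanged within 2%", {
  dt <- 0.5; Tn <- 500
  tv <- (seq_len(Tn) - 1) * dt
  sch <- one_event_schedule(200, 219, Tn)
  kern <- vnoca:::transient_kernel(tv - 199 * dt, 1, 8)
  clean <- structure(list(values = 500 * exp(-tv / 400),
                          frame_interval = dt, roi_id = "a"),
                     class = "ca_trace")
  bumped <- clean
  bumped$values <- clean$values * (1 + 1.0 * kern)
  tau_clean <- fit_baseline(clean, sch)$parameters["tau"]
  tau_bump <- fit_baseline(bumped, sch)$parameters["tau"]
  expect_equal(unname(tau_bump), unname(tau_clean), tolerance = 0.02)
})

test_that("baseline fit demands enough unmasked frames", {
  tr <- exp_trace(100, 200, 30)
  sch <- one_event_schedule(5, 10, 30)     # window masks frames 5..125
  expect_error(fit_baseline(tr, sch), "fewer than 10")
})

test_that("peak detection finds the smoothed maximum in-window", {
  Tn <- 300; dt <- 0.5
  v <- rep(100, Tn)
  v[120:140] <- 100 + c(seq(0, 100, length.out = 11),
                        seq(90, 0, length.out = 10))  # triangle peak @130
  tr <- structure(list(values = v, frame_interval = dt, roi_id = "t"),
                  class = "ca_trace")
  ev <- list(onset_frame = 110L, label = "S", concentration_M = NA)
  pk <- detect_peak(tr, ev, response_window_s = 60)
  expect_lte(abs(pk$peak_frame - 130L), 1L)

  # two bumps: the larger wins and matches a brute-force smoothed scan
  v2 <- rep(100, Tn)
  v2[115:119] <- 130; v2[150:154] <- 160
  tr2 <- structure(list(values = v2, frame_interval = dt, roi_id = "t"),
                   class = "ca_trace")
  pk2 <- detect_peak(tr2, ev, response_window_s = 60)
  sm <- sapply(2:(Tn - 1), function(i) mean(v2[(i - 1):(i + 1)]))
  win <- 110:230
  expect_equal(pk2$peak_value, max(sm[win - 1]))
  expect_true(pk2$peak_frame %in% 150:154)
  expect_error(detect_peak(tr, ev, response_window_s = 0.5), "3 frames")
})

test_that("response calls apply the 30% threshold inclusively", {
  Tn <- 200; dt <- 0.5
  mkcall <- function(peak_level) {
    v <- rep(100, Tn); v[60:70] <- peak_level
    tr <- structure(list(values = v, frame_interval = dt, roi_id = "t"),
                    class = "ca_trace")
    sch <- one_event_schedule(55, 75, Tn)
    bl <- fit_baseline(tr, sch)
    call_response(tr, bl, vnoca:::schedule_event(sch, 1))
  }
  hit <- mkcall(140)
  expect_equal(hit$dff, 0.40, tolerance = 1e-9)
  expect_true(hit$responder)
  edge <- mkcall(130)                      # dF/F exactly 0.30
  expect_equal(edge$dff, 0.30, tolerance = 1e-9)
  expect_true(edge$responder)              # inclusive threshold
  flat <- mkcall(100)
  expect_equal(flat$dff, 0, tolerance = 1e-9)
  expect_false(flat$responder)
})

test_that("sub-threshold cells are called non-responders under noise", {
  misses <- 0L
  for (s in 1:100) {
    cfg <- tiny_config(n_cells = 1, amplitude = 0.25, noise_sigma = 15,
                       seed = s, image_shape = c(48, 48))
    sch <- tiny_schedule(cfg)
    sim <- generate_slice_movie(cfg, sch)
    tr <- extract_trace(sim$movie, gt_roi(sim$ground_truth, 1), "c")
    bl <- fit_baseline(tr, sch)
    cl <- call_response(tr, bl, vnoca:::schedule_event(sch, 1))
    if (!cl$responder) misses <- misses + 1L
  }
  expect_gte(misses, 95L)
})

test_that("dF/F is scale invariant and monotone in amplitude", {
  cfg <- tiny_config(n_cells = 1, amplitude = 0.5, noise_sigma = 0)
  sch <- tiny_schedule(cfg)
  sim <- generate_slice_movie(cfg, sch)
  tr <- extract_trace(sim$movie, gt_roi(sim$ground_truth, 1), "c")
  bl <- fit_baseline(tr, sch)
  ev <- vnoca:::schedule_event(sch, 1)
  dff1 <- call_response(tr, bl, ev)$dff
  tr2 <- tr; tr2$values <- tr$values * 3.7
  bl2 <- fit_baseline(tr2, sch)
  expect_equal(call_response(tr2, bl2, ev)$dff, dff1, tolerance = 1e-6)

  dffs <- sapply(c(0.1, 0.3, 0.5, 0.8), function(a) {
    cfg <- tiny_config(n_cells = 1, amplitude = a, noise_sigma = 0)
    sim <- generate_slice_movie(cfg, sch)
    tr <- extract_trace(sim$movie, gt_roi(sim$ground_truth, 1), "c")
    call_response(tr, fit_baseline(tr, sch), ev)$dff
  })
  expect_true(all(diff(dffs) > 0))
})
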