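# Forward model of VNO-slice GCaMP recordings: bright somata on a dark
# background, exponential photobleaching, stimulus-locked calcium
# transients, tuning-class population structure and additive Gaussian
# noise.  Every latent is recorded so downstream stages can be tested by
# recovery.

#' Simulation configuration for synthetic VNO-slice movies
#'
#' Defaults describe a typical two-photon VNO slice recording: a
#' 256 x 256 field with ~50 compact somata, 16-bit-scale baseline
#' brightness, slow photobleaching and GCaMP-like transient kinetics.
#'
#' @param image_shape `c(H, W)` pixels.
#' @param n_frames number of frames; `NULL` to take it from the schedule.
#' @param frame_interval seconds per frame.
#' @param n_cells number of somata.
#' @param cell_radius_range `c(min, max)` radius in pixels.
#' @param baseline_intensity_range `c(min, max)` resting fluorescence per
#'   cell (arbitrary units on a 16-bit scale).
#' @param bleach_tau photobleaching time constant, seconds.
#' @param noise_sigma SD of additive Gaussian pixel noise.
#' @param transient_amplitude default peak response amplitude (dF/F).
#' @param transient_rise_tau,transient_decay_tau transient kinetics, seconds.
#' @param drift_per_frame rigid drift speed, pixels per frame (applied
#'   along the image diagonal).
#' @param tuning_classes list of classes, each a list with `label`,
#'   `fraction`, `response_prob` (named per stimulus label) and `amplitude`
#'   (scalar or named per stimulus label).  `NULL` uses the default
#'   population: a fraction `se_tuned_fraction` of cells responds to the
#'   sulfated-estrogen stimulus "SE", and those cells co-respond to estrus
#'   urine "EU" with probability 0.65 and to non-estrus urine "NEU" with
#'   probability 0.05; remaining cells respond to nothing (except a
#'   depolarizing control, see `depolarization_label`).
#' @param se_tuned_fraction fraction of cells tuned to the SE stimulus in
#'   the default population (control-slice default 0.10).
#' @param colabel_fraction fraction of cells positive for the second
#'   (co-label, e.g. tdTomato) channel.
#' @param hill_ec50,hill_coefficient Hill parameters scaling response
#'   amplitude with stimulus concentration (molar); applied only to events
#'   with a finite positive concentration.
#' @param min_separation_px extra clearance enforced between somata rims
#'   (somata form a monolayer and are drawn non-overlapping).
#' @param depolarization_label stimulus label treated as a depolarizing
#'   control (e.g. high-K+ Ringer): every cell responds to it with
#'   probability 1 at `transient_amplitude`, which makes the full viable
#'   population visible to activity-based ROI detection.
#' @param seed integer RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(image_shape = c(256L, 256L),
                       n_frames = NULL,
                       frame_interval = 0.5,
                       n_cells = 50L,
                       cell_radius_range = c(4, 7),
                       baseline_intensity_range = c(400, 1200),
                       bleach_tau = 600,
                       noise_sigma = 15,
                       transient_amplitude = 0.6,
                       transient_rise_tau = 1,
                       transient_decay_tau = 8,
                       drift_per_frame = 0,
                       tuning_classes = NULL,
                       se_tuned_fraction = 0.10,
                       colabel_fraction = 0.4,
                       hill_ec50 = 1e-8,
                       hill_coefficient = 1,
                       min_separation_px = 2,
                       depolarization_label = "KCl",
                       seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape),
              n_frames = if (is.null(n_frames)) NULL else as.integer(n_frames),
              frame_interval = frame_interval, n_cells = as.integer(n_cells),
              cell_radius_range = cell_radius_range,
              baseline_intensity_range = baseline_intensity_range,
              bleach_tau = bleach_tau, noise_sigma = noise_sigma,
              transient_amplitude = transient_amplitude,
              transient_rise_tau = transient_rise_tau,
              transient_decay_tau = transient_decay_tau,
              drift_per_frame = drift_per_frame,
              tuning_classes = tuning_classes,
              se_tuned_fraction = se_tuned_fraction,
              colabel_fraction = colabel_fraction,
              hill_ec50 = hill_ec50, hill_coefficient = hill_coefficient,
              min_separation_px = min_separation_px,
              depolarization_label = depolarization_label,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2L, all(cfg$image_shape >= 16L),
            cfg$frame_interval > 0, cfg$n_cells >= 1L,
            length(cfg$cell_radius_range) == 2L,
            all(cfg$cell_radius_range > 0),
            diff(cfg$cell_radius_range) >= 0,
            all(cfg$baseline_intensity_range > 0),
            cfg$bleach_tau > 0, cfg$noise_sigma >= 0,
            cfg$transient_rise_tau > 0, cfg$transient_decay_tau > 0,
            cfg$transient_decay_tau != cfg$transient_rise_tau,
            cfg$drift_per_frame >= 0,
            cfg$se_tuned_fraction >= 0, cfg$se_tuned_fraction <= 1,
            cfg$colabel_fraction >= 0, cfg$colabel_fraction <= 1,
            cfg$hill_ec50 > 0, cfg$hill_coefficient > 0)
  cls <- cfg$tuning_classes
  if (!is.null(cls)) {
    fr <- vapply(cls, function(cl) cl$fraction, numeric(1))
    if (any(fr < 0) || sum(fr) > 1 + 1e-9)
      stop("tuning class fractions must be non-negative and sum to <= 1")
  }
  invisible(cfg)
}

default_tuning_classes <- function(cfg) {
  list(list(label = "SE_tuned",
            fraction = cfg$se_tuned_fraction,
            response_prob = c(SE = 1, EU = 0.65, NEU = 0.05),
            amplitude = cfg$transient_amplitude))
}

# Difference-of-exponentials transient, normalized to unit peak; zero for
# t < 0.
transient_kernel <- function(t, rise_tau, decay_tau) {
  tp <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  k <- ifelse(t >= 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak, 0)
  pmax(k, 0)
}

hill_scale <- function(conc, ec50, h) {
  if (!is.finite(conc) || conc <= 0) return(1)
  conc^h / (conc^h + ec50^h)
}

#' Build a stimulus schedule from a configuration
#'
#' Events are laid out in delivery order with a fixed epoch duration and
#' inter-stimulus gap; the lead-in before the first onset defaults to half
#' a gap.  Onset frame indices are 1-based.
#'
#' @param config a [sim_config()].
#' @param stimuli data.frame with columns `label` and `concentration_M`
#'   (`NA` allowed), or a character vector of labels.
#' @param epoch_s stimulus epoch duration, seconds.
#' @param gap_s gap between offset and next onset, seconds; must be at
#'   least 5 transient decay time constants so responses die out between
#'   stimuli.
#' @param lead_in_s baseline recording before the first onset.
#' @return A [stim_schedule()].
#' @export
generate_stimulus_schedule <- function(config, stimuli,
                                       epoch_s = 10, gap_s = 120,
                                       lead_in_s = gap_s / 2) {
  if (length(stimuli) == 0L ||
      (is.data.frame(stimuli) && nrow(stimuli) == 0L))
    stop("`stimuli` must be a non-empty data.frame or character vector")
  if (is.character(stimuli))
    stimuli <- data.frame(label = stimuli, concentration_M = NA_real_)
  if (!is.data.frame(stimuli))
    stop("`stimuli` must be a non-empty data.frame or character vector")
  if (is.null(stimuli$concentration_M)) stimuli$concentration_M <- NA_real_
  if (gap_s < 5 * config$transient_decay_tau)
    stop("inter-stimulus gap must be >= 5 transient decay time constants")
  dt <- config$frame_interval
  n <- nrow(stimuli)
  onset_t <- lead_in_s + (seq_len(n) - 1L) * (epoch_s + gap_s)
  onset_frame <- as.integer(floor(onset_t / dt + 1e-9)) + 1L
  offset_frame <- onset_frame + as.integer(round(epoch_s / dt)) - 1L
  total_t <- lead_in_s + n * (epoch_s + gap_s)
  need_frames <- as.integer(ceiling(total_t / dt))
  nf <- config$n_frames %||% need_frames
  if (nf < max(offset_frame))
    stop("schedule is longer than the movie (configuration error)")
  stim_schedule(data.frame(label = as.character(stimuli$label),
                           concentration_M = stimuli$concentration_M,
                           onset_frame = onset_frame,
                           offset_frame = offset_frame),
                frame_interval = dt, n_frames = nf)
}

draw_cells <- function(cfg) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  n <- cfg$n_cells
  cy <- numeric(n); cx <- numeric(n); rad <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      r <- stats::runif(1, cfg$cell_radius_range[1], cfg$cell_radius_range[2])
      y <- stats::runif(1, 1, H); x <- stats::runif(1, 1, W)
      if (y - r < 1 || y + r > H || x - r < 1 || x + r > W) next
      if (i > 1L) {
        j <- seq_len(i - 1L)
        d2 <- (cy[j] - y)^2 + (cx[j] - x)^2
        if (any(d2 < (rad[j] + r + cfg$min_separation_px)^2)) next
      }
      cy[i] <- y; cx[i] <- x; rad[i] <- r
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place cell ", i,
                  " after 1000 draws; reduce n_cells or cell size")
  }
  b0 <- stats::runif(n, cfg$baseline_intensity_range[1],
                     cfg$baseline_intensity_range[2])
  list(centers = cbind(y = cy, x = cx), radii = rad, b0 = b0)
}

assign_classes <- function(cfg, n) {
  classes <- cfg$tuning_classes %||% default_tuning_classes(cfg)
  fr <- vapply(classes, function(cl) cl$fraction, numeric(1))
  labels <- vapply(classes, function(cl) cl$label, character(1))
  probs <- c(fr, max(0, 1 - sum(fr)))
  sample(c(labels, "none"), n, replace = TRUE, prob = probs)
}

# Bernoulli responder draws per (cell, stimulus label); one draw per label
# so a dose series of the same stimulus shares its responder identity.
draw_responders <- function(cfg, classes, class_of_cell, stim_labels) {
  n <- length(class_of_cell)
  resp <- matrix(FALSE, n, length(stim_labels),
                 dimnames = list(NULL, stim_labels))
  amp <- matrix(0, n, length(stim_labels),
                dimnames = list(NULL, stim_labels))
  by_label <- stats::setNames(classes,
                              vapply(classes, `[[`, character(1), "label"))
  for (s in stim_labels) {
    if (identical(s, cfg$depolarization_label)) {
      resp[, s] <- TRUE
      amp[, s] <- cfg$transient_amplitude
      next
    }
    for (i in seq_len(n)) {
      cl <- by_label[[class_of_cell[i]]]
      if (is.null(cl)) next
      p <- cl$response_prob[s]
      if (is.na(p) || p <= 0) next
      if (stats::runif(1) < p) {
        a <- if (length(cl$amplitude) > 1L) cl$amplitude[s] else cl$amplitude
        if (is.na(a)) a <- cfg$transient_amplitude
        resp[i, s] <- TRUE
        amp[i, s] <- a
      }
    }
  }
  list(responder = resp, amplitude = amp)
}

#' Generate a synthetic VNO-slice movie with ground truth
#'
#' Renders `signal(t) = sum_cells disk * B0 * exp(-t/bleach_tau) *
#' (1 + sum_events a * kernel(t - t_onset)) + N(0, noise_sigma)` with a
#' unit-peak difference-of-exponentials transient kernel, optional rigid
#' drift accumulating along the image diagonal, and per-event amplitudes
#' scaled by a Hill function of concentration.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param schedule a [stim_schedule()], e.g. from
#'   [generate_stimulus_schedule()].
#' @return list with elements `movie` (a [ca_movie()]) and `ground_truth`
#'   (class `ground_truth`: cell centers, radii, baseline intensities,
#'   tuning class per cell, per-event responder flags and amplitudes,
#'   co-label flags, and the config/schedule used).
#' @export
generate_slice_movie <- function(config, schedule) {
  validate_sim_config(config)
  set.seed(config$seed)
  H <- config$image_shape[1]; W <- config$image_shape[2]
  Tn <- attr(schedule, "n_frames")
  if (!isTRUE(all.equal(attr(schedule, "frame_interval"),
                        config$frame_interval)))
    stop("schedule frame_interval does not match config")
  cells <- draw_cells(config)
  class_of_cell <- assign_classes(config, config$n_cells)
  classes <- config$tuning_classes %||% default_tuning_classes(config)
  stim_labels <- unique(as.character(schedule$label))
  drawn <- draw_responders(config, classes, class_of_cell, stim_labels)
  colabel_positive <- stats::runif(config$n_cells) < config$colabel_fraction

  # per-event amplitude = per-label amplitude x Hill(concentration)
  n_ev <- nrow(schedule)
  ev_amp <- matrix(0, config$n_cells, n_ev)
  ev_resp <- matrix(FALSE, config$n_cells, n_ev)
  for (e in seq_len(n_ev)) {
    lab <- as.character(schedule$label[e])
    hs <- hill_scale(schedule$concentration_M[e],
                     config$hill_ec50, config$hill_coefficient)
    ev_resp[, e] <- drawn$responder[, lab]
    ev_amp[, e] <- drawn$amplitude[, lab] * hs * ev_resp[, e]
  }

  dt <- config$frame_interval
  tv <- (seq_len(Tn) - 1) * dt
  bleach <- exp(-tv / config$bleach_tau)
  kern <- matrix(0, Tn, n_ev)
  for (e in seq_len(n_ev)) {
    t_on <- (schedule$onset_frame[e] - 1) * dt
    kern[, e] <- transient_kernel(tv - t_on, config$transient_rise_tau,
                                  config$transient_decay_tau)
  }

  frames <- render_frames(config, cells, ev_amp, bleach, kern, H, W, Tn)
  if (config$noise_sigma > 0) {
    for (t in seq_len(Tn))
      frames[, , t] <- pmax(frames[, , t] +
                              stats::rnorm(H * W, 0, config$noise_sigma), 0)
  }

  gt <- structure(list(cell_centers = cells$centers,
                       cell_radii = cells$radii,
                       baseline_intensity = cells$b0,
                       class_of_cell = class_of_cell,
                       true_responder = ev_resp,
                       true_amplitude = ev_amp,
                       colabel_positive = colabel_positive,
                       config = config, schedule = schedule),
                  class = "ground_truth")
  list(movie = ca_movie(frames, dt), ground_truth = gt)
}

# Noise-free rendering; fast path when there is no drift (one mask per
# cell), per-frame stamping otherwise.
render_frames <- function(cfg, cells, ev_amp, bleach, kern, H, W, Tn) {
  n <- cfg$n_cells
  frames <- array(0, c(H, W, Tn))
  HW <- H * W
  if (cfg$drift_per_frame == 0) {
    for (i in seq_len(n)) {
      pix <- disk_pixels(cells$centers[i, 1], cells$centers[i, 2],
                         cells$radii[i], H, W)
      lin <- pix_linear(pix, H)
      trace <- cells$b0[i] * bleach *
        (1 + as.numeric(kern %*% ev_amp[i, ]))
      idx <- rep(lin, Tn) + rep((seq_len(Tn) - 1L) * HW, each = length(lin))
      frames[idx] <- frames[idx] + rep(trace, each = length(lin))
    }
  } else {
    step <- cfg$drift_per_frame / sqrt(2)     # equal y/x components
    traces <- matrix(0, n, Tn)
    for (i in seq_len(n))
      traces[i, ] <- cells$b0[i] * bleach *
        (1 + as.numeric(kern %*% ev_amp[i, ]))
    for (t in seq_len(Tn)) {
      off <- (t - 1) * step
      fr <- matrix(0, H, W)
      for (i in seq_len(n)) {
        pix <- disk_pixels(cells$centers[i, 1] + off,
                           cells$centers[i, 2] + off,
                           cells$radii[i], H, W)
        if (nrow(pix) == 0L) next
        lin <- pix_linear(pix, H)
        fr[lin] <- fr[lin] + traces[i, t]
      }
      frames[, , t] <- fr
    }
  }
  frames
}

#' Reconstruct the noise-free movie encoded by a ground-truth record
#'
#' Replays the forward model from recorded latents with noise off; with
#' `noise_sigma = 0` and no drift the generated movie equals this
#' reconstruction pixel for pixel.
#'
#' @param ground_truth as returned by [generate_slice_movie()].
#' @return A [ca_movie()].
#' @export
reconstruct_movie <- function(ground_truth) {
  gt <- ground_truth
  cfg <- gt$config
  schedule <- gt$schedule
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  Tn <- attr(schedule, "n_frames")
  dt <- cfg$frame_interval
  tv <- (seq_len(Tn) - 1) * dt
  bleach <- exp(-tv / cfg$bleach_tau)
  n_ev <- nrow(schedule)
  kern <- matrix(0, Tn, n_ev)
  for (e in seq_len(n_ev)) {
    t_on <- (schedule$onset_frame[e] - 1) * dt
    kern[, e] <- transient_kernel(tv - t_on, cfg$transient_rise_tau,
                                  cfg$transient_decay_tau)
  }
  cells <- list(centers = gt$cell_centers, radii = gt$cell_radii,
                b0 = gt$baseline_intensity)
  frames <- render_frames(cfg, cells, gt$true_amplitude, bleach, kern,
                          H, W, Tn)
  ca_movie(frames, dt)
}

#' Render the co-label (second channel) still image
#'
#' Co-label-positive cells are drawn as bright disks (intensity 800) on a
#' dark background with the configured additive noise.
#'
#' @param ground_truth as returned by [generate_slice_movie()].
#' @param label_intensity fluorescence of labeled somata.
#' @return An `H x W` numeric matrix.
#' @export
generate_colabel_image <- function(ground_truth, label_intensity = 800) {
  cfg <- ground_truth$config
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  img <- matrix(0, H, W)
  pos <- which(ground_truth$colabel_positive)
  for (i in pos) {
    pix <- disk_pixels(ground_truth$cell_centers[i, 1],
                       ground_truth$cell_centers[i, 2],
                       ground_truth$cell_radii[i], H, W)
    img[pix_linear(pix, H)] <- label_intensity
  }
  if (cfg$noise_sigma > 0)
    img <- pmax(img + stats::rnorm(H * W, 0, cfg$noise_sigma), 0)
  img
}

#' Behavior-assay simulation configuration
#'
#' @param groups data.frame with columns `group`, `n_animals`,
#'   `mount_rate` (expected mounts per session), `mean_duration_s` and
#'   `session_length_s`.
#' @param seed integer RNG seed.
#' @return An object of class `behavior_config`.
#' @export
behavior_config <- function(groups, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n_animals", "mount_rate", "mean_duration_s",
                  "session_length_s") %in% names(groups)),
            all(groups$mount_rate >= 0), all(groups$session_length_s > 0),
            all(groups$mean_duration_s > 0), all(groups$n_animals >= 1))
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "behavior_config")
}

#' Simulate a mount-event table
#'
#' Per animal the mount count is Poisson with the group rate, start times
#' are uniform over the session, durations are exponential with the group
#' mean (truncated at session end) and overlapping events are redrawn.
#'
#' @param config a [behavior_config()].
#' @return data.frame (`animal_id`, `group`, `event_start_s`,
#'   `event_end_s`) with attributes `animals` (roster data.frame, so
#'   zero-mount animals are kept) and `session_length` (named per group).
#' @export
generate_behavior_table <- function(config) {
  set.seed(config$seed)
  rows <- list(); roster <- list(); aid <- 0L
  for (g in seq_len(nrow(config$groups))) {
    gr <- config$groups[g, ]
    for (a in seq_len(gr$n_animals)) {
      aid <- aid + 1L
      id <- sprintf("%s_%02d", gr$group, a)
      roster[[aid]] <- data.frame(animal_id = id, group = gr$group,
                                  session_length_s = gr$session_length_s)
      n <- stats::rpois(1, gr$mount_rate)
      if (n == 0L) next
      ev <- draw_nonoverlapping_events(n, gr$session_length_s,
                                       gr$mean_duration_s)
      rows[[length(rows) + 1L]] <-
        data.frame(animal_id = id, group = gr$group,
                   event_start_s = ev$start, event_end_s = ev$end)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(), group = character(),
               event_start_s = numeric(), event_end_s = numeric())
  rownames(out) <- NULL
  structure(out, animals = do.call(rbind, roster))
}

draw_nonoverlapping_events <- function(n, session_len, mean_dur) {
  for (attempt in seq_len(1000L)) {
    start <- sort(stats::runif(n, 0, session_len))
    dur <- stats::rexp(n, 1 / mean_dur)
    end <- pmin(start + dur, session_len)
    if (n == 1L || all(start[-1L] >= end[-n])) {
      return(list(start = start, end = end))
    }
  }
  stop("could not draw non-overlapping mount events after 1000 attempts")
}
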