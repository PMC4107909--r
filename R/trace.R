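# From a global ROI's raw temporal profile to a photobleaching-corrected
# dF/F response call per stimulus.
#
# F is modeled in two parts: a baseline fit (exponential photobleaching
# with linear and constant fallbacks) over frames outside response
# windows, and a peak found on a lightly smoothed trace inside the
# response window.  dF = peak - baseline(peak time); a cell is a responder
# when dF/F >= 0.30.

#' Extract the raw temporal profile of an ROI
#'
#' @param movie a [ca_movie()].
#' @param roi an ROI (list with a `pixels` matrix).
#' @param roi_id identifier carried on the trace.
#' @return An object of class `ca_trace`: `values`, `frame_interval`,
#'   `roi_id`.
#' @export
extract_trace <- function(movie, roi, roi_id = "roi") {
  if (is.null(roi$pixels) || nrow(roi$pixels) == 0L)
    stop("empty ROI")
  d <- dim(movie$frames)
  if (any(roi$pixels[, 1L] > d[1]) || any(roi$pixels[, 2L] > d[2]) ||
      any(roi$pixels < 1L))
    stop("ROI pixels outside the movie frame")
  lin <- pix_linear(roi$pixels, d[1])
  HW <- d[1] * d[2]
  Tn <- d[3]
  idx <- rep(lin, Tn) + rep((seq_len(Tn) - 1L) * HW, each = length(lin))
  vals <- colMeans(matrix(movie$frames[idx], length(lin), Tn))
  structure(list(values = vals, frame_interval = movie$frame_interval,
                 roi_id = roi_id), class = "ca_trace")
}

response_window_frames <- function(schedule_or_event, response_window_s,
                                   frame_interval, n_frames) {
  on <- schedule_or_event$onset_frame
  w <- round(response_window_s / frame_interval)
  unlist(lapply(on, function(o) seq.int(o, min(o + w, n_frames))))
}

#' Fit a photobleaching baseline to a trace
#'
#' Least-squares fit of `B0 * exp(-t / tau)` to the frames outside all
#' response windows (event onset to onset + `response_window_s`).  If the
#' exponential fit fails to converge, gives a non-positive or absurd tau
#' (more than 100 trace durations), the fit falls back to a linear trend,
#' and then to a constant (the median); `model_kind` records the level
#' used.
#'
#' @param trace a [extract_trace()] result (or list with `values` and
#'   `frame_interval`).
#' @param schedule a [stim_schedule()] whose events define the masked
#'   response windows.
#' @param response_window_s seconds after onset excluded from the fit.
#' @return An object of class `baseline_model`: `model_kind`
#'   ("exponential", "linear" or "constant"), `parameters`, `fitted_on`
#'   (frame indices used).
#' @export
fit_baseline <- function(trace, schedule, response_window_s = 60) {
  v <- trace$values
  Tn <- length(v)
  dt <- trace$frame_interval
  masked <- unique(response_window_frames(schedule, response_window_s,
                                          dt, Tn))
  keep <- setdiff(seq_len(Tn), masked)
  if (length(keep) < 10L)
    stop("fewer than 10 frames outside response windows")
  tt <- (keep - 1) * dt
  y <- v[keep]
  dur <- Tn * dt

  if (stats::sd(y) == 0) {
    model <- list(model_kind = "constant",
                  parameters = c(level = y[1]),
                  fitted_on = keep, frame_interval = dt)
    return(structure(model, class = "baseline_model"))
  }
  model <- NULL
  if (all(y > 0)) {
    lf <- stats::lm.fit(cbind(1, tt), log(y))
    tau0 <- -1 / lf$coefficients[2]
    start <- list(B0 = exp(lf$coefficients[1]),
                  tau = if (is.finite(tau0) && tau0 > 0) tau0 else dur)
    # warnOnly + suppressWarnings: noiseless traces hit the zero-residual
    # convergence quirk of nls; the parameters are validated below anyway
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ B0 * exp(-tt / tau), start = start,
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      if (is.finite(p["tau"]) && p["tau"] > 0 && p["tau"] <= 100 * dur &&
          p["B0"] > 0)
        model <- list(model_kind = "exponential",
                      parameters = c(B0 = unname(p["B0"]),
                                     tau = unname(p["tau"])))
    }
  }
  if (is.null(model)) {
    lf <- stats::lm.fit(cbind(1, tt), y)
    co <- lf$coefficients
    pred <- co[1] + co[2] * (seq_len(Tn) - 1) * dt
    if (all(pred > 0))
      model <- list(model_kind = "linear",
                    parameters = c(intercept = unname(co[1]),
                                   slope = unname(co[2])))
  }
  if (is.null(model))
    model <- list(model_kind = "constant",
                  parameters = c(level = stats::median(y)))
  model$fitted_on <- keep
  model$frame_interval <- dt
  structure(model, class = "baseline_model")
}

#' Evaluate a baseline model at given frames
#'
#' @param model a [fit_baseline()] result.
#' @param frames integer frame indices (1-based).
#' @return Numeric baseline predictions.
#' @export
predict_baseline <- function(model, frames) {
  tt <- (frames - 1) * model$frame_interval
  p <- model$parameters
  switch(model$model_kind,
         exponential = p["B0"] * exp(-tt / p["tau"]),
         linear = p["intercept"] + p["slope"] * tt,
         constant = rep(p["level"], length(tt)),
         stop("unknown baseline model kind")) |> unname()
}

#' Locate the response peak inside an event window
#'
#' The peak is the maximum of a 3-frame moving average of the trace over
#' `[onset, onset + response_window_s]`; its center frame is reported.
#' Smoothing suppresses single-frame noise maxima.
#'
#' @param trace a [extract_trace()] result.
#' @param event schedule row as a list (`onset_frame` needed).
#' @param response_window_s search window after onset, seconds.
#' @return list `peak_value`, `peak_frame`.
#' @export
detect_peak <- function(trace, event, response_window_s = 60) {
  v <- trace$values
  Tn <- length(v)
  on <- event$onset_frame
  w <- round(response_window_s / trace$frame_interval)
  hi <- min(on + w, Tn)
  if (hi - on + 1L < 3L) stop("response window shorter than 3 frames")
  sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)   # centered 3-frame MA
  sm[1] <- mean(v[1:2]); sm[Tn] <- mean(v[(Tn - 1):Tn])
  win <- seq.int(on, hi)
  pk <- win[which.max(sm[win])]
  list(peak_value = as.numeric(sm[pk]), peak_frame = pk)
}

#' Call a stimulus response for one ROI
#'
#' `dF/F = (peak - baseline(peak frame)) / baseline(peak frame)`; the ROI
#' is a responder when `dF/F` is at or above `response_threshold`
#' (inclusive, default 0.30).
#'
#' @param trace a [extract_trace()] result.
#' @param baseline a [fit_baseline()] result.
#' @param event schedule row as a list (`label`, `concentration_M`,
#'   `onset_frame`).
#' @param response_window_s peak search window, seconds.
#' @param response_threshold responder threshold on dF/F.
#' @return One-row data.frame: `roi_id`, `stimulus`, `concentration_M`,
#'   `baseline_at_peak`, `peak_value`, `peak_frame`, `dff`, `responder`.
#' @export
call_response <- function(trace, baseline, event,
                          response_window_s = 60,
                          response_threshold = 0.30) {
  pk <- detect_peak(trace, event, response_window_s)
  b <- predict_baseline(baseline, pk$peak_frame)
  if (!is.finite(b) || b <= 0)
    stop("baseline at peak is not positive (invariant breach)")
  dff <- (pk$peak_value - b) / b
  data.frame(roi_id = trace$roi_id,
             stimulus = as.character(event$label),
             concentration_M = as.numeric(event$concentration_M %||% NA),
             baseline_at_peak = b,
             peak_value = pk$peak_value,
             peak_frame = pk$peak_frame,
             dff = dff,
             responder = dff >= response_threshold)
}
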