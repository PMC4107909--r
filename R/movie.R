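# Containers for time-lapse fluorescence movies and stimulus schedules.

#' Construct a calcium-imaging movie
#'
#' A movie is a `H x W x T` numeric array of fluorescence values plus the
#' acquisition frame interval in seconds.  Frames are indexed 1..T and frame
#' `t` was acquired at time `(t - 1) * frame_interval` seconds.
#'
#' @param frames numeric array with `dim = c(H, W, T)`; finite, non-negative.
#' @param frame_interval seconds between consecutive frames (> 0).
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, frame_interval) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-d array (H x W x T)")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_movie> %d x %d pixels, %d frames @ %.3g s/frame (%.1f s)\n",
              d[1], d[2], d[3], x$frame_interval, d[3] * x$frame_interval))
  invisible(x)
}

#' @export
dim.ca_movie <- function(x) dim(x$frames)

n_frames <- function(movie) dim(movie$frames)[3]

#' Construct a stimulus schedule
#'
#' An ordered table of stimulus delivery events for one movie.  Frame indices
#' are 1-based and inclusive on both ends.
#'
#' @param events data.frame with columns `label` (character),
#'   `concentration_M` (molar; `NA` for undiluted/categorical stimuli such as
#'   urine or a depolarizing control), `onset_frame`, `offset_frame`.
#' @param frame_interval seconds per frame.
#' @param n_frames total frames in the movie the schedule belongs to.
#' @return An object of class `stim_schedule` (a data.frame with attributes).
#' @export
stim_schedule <- function(events, frame_interval, n_frames) {
  stopifnot(is.data.frame(events),
            all(c("label", "concentration_M", "onset_frame",
                  "offset_frame") %in% names(events)))
  if (nrow(events) == 0L) stop("schedule must contain at least one event")
  ev <- events[order(events$onset_frame), , drop = FALSE]
  if (any(ev$onset_frame < 1L) || any(ev$offset_frame > n_frames))
    stop("schedule events fall outside the movie (configuration error)")
  if (any(ev$offset_frame < ev$onset_frame))
    stop("event offset precedes onset")
  if (nrow(ev) > 1L &&
      any(ev$onset_frame[-1L] <= ev$offset_frame[-nrow(ev)]))
    stop("schedule events overlap")
  rownames(ev) <- NULL
  structure(ev, class = c("stim_schedule", "data.frame"),
            frame_interval = frame_interval, n_frames = n_frames)
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d events, %d frames @ %.3g s/frame\n",
              nrow(x), attr(x, "n_frames"), attr(x, "frame_interval")))
  print.data.frame(x, ...)
  invisible(x)
}

schedule_event <- function(schedule, i) {
  ev <- as.list(schedule[i, , drop = FALSE])
  ev$frame_interval <- attr(schedule, "frame_interval")
  ev
}

#' Write / read a stimulus schedule as JSON
#'
#' @param schedule a [stim_schedule()].
#' @param path file path.
#' @return `read_schedule_json` returns a [stim_schedule()].
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- list(frame_interval = attr(schedule, "frame_interval"),
              n_frames = attr(schedule, "n_frames"),
              events = as.data.frame(schedule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(obj$events)
  if (is.null(ev$concentration_M)) ev$concentration_M <- NA_real_
  ev$concentration_M <- as.numeric(ev$concentration_M)
  stim_schedule(ev, obj$frame_interval, obj$n_frames)
}
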