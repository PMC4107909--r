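# Rigid translational registration of a movie to its first frame by
# FFT cross-correlation, integer-pixel shifts only.

#' Register movie frames to the first frame
#'
#' Each frame is translated by the integer-pixel shift that maximizes its
#' cross-correlation with frame 1 (the reference).  Pixels exposed by the
#' translation are filled with the frame median.  The search is bounded to
#' +/- `max_shift_frac` of the image size to prevent pathological matches.
#'
#' @param movie a [ca_movie()] with at least 2 frames.
#' @param max_shift_frac maximum shift searched, as a fraction of the
#'   smaller image dimension.
#' @return list with `movie` (registered copy) and `shifts`, a data.frame
#'   (`frame`, `dy`, `dx`) of the detected displacement of each frame
#'   relative to frame 1 (the applied correction is its negation).  An
#'   attribute `flat_frames` flags all-constant frames, whose correlation
#'   is undefined and whose shift is reported as (0, 0).
#' @export
register_frames <- function(movie, max_shift_frac = 0.1) {
  fr <- movie$frames
  d <- dim(fr)
  if (d[3] < 2L) stop("registration needs at least 2 frames")
  H <- d[1]; W <- d[2]; Tn <- d[3]
  max_dy <- max(1L, floor(min(H, W) * max_shift_frac))
  ref <- fr[, , 1L]
  ref_c <- ref - mean(ref)
  Fref <- stats::fft(ref_c)
  dy <- integer(Tn); dx <- integer(Tn)
  flat <- logical(Tn)
  flat[1] <- stats::sd(ref) == 0
  out <- fr
  for (t in 2:Tn) {
    f <- fr[, , t]
    if (stats::sd(f) == 0) {
      flat[t] <- TRUE
      next
    }
    s <- cc_peak_shift(Fref, f - mean(f), H, W, max_dy)
    dy[t] <- s[1]; dx[t] <- s[2]
    if (s[1] != 0L || s[2] != 0L)
      out[, , t] <- translate_frame(f, -s[1], -s[2], stats::median(f))
  }
  if (any(flat))
    warning("all-constant frame(s): ", paste(which(flat), collapse = ", "),
            "; shift undefined, reported as (0, 0)")
  shifts <- data.frame(frame = seq_len(Tn), dy = dy, dx = dx)
  attr(shifts, "flat_frames") <- which(flat)
  list(movie = ca_movie(out, movie$frame_interval), shifts = shifts)
}

# Displacement (dy, dx) of frame `g` relative to the reference whose FFT is
# `Fref`: argmax of the circular cross-correlation, restricted to
# +/- max_dy.  A frame equal to the reference rolled down-right by (a, b)
# yields (a, b).
cc_peak_shift <- function(Fref, g, H, W, max_dy) {
  cc <- Re(stats::fft(Conj(Fref) * stats::fft(g), inverse = TRUE))
  allowed <- c(0:max_dy, (H - max_dy):(H - 1))
  allowed_c <- c(0:max_dy, (W - max_dy):(W - 1))
  sub <- cc[allowed + 1L, allowed_c + 1L, drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  dy <- allowed[pk[1]]
  dx <- allowed_c[pk[2]]
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(as.integer(dy), as.integer(dx))
}

#' Write frame shifts to CSV
#'
#' @param shifts data.frame from [register_frames()].
#' @param path file path.
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(shifts, path, row.names = FALSE)
  invisible(path)
}
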