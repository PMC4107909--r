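# Per-stimulus (local) ROI detection by a pixelwise signal-to-noise
# criterion, shape-based candidate filtering, and integration of local
# sets into one global ROI list.

#' ROI detection parameters
#'
#' @param snr_threshold pixel score needed to enter a candidate ROI.
#' @param min_area,max_area candidate area gates, pixels.
#' @param min_circularity isoperimetric circularity gate in `[0, 1]`.
#' @param iou_merge_threshold intersection-over-union at or above which
#'   local ROIs from different stimuli are merged into one global ROI.
#' @param baseline_window_s length of the pre-event window used for the
#'   baseline mean and robust noise estimate, seconds.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(snr_threshold = 5,
                             min_area = 10L, max_area = 400L,
                             min_circularity = 0.5,
                             iou_merge_threshold = 0.3,
                             baseline_window_s = 30) {
  stopifnot(snr_threshold > 0, min_area > 0, max_area > min_area,
            min_circularity >= 0, min_circularity <= 1,
            iou_merge_threshold >= 0, iou_merge_threshold <= 1,
            baseline_window_s > 0)
  structure(list(snr_threshold = snr_threshold,
                 min_area = as.integer(min_area),
                 max_area = as.integer(max_area),
                 min_circularity = min_circularity,
                 iou_merge_threshold = iou_merge_threshold,
                 baseline_window_s = baseline_window_s),
            class = "detection_params")
}

new_roi <- function(pix, source_stimulus) {
  list(pixels = pix,
       centroid = c(y = mean(pix[, 1L]), x = mean(pix[, 2L])),
       area = nrow(pix),
       source_stimulus = source_stimulus)
}

#' Detect local (per-stimulus) ROI candidates
#'
#' For every pixel the score is `(mean over the event window - mean over
#' the pre-event baseline window) / robust SD of the pre-event residuals`,
#' where residuals are taken about a per-pixel linear trend of the
#' baseline window (so slow photobleaching does not inflate the noise
#' estimate) and the robust SD is `1.4826 * median(|residual|)`.  Pixels
#' scoring at or above `snr_threshold` are thresholded and 8-connected
#' components become candidate ROIs.
#'
#' @param movie a registered [ca_movie()].
#' @param event one row of a [stim_schedule()] as a list (see
#'   [generate_stimulus_schedule()]), or a list with `label`,
#'   `onset_frame`, `offset_frame`.
#' @param params a [detection_params()].
#' @return list of ROIs (each: `pixels`, `centroid`, `area`,
#'   `source_stimulus`).
#' @export
detect_local_rois <- function(movie, event, params = detection_params()) {
  fr <- movie$frames
  d <- dim(fr)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  on <- event$onset_frame; off <- event$offset_frame
  if (is.null(on) || is.null(off) || off > Tn || on < 1L)
    stop("event window outside the movie")
  if (off - on + 1L < 3L) stop("event window shorter than 3 frames")
  nb <- max(3L, round(params$baseline_window_s / movie$frame_interval))
  b0 <- max(1L, on - nb); b1 <- on - 1L
  if (b1 < b0 + 2L) stop("fewer than 3 pre-event baseline frames")
  base_fr <- seq.int(b0, b1)
  ev_fr <- seq.int(on, off)

  HW <- H * W
  # only the two windows are materialized, never the whole movie
  Yb <- t(matrix(fr[, , base_fr], HW, length(base_fr)))  # frames x pixels
  acc <- matrix(0, H, W)
  for (t in ev_fr) acc <- acc + fr[, , t]
  Ye_mean <- as.numeric(acc) / length(ev_fr)
  Yb_mean <- colMeans(Yb)

  # per-pixel linear detrend of the baseline window, vectorized
  tt <- seq_along(base_fr)
  X <- cbind(1, tt)
  beta <- solve(crossprod(X), crossprod(X, Yb))
  resid <- Yb - X %*% beta
  mad_px <- 1.4826 * col_medians(abs(resid))
  mad_px <- pmax(mad_px, 1e-6)

  score <- (Ye_mean - Yb_mean) / mad_px
  mask <- matrix(score >= params$snr_threshold, H, W)
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  comp <- split(idx, lab[idx])
  lapply(comp, function(lin) {
    pix <- cbind(row = ((lin - 1L) %% H) + 1L,
                 col = ((lin - 1L) %/% H) + 1L)
    new_roi(pix, as.character(event$label))
  })
}

#' Filter ROI candidates by area and circularity
#'
#' An automated surrogate for manual candidate inspection: keeps ROIs with
#' `min_area <= area <= max_area` and isoperimetric circularity
#' `4*pi*A/P^2 >= min_circularity`, with the perimeter estimated from the
#' 4-connected boundary edge count corrected by `pi/4` (so an ideal disk
#' scores ~1).
#'
#' @param rois list of ROIs.
#' @param params a [detection_params()].
#' @return Filtered list of ROIs.
#' @export
filter_candidates <- function(rois, params = detection_params()) {
  if (length(rois) == 0L) return(rois)
  keep <- vapply(rois, function(r) {
    if (r$area < params$min_area || r$area > params$max_area) return(FALSE)
    H <- max(r$pixels[, 1L]); W <- max(r$pixels[, 2L])
    pixel_circularity(r$pixels, H, W) >= params$min_circularity
  }, logical(1))
  rois[keep]
}

roi_iou <- function(a, b, H) {
  la <- pix_linear(a$pixels, H)
  lb <- pix_linear(b$pixels, H)
  inter <- length(intersect(la, lb))
  if (inter == 0L) return(0)
  inter / (length(la) + length(lb) - inter)
}

#' Integrate local ROI sets into a global ROI list
#'
#' ROIs (across all stimuli) whose pairwise IoU is at or above
#' `iou_merge_threshold` are unioned under transitive closure; each global
#' ROI records the stimuli that contributed to it.
#'
#' @param local_sets list of lists of ROIs (one element per stimulus), or
#'   one flat list of ROIs.
#' @param params a [detection_params()].
#' @param image_shape `c(H, W)`; taken from pixel extents when omitted.
#' @return list of global ROIs; each has `source_stimulus = "global"` and
#'   a `sources` character vector of contributing stimulus labels.
#' @export
merge_to_global <- function(local_sets, params = detection_params(),
                            image_shape = NULL) {
  rois <- if (length(local_sets) && is.list(local_sets[[1]]) &&
              !is.null(local_sets[[1]]$pixels)) local_sets
          else do.call(c, local_sets)
  n <- length(rois)
  if (n == 0L) return(list())
  H <- if (is.null(image_shape))
    max(vapply(rois, function(r) max(r$pixels[, 1L]), numeric(1)))
  else image_shape[1]

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (roi_iou(rois[[i]], rois[[j]], H) >= params$iou_merge_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  out <- lapply(groups, function(g) {
    pix <- unique(do.call(rbind, lapply(rois[g], `[[`, "pixels")))
    r <- new_roi(pix, "global")
    r$sources <- sort(unique(vapply(rois[g], `[[`, character(1),
                                    "source_stimulus")))
    r
  })
  names(out) <- NULL
  out
}

#' Serialize ROIs to JSON (run-length encoded) and to CSV
#'
#' The JSON stores each ROI's pixel set as per-column runs
#' (`col`, `row_start`, `row_end`); the CSV is an ImageJ-style summary
#' (`label`, `centroid_y`, `centroid_x`, `area`).
#'
#' @param rois list of ROIs.
#' @param path output file.
#' @return `read_rois_json` returns a list of ROIs.
#' @export
write_rois_json <- function(rois, path) {
  enc <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    pix <- r$pixels[order(r$pixels[, 2L], r$pixels[, 1L]), , drop = FALSE]
    runs <- list()
    j <- 1L
    while (j <= nrow(pix)) {
      col <- pix[j, 2L]; start <- pix[j, 1L]; end <- start
      while (j < nrow(pix) && pix[j + 1L, 2L] == col &&
             pix[j + 1L, 1L] == end + 1L) { j <- j + 1L; end <- end + 1L }
      runs[[length(runs) + 1L]] <- c(col, start, end)
      j <- j + 1L
    }
    list(label = sprintf("roi_%03d", i),
         source_stimulus = r$source_stimulus,
         sources = r$sources %||% r$source_stimulus,
         runs = do.call(rbind, runs))
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(enc)), function(i) {
    runs <- enc$runs[[i]]
    if (is.null(dim(runs))) runs <- matrix(runs, ncol = 3)
    pix <- do.call(rbind, lapply(seq_len(nrow(runs)), function(k)
      cbind(row = runs[k, 2]:runs[k, 3], col = runs[k, 1])))
    r <- new_roi(pix, enc$source_stimulus[i])
    r$sources <- enc$sources[[i]]
    r
  })
}

#' @rdname write_rois_json
#' @export
write_rois_csv <- function(rois, path) {
  df <- data.frame(label = sprintf("roi_%03d", seq_along(rois)),
                   centroid_y = vapply(rois, function(r) r$centroid[1],
                                       numeric(1)),
                   centroid_x = vapply(rois, function(r) r$centroid[2],
                                       numeric(1)),
                   area = vapply(rois, function(r) r$area, numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
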