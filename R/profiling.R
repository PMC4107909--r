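# Population summaries over the ROI x stimulus response matrix:
# stimulus-overlap (Venn) statistics, percent responding with optional
# co-label gating, normalized tuning panels and dose-response curves.

#' Build a response matrix for one movie
#'
#' Extracts each global ROI's trace, fits its photobleaching baseline and
#' calls a response for every scheduled event.
#'
#' @param movie a registered [ca_movie()].
#' @param rois list of global ROIs (see [merge_to_global()]).
#' @param schedule a [stim_schedule()].
#' @param response_window_s peak-search / baseline-mask window, seconds.
#' @param response_threshold responder threshold on dF/F.
#' @param slice_id identifier prefixed to ROI ids so matrices from several
#'   slices can be pooled.
#' @return A `response_matrix`: a tidy data.frame with one row per
#'   (ROI, event) holding the [call_response()] fields plus `slice_id`.
#' @export
build_response_matrix <- function(movie, rois, schedule,
                                  response_window_s = 60,
                                  response_threshold = 0.30,
                                  slice_id = "slice1") {
  calls <- vector("list", length(rois) * nrow(schedule))
  k <- 0L
  for (i in seq_along(rois)) {
    id <- sprintf("%s_roi_%03d", slice_id, i)
    tr <- extract_trace(movie, rois[[i]], roi_id = id)
    bl <- fit_baseline(tr, schedule, response_window_s)
    for (e in seq_len(nrow(schedule))) {
      k <- k + 1L
      calls[[k]] <- call_response(tr, bl, schedule_event(schedule, e),
                                  response_window_s, response_threshold)
    }
  }
  out <- if (k > 0L) do.call(rbind, calls[seq_len(k)]) else
    data.frame(roi_id = character(), stimulus = character(),
               concentration_M = numeric(), baseline_at_peak = numeric(),
               peak_value = numeric(), peak_frame = integer(),
               dff = numeric(), responder = logical())
  out$slice_id <- slice_id
  class(out) <- c("response_matrix", "data.frame")
  out
}

#' Pool response matrices from several slices
#'
#' @param ... `response_matrix` objects (or a single list of them).
#' @return A pooled `response_matrix`.
#' @export
pool_response_matrices <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && !inherits(mats[[1]], "data.frame"))
    mats <- mats[[1]]
  out <- do.call(rbind, lapply(mats, as.data.frame))
  class(out) <- c("response_matrix", "data.frame")
  out
}

responder_ids <- function(matrix, labels) {
  m <- as.data.frame(matrix)
  unique(m$roi_id[m$stimulus %in% labels & m$responder])
}

#' Overlap (Venn) summary between two stimulus sets
#'
#' A cell belongs to set A when it is a responder to any member of
#' `stim_A` (any-responder semantics for multi-sample stimulus classes),
#' and likewise for B.  Reports `n_A`, `n_B`, `n_AB` and
#' `pct_B_given_A = 100 * n_AB / n_A`.
#'
#' @param matrix a `response_matrix`.
#' @param stim_A,stim_B character vectors of stimulus labels.
#' @return An object of class `venn_summary`; `pct_B_given_A` is `NA`
#'   (flagged `undefined = TRUE`) when `n_A = 0`.
#' @export
overlap_summary <- function(matrix, stim_A, stim_B) {
  m <- as.data.frame(matrix)
  present <- unique(m$stimulus)
  missing <- setdiff(c(stim_A, stim_B), present)
  if (length(missing))
    stop("stimuli absent from the response matrix: ",
         paste(missing, collapse = ", "))
  a <- responder_ids(m, stim_A)
  b <- responder_ids(m, stim_B)
  n_ab <- length(intersect(a, b))
  structure(list(n_A = length(a), n_B = length(b), n_AB = n_ab,
                 pct_B_given_A = if (length(a) > 0)
                   100 * n_ab / length(a) else NA_real_,
                 undefined = length(a) == 0L,
                 stim_A = stim_A, stim_B = stim_B),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> A={%s} n=%d; B={%s} n=%d; overlap %d",
              paste(x$stim_A, collapse = ","), x$n_A,
              paste(x$stim_B, collapse = ","), x$n_B, x$n_AB))
  if (x$undefined) cat("; pct(B|A) undefined (n_A = 0)\n")
  else cat(sprintf("; pct(B|A) = %.1f%%\n", x$pct_B_given_A))
  invisible(x)
}

#' 2x2 responder contingency table for two stimulus sets
#'
#' @inheritParams overlap_summary
#' @return A 2x2 integer table (responder A x responder B) over all ROIs.
#' @export
overlap_table <- function(matrix, stim_A, stim_B) {
  m <- as.data.frame(matrix)
  ids <- unique(m$roi_id)
  a <- ids %in% responder_ids(m, stim_A)
  b <- ids %in% responder_ids(m, stim_B)
  table(responder_A = factor(a, c(TRUE, FALSE)),
        responder_B = factor(b, c(TRUE, FALSE)))
}

#' Percent of cells responding to a stimulus
#'
#' @param matrix a `response_matrix`.
#' @param stim stimulus label (or vector; any-responder semantics).
#' @param denominator `"all_rois"` or `"colabel_positive"`.
#' @param colabel_mask named logical vector (names = roi ids) from
#'   [colabel_gate()]; required when `denominator = "colabel_positive"`.
#' @return list `percent`, `n_responding`, `n_denominator`.
#' @export
percent_responding <- function(matrix, stim,
                               denominator = c("all_rois",
                                               "colabel_positive"),
                               colabel_mask = NULL) {
  denominator <- match.arg(denominator)
  m <- as.data.frame(matrix)
  ids <- unique(m$roi_id)
  if (denominator == "colabel_positive") {
    if (is.null(colabel_mask)) stop("colabel_mask required")
    ids <- ids[ids %in% names(colabel_mask)[colabel_mask]]
  }
  if (length(ids) == 0L) stop("empty denominator")
  resp <- intersect(responder_ids(m, stim), ids)
  list(percent = 100 * length(resp) / length(ids),
       n_responding = length(resp), n_denominator = length(ids))
}

#' Normalized tuning panel (mean +/- SEM of per-cell-max-normalized dF/F)
#'
#' Each cell's dF/F vector over the panel is divided by its own maximum,
#' making tuning profiles comparable across cells and bounded by 1; cells
#' whose maximum is not positive are excluded and counted.
#'
#' @param matrix a `response_matrix`.
#' @param panel character vector of stimulus labels; every included cell
#'   must have a call for each.
#' @return list with `summary` (data.frame: `stimulus`, `mean_norm_dff`,
#'   `sem_norm_dff`, `n_cells`) and `n_excluded`.
#' @export
normalized_amplitudes <- function(matrix, panel) {
  if (length(panel) == 0L) stop("empty stimulus panel")
  m <- as.data.frame(matrix)
  m <- m[m$stimulus %in% panel, c("roi_id", "stimulus", "dff")]
  wide <- stats::reshape(m, idvar = "roi_id", timevar = "stimulus",
                         direction = "wide")
  cols <- paste0("dff.", panel)
  if (!all(cols %in% names(wide)))
    stop("panel stimuli absent from the response matrix")
  complete <- stats::complete.cases(wide[, cols, drop = FALSE])
  wide <- wide[complete, , drop = FALSE]
  vals <- as.matrix(wide[, cols, drop = FALSE])
  mx <- apply(vals, 1L, max)
  excl <- mx <= 0
  vals <- vals[!excl, , drop = FALSE] / mx[!excl]
  n <- nrow(vals)
  summary <- data.frame(stimulus = panel,
                        mean_norm_dff = if (n) colMeans(vals) else NA_real_,
                        sem_norm_dff = if (n > 1)
                          apply(vals, 2L, stats::sd) / sqrt(n) else NA_real_,
                        n_cells = n, row.names = NULL)
  if (n == 0L) summary <- summary[0, ]
  list(summary = summary, n_excluded = sum(excl))
}

#' Dose-response curve for one stimulus over a cell set
#'
#' Per concentration: the fraction of the cell set called responding and
#' their mean dF/F.  The threshold concentration is the lowest tested
#' concentration with at least one responder ("as low as" semantics);
#' alternatively the lowest with at least `min_fraction` responding.  A
#' Hill curve `ymax * c^h / (c^h + EC50^h)` is least-squares fitted to the
#' mean dF/F when at least 2 concentrations are available.
#'
#' @param matrix a `response_matrix`.
#' @param stim stimulus label of the dose series.
#' @param concentrations strictly increasing molar concentrations; every
#'   (cell, concentration) must have a call.
#' @param cell_set roi ids to evaluate; default all.
#' @param min_fraction optional fraction-based threshold criterion.
#' @return An object of class `dose_response`: `table` (data.frame
#'   `concentration_M`, `fraction_responding`, `mean_dff`),
#'   `threshold_concentration` (`NA` if no responder at any dose) and
#'   `hill` (list `ymax`, `ec50`, `coefficient`, or `NULL`).
#' @export
dose_response <- function(matrix, stim, concentrations, cell_set = NULL,
                          min_fraction = NULL) {
  stopifnot(length(concentrations) >= 1L,
            !is.unsorted(concentrations, strictly = TRUE))
  m <- as.data.frame(matrix)
  m <- m[m$stimulus == stim & m$concentration_M %in% concentrations, ]
  if (is.null(cell_set)) cell_set <- unique(m$roi_id)
  m <- m[m$roi_id %in% cell_set, ]
  tab <- do.call(rbind, lapply(concentrations, function(cc) {
    mc <- m[m$concentration_M == cc, ]
    if (!all(cell_set %in% mc$roi_id))
      stop("missing calls for some cells at concentration ", cc)
    data.frame(concentration_M = cc,
               fraction_responding = mean(mc$responder),
               mean_dff = mean(mc$dff))
  }))
  thr_idx <- if (is.null(min_fraction)) which(tab$fraction_responding > 0)
             else which(tab$fraction_responding >= min_fraction)
  threshold <- if (length(thr_idx)) tab$concentration_M[min(thr_idx)]
               else NA_real_
  hill <- NULL
  if (nrow(tab) >= 2L && any(tab$mean_dff > 0)) {
    hill <- fit_hill(tab$concentration_M, tab$mean_dff)
  }
  structure(list(table = tab, threshold_concentration = threshold,
                 hill = hill, stimulus = stim),
            class = "dose_response")
}

fit_hill <- function(conc, y) {
  ymax0 <- max(y)
  half <- ymax0 / 2
  above <- which(y >= half)
  ec0 <- if (length(above)) conc[min(above)] else stats::median(conc)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ ymax * conc^h / (conc^h + ec50^h),
                 start = list(ymax = ymax0, ec50 = ec0, h = 1),
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 200),
                 lower = c(ymax = 1e-12, ec50 = 1e-15, h = 0.1),
                 algorithm = "port")),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  list(ymax = unname(p["ymax"]), ec50 = unname(p["ec50"]),
       coefficient = unname(p["h"]))
}

#' Gate ROIs on a co-label (second channel) image
#'
#' An ROI is co-label positive when its mean intensity in the co-label
#' image is at or above `intensity_threshold`.  The default threshold is
#' half the image maximum, which cleanly separates labeled somata from
#' background in the synthetic channel.
#'
#' @param rois list of ROIs.
#' @param colabel_image `H x W` matrix matching the movie frames.
#' @param intensity_threshold fluorescence cutoff; `NULL` for the default.
#' @param image_shape `c(H, W)` of the movie, to validate the match.
#' @return Logical vector (one per ROI), named `roi_ids` when given.
#' @param roi_ids optional names for the result.
#' @export
colabel_gate <- function(rois, colabel_image, intensity_threshold = NULL,
                         image_shape = NULL, roi_ids = NULL) {
  if (!is.null(image_shape) &&
      !identical(dim(colabel_image), as.integer(image_shape)))
    stop("co-label image shape does not match the movie frames")
  if (is.null(intensity_threshold))
    intensity_threshold <- max(colabel_image) / 2
  H <- nrow(colabel_image)
  out <- vapply(rois, function(r) {
    if (any(r$pixels[, 1L] > H) || any(r$pixels[, 2L] > ncol(colabel_image)))
      stop("ROI pixels outside the co-label image")
    mean(colabel_image[pix_linear(r$pixels, H)]) >= intensity_threshold
  }, logical(1))
  if (!is.null(roi_ids)) names(out) <- roi_ids
  out
}

#' Export a response matrix as tidy CSV
#'
#' Columns: `roi_id`, `stimulus`, `concentration_M`, `dff`, `responder`,
#' `slice_id`.
#'
#' @param matrix a `response_matrix`.
#' @param path file path.
#' @export
write_calls_csv <- function(matrix, path) {
  m <- as.data.frame(matrix)
  utils::write.csv(m[, c("roi_id", "stimulus", "concentration_M", "dff",
                         "responder", "slice_id")],
                   path, row.names = FALSE)
  invisible(path)
}
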