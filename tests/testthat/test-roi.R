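# Local ROI detection, candidate filtering, global merge.

make_layout_movie <- function(amplitudes, centers, radii = NULL,
                              shape = c(96, 96), noise = 0) {
  n <- nrow(centers)
  if (is.null(radii)) radii <- rep(4, n)
  cfg <- sim_config(image_shape = shape, n_cells = n, noise_sigma = noise,
                    cell_radius_range = c(min(radii), max(radii) + 0.1),
                    seed = 1)
  sch <- tiny_schedule(cfg)
  manual_movie(centers, radii, rep(600, n),
               matrix(amplitudes, ncol = 1), cfg, sch)
}

test_that("responding disks are detected, silent disks are not", {
  centers <- cbind(y = c(20, 20, 50, 50, 80, 80, 20, 50, 80, 35),
                   x = c(20, 70, 20, 70, 20, 70, 45, 45, 45, 85))
  amps <- c(0.6, 0.6, 0.6, 0.6, rep(0, 6))
  sim <- make_layout_movie(amps, centers)
  sch <- sim$ground_truth$schedule
  cand <- detect_local_rois(sim$movie, vnoca:::schedule_event(sch, 1))
  expect_length(cand, 4L)
  cent <- t(vapply(cand, function(r) r$centroid, numeric(2)))
  for (i in 1:4) {
    d <- sqrt((cent[, 1] - centers[i, 1])^2 + (cent[, 2] - centers[i, 2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("a movie with no responders yields no candidates", {
  centers <- cbind(y = c(30, 60), x = c(30, 60))
  sim <- make_layout_movie(c(0, 0), centers)
  sch <- sim$ground_truth$schedule
  expect_length(detect_local_rois(sim$movie,
                                  vnoca:::schedule_event(sch, 1)), 0L)
})

test_that("heavily overlapping responders come back as one component", {
  centers <- cbind(y = c(48, 52), x = c(48, 50))   # disks overlap > 50%
  sim <- make_layout_movie(c(0.6, 0.6), centers, radii = c(5, 5))
  sch <- sim$ground_truth$schedule
  cand <- detect_local_rois(sim$movie, vnoca:::schedule_event(sch, 1))
  expect_length(cand, 1L)
})

test_that("event windows shorter than 3 frames are rejected", {
  sim <- make_layout_movie(0.6, cbind(y = 40, x = 40))
  ev <- vnoca:::schedule_event(sim$ground_truth$schedule, 1)
  ev$offset_frame <- ev$onset_frame + 1L
  expect_error(detect_local_rois(sim$movie, ev), "3 frames")
})

test_that("area and circularity gates drop speckles and streaks", {
  disk <- list(pixels = vnoca:::disk_pixels(30, 30, 5, 96, 96))
  disk$centroid <- c(30, 30); disk$area <- nrow(disk$pixels)
  speck <- list(pixels = cbind(row = 5L, col = 5L), centroid = c(5, 5),
                area = 1L)
  streak <- list(pixels = as.matrix(expand.grid(row = 10:11, col = 20:59)),
                 centroid = c(10.5, 39.5), area = 80L)
  colnames(streak$pixels) <- c("row", "col")
  out <- filter_candidates(list(disk, speck, streak), detection_params())
  expect_length(out, 1L)
  expect_equal(out[[1]]$area, disk$area)
  # the isoperimetric score of a digital disk is ~1, a 2x40 streak far below
  circ_disk <- vnoca:::pixel_circularity(disk$pixels, 96, 96)
  circ_streak <- vnoca:::pixel_circularity(streak$pixels, 96, 96)
  expect_equal(circ_disk, 1, tolerance = 0.15)
  expect_lt(circ_streak, 0.5)
})

test_that("identical and disjoint ROIs merge as expected", {
  pixA <- vnoca:::disk_pixels(20, 20, 4, 96, 96)
  pixB <- vnoca:::disk_pixels(60, 60, 4, 96, 96)
  mk <- function(pix, src) {
    r <- list(pixels = pix, centroid = colMeans(pix), area = nrow(pix),
              source_stimulus = src)
    r
  }
  g1 <- merge_to_global(list(list(mk(pixA, "s1")), list(mk(pixA, "s2")),
                             list(mk(pixA, "s3"))),
                        image_shape = c(96, 96))
  expect_length(g1, 1L)
  expect_equal(g1[[1]]$sources, c("s1", "s2", "s3"))
  g2 <- merge_to_global(list(list(mk(pixA, "s1")), list(mk(pixB, "s2"))),
                        image_shape = c(96, 96))
  expect_length(g2, 2L)
})

test_that("merge closure equals a brute-force oracle, inclusive at threshold", {
  set.seed(42)
  params <- detection_params(iou_merge_threshold = 0.3)
  # independent oracle: adjacency by IoU >= thr, components by BFS
  oracle_groups <- function(rois, thr) {
    n <- length(rois)
    keys <- lapply(rois, function(r) paste(r$pixels[, 1], r$pixels[, 2]))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      inter <- length(intersect(keys[[i]], keys[[j]]))
      uni <- length(union(keys[[i]], keys[[j]]))
      adj[i, j] <- inter / uni >= thr
    }
    comp <- rep(0L, n); k <- 0L
    for (s in seq_len(n)) {
      if (comp[s]) next
      k <- k + 1L; todo <- s; comp[s] <- k
      while (length(todo)) {
        v <- todo[1]; todo <- todo[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- k; todo <- c(todo, nb)
      }
    }
    sort(tabulate(comp))
  }
  for (rep in 1:5) {
    rois <- lapply(1:12, function(i) {
      cy <- runif(1, 10, 80); cx <- runif(1, 10, 80)
      pix <- vnoca:::disk_pixels(cy, cx, runif(1, 3, 6), 96, 96)
      list(pixels = pix, centroid = colMeans(pix), area = nrow(pix),
           source_stimulus = sprintf("s%d", i %% 3))
    })
    merged <- merge_to_global(rois, params, image_shape = c(96, 96))
    expect_equal(length(merged),
                 length(oracle_groups(rois, params$iou_merge_threshold)))
  }
  # IoU exactly at threshold merges (inclusive >=): two 3-pixel overlaps
  pix1 <- cbind(row = 1:5, col = 1L)      # 5 px
  pix2 <- cbind(row = 3:7, col = 1L)      # IoU = 3/7 with thr 3/7
  p <- detection_params(iou_merge_threshold = 3 / 7)
  r1 <- list(pixels = pix1, centroid = c(3, 1), area = 5L,
             source_stimulus = "a")
  r2 <- list(pixels = pix2, centroid = c(5, 1), area = 5L,
             source_stimulus = "b")
  expect_length(merge_to_global(list(r1, r2), p, image_shape = c(96, 96)),
                1L)
})

test_that("detection is translation-equivariant", {
  centers <- cbind(y = c(30, 60), x = c(30, 55))
  sim <- make_layout_movie(c(0.6, 0.6), centers)
  sch <- sim$ground_truth$schedule
  ev <- vnoca:::schedule_event(sch, 1)
  n0 <- length(detect_local_rois(sim$movie, ev))
  shifted <- sim$movie
  for (t in seq_len(dim(shifted$frames)[3]))
    shifted$frames[, , t] <-
      vnoca:::translate_frame(sim$movie$frames[, , t], 7, -5, 0)
  expect_equal(length(detect_local_rois(shifted, ev)), n0)
})

test_that("ROI JSON round-trips through run-length encoding", {
  pix <- vnoca:::disk_pixels(12, 14, 4, 32, 32)
  roi <- list(pixels = pix, centroid = colMeans(pix), area = nrow(pix),
              source_stimulus = "SE")
  path <- tempfile(fileext = ".json")
  write_rois_json(list(roi), path)
  back <- read_rois_json(path)
  expect_length(back, 1L)
  ord <- function(p) p[order(p[, 1], p[, 2]), ]
  expect_equal(unname(ord(back[[1]]$pixels)), unname(ord(pix)))
  expect_equal(back[[1]]$area, nrow(pix))
})
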