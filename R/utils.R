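# Internal image-processing helpers shared by the simulator, registration
# and ROI detection.

# Pixels of a filled disk (continuous center, inclusive radius) clipped to
# an H x W grid.  Returns a 2-column integer matrix (row, col).
disk_pixels <- function(cy, cx, r, H, W) {
  r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  keep <- (rr - cy)^2 + (cc - cx)^2 <= r^2
  cbind(row = rr[keep], col = cc[keep])
}

pix_linear <- function(pix, H) pix[, 1L] + (pix[, 2L] - 1L) * H

# Integer translation of a matrix: content moves by (dy, dx); exposed
# pixels are filled with `fill`.
translate_frame <- function(m, dy, dx, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sr <- max(1L, 1L - dy):min(H, H - dy)   # source rows
  sc <- max(1L, 1L - dx):min(W, W - dx)
  if (length(sr) > 0L && length(sc) > 0L && sr[1] <= sr[length(sr)])
    out[sr + dy, sc + dx] <- m[sr, sc]
  out
}

# Label 8-connected components of a logical matrix.  Returns an integer
# matrix of labels (0 = background).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    todo <- seed
    lab[seed] <- cur
    i <- 1L
    while (i <= length(todo)) {
      p <- todo[i]; i <- i + 1L
      pr <- ((p - 1L) %% H) + 1L
      pc <- ((p - 1L) %/% H) + 1L
      for (k in 1:8) {
        qr <- pr + nb_dr[k]; qc <- pc + nb_dc[k]
        if (qr < 1L || qr > H || qc < 1L || qc > W) next
        q <- qr + (qc - 1L) * H
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          todo <- c(todo, q)
        }
      }
    }
  }
  lab
}

# Count of exposed 4-neighbor edges of a pixel set (taxicab boundary
# length).  For smooth convex shapes the Euclidean perimeter is about
# pi/4 times this count.
boundary_edge_count <- function(pix, H, W) {
  m <- matrix(FALSE, H + 2L, W + 2L)          # 1-pixel pad avoids bounds checks
  m[cbind(pix[, 1L] + 1L, pix[, 2L] + 1L)] <- TRUE
  core <- m[2:(H + 1L), 2:(W + 1L)]
  up    <- m[1:H,          2:(W + 1L)]
  down  <- m[3:(H + 2L),   2:(W + 1L)]
  left  <- m[2:(H + 1L),   1:W]
  right <- m[2:(H + 1L),   3:(W + 2L)]
  sum(core & !up) + sum(core & !down) + sum(core & !left) + sum(core & !right)
}

# Isoperimetric circularity 4*pi*A/P^2 with the taxicab-corrected
# perimeter P = (pi/4) * edge count; equals 1 for an ideal disk.
pixel_circularity <- function(pix, H, W) {
  e <- boundary_edge_count(pix, H, W)
  if (e == 0L) return(0)
  64 * nrow(pix) / (pi * e^2)
}

# Per-column median of a matrix (columns = pixels), used for robust noise
# estimates.  Plain apply; callers keep the matrices modest.
col_medians <- function(m) apply(m, 2L, stats::median)

`%||%` <- function(a, b) if (is.null(a)) b else a
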