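# Minimal multi-page TIFF I/O for movies: uncompressed little-endian
# grayscale, 16-bit (or 8-bit) unsigned, one strip per page.  No R TIFF
# binding is assumed; this writes and reads exactly the baseline subset
# of the format that microscopy stacks need.

#' Write a movie as an uncompressed multi-page TIFF
#'
#' Frames are clamped to `[0, 2^bits - 1]`, rounded, and stored as
#' unsigned little-endian integers, one page per frame, one strip per
#' page.  The frame interval is not stored in the file; keep it in the
#' schedule JSON.
#'
#' @param movie a [ca_movie()] (or bare `H x W x T` array).
#' @param path output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, bits = 16L) {
  fr <- if (inherits(movie, "ca_movie")) movie$frames else movie
  stopifnot(length(dim(fr)) == 3L, bits %in% c(8L, 16L))
  H <- dim(fr)[1]; W <- dim(fr)[2]; Tn <- dim(fr)[3]
  maxval <- 2^bits - 1
  bytes_pp <- bits / 8L
  strip_bytes <- H * W * bytes_pp
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  page_bytes <- strip_bytes + ifd_bytes   # layout: strip then its IFD

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, value) {
    w2(tag); w2(type); w4(1L); w4(value)
  }

  writeBin(charToRaw("II"), con); w2(42L)
  w4(8L + strip_bytes)                    # offset of first IFD
  for (t in seq_len(Tn)) {
    strip_off <- 8L + (t - 1L) * page_bytes
    vals <- pmin(pmax(round(fr[, , t]), 0), maxval)
    writeBin(as.integer(t(vals)), con, size = bytes_pp, endian = "little")
    w2(n_entries)                         # entries, ascending tag order
    entry(256L, 4L, W)                    # ImageWidth
    entry(257L, 4L, H)                    # ImageLength
    entry(258L, 3L, bits)                 # BitsPerSample
    entry(259L, 3L, 1L)                   # Compression: none
    entry(262L, 3L, 1L)                   # Photometric: BlackIsZero
    entry(273L, 4L, strip_off)            # StripOffsets
    entry(278L, 4L, H)                    # RowsPerStrip
    entry(279L, 4L, strip_bytes)          # StripByteCounts
    entry(339L, 3L, 1L)                   # SampleFormat: unsigned int
    w4(if (t < Tn) 8L + t * page_bytes + strip_bytes else 0L)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF as a movie
#'
#' Supports the uncompressed little-endian baseline subset written by
#' [write_movie_tiff()] (and equivalent stacks from other writers:
#' 8/16-bit unsigned grayscale, no compression, any strip layout).
#'
#' @param path TIFF file.
#' @param frame_interval seconds per frame for the returned [ca_movie()].
#' @return A [ca_movie()].
#' @export
read_movie_tiff <- function(path, frame_interval = 1) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian ('II') TIFF is supported")
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  if (u16(2L) != 42L) stop("bad TIFF magic")

  pages <- list()
  ifd_off <- u32(4L)
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      size <- c(1, 1, 2, 4, 8)[type]
      inline <- size * count <= 4
      voff <- if (inline) e + 8L else u32(e + 8L)
      vals <- vapply(seq_len(count) - 1L, function(k) {
        if (type == 3L) u16(voff + 2L * k) else u32(voff + 4L * k)
      }, numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- u32(ifd_off + 2L + n * 12L)
  }
  if (length(pages) == 0L) stop("TIFF has no pages")

  frames <- lapply(pages, function(tg) {
    W <- tg[["256"]][1]; H <- tg[["257"]][1]
    bits <- (tg[["258"]] %||% 8)[1]
    if (!is.null(tg[["259"]]) && tg[["259"]][1] != 1)
      stop("compressed TIFF not supported")
    offs <- tg[["273"]]; counts <- tg[["279"]]
    px <- unlist(lapply(seq_along(offs), function(s) {
      start <- offs[s]
      n_px <- counts[s] / (bits / 8)
      if (bits == 16) {
        b <- raw[start + seq_len(counts[s])]
        readBin(b, "integer", n_px, size = 2, signed = FALSE,
                endian = "little")
      } else {
        as.integer(raw[start + seq_len(counts[s])])
      }
    }))
    matrix(px, H, W, byrow = TRUE)
  })
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  arr <- array(0, c(H, W, length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  ca_movie(arr, frame_interval)
}
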