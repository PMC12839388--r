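## Minimal baseline-TIFF codec: uncompressed grayscale, 8- or 16-bit,
## little-endian, one strip per page, multi-page via chained IFDs.
## Covers exactly what the pipeline needs (binary masks, synthetic frame
## stacks); it is not a general TIFF reader.

.TIFF_TYPE_SHORT <- 3L
.TIFF_TYPE_LONG  <- 4L

#' Write grayscale images as an uncompressed multi-page TIFF
#'
#' @param frames a numeric matrix (single page) or a list of matrices /
#'   3D array `[frame, row, col]` (multi-page).  Values must be
#'   non-negative integers representable in `bits` bits.
#' @param path output file path
#' @param bits bits per sample, 8 or 16
#' @return `path`, invisibly
#' @export
write_tiff <- function(frames, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[1L]), function(i) frames[i, , ])
  if (!is.list(frames) || !length(frames))
    stopf("frames must be a matrix, 3D array or non-empty list")
  maxv <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  # header: II, 42, offset of first IFD (filled per-page chain below)
  writeBin(charToRaw("II"), con)
  wr2(42L)
  offset <- 8L                      # running file offset after header
  wr4(offset)
  n_entries <- 9L
  ifd_size <- 2L + 12L * n_entries + 4L
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    if (!is.matrix(m)) stopf("frame %d is not a matrix", k)
    v <- as.vector(t(m))            # row-major
    if (any(!is.finite(v)) || any(v < 0) || any(v > maxv))
      stopf("frame %d has values outside [0, %d]", k, maxv)
    h <- nrow(m); w <- ncol(m)
    nbytes <- length(v) * (bits %/% 8L)
    data_off <- offset + ifd_size
    entry <- function(tag, type, count, value) {
      wr2(tag); wr2(type); wr4(count)
      if (type == .TIFF_TYPE_SHORT) { wr2(value); wr2(0L) } else wr4(value)
    }
    wr2(n_entries)
    entry(256L, .TIFF_TYPE_LONG, 1L, w)        # ImageWidth
    entry(257L, .TIFF_TYPE_LONG, 1L, h)        # ImageLength
    entry(258L, .TIFF_TYPE_SHORT, 1L, bits)    # BitsPerSample
    entry(259L, .TIFF_TYPE_SHORT, 1L, 1L)      # Compression: none
    entry(262L, .TIFF_TYPE_SHORT, 1L, 1L)      # Photometric: BlackIsZero
    entry(273L, .TIFF_TYPE_LONG, 1L, data_off) # StripOffsets
    entry(277L, .TIFF_TYPE_SHORT, 1L, 1L)      # SamplesPerPixel
    entry(278L, .TIFF_TYPE_LONG, 1L, h)        # RowsPerStrip
    entry(279L, .TIFF_TYPE_LONG, 1L, nbytes)   # StripByteCounts
    next_ifd <- if (k < length(frames)) data_off + nbytes else 0L
    wr4(next_ifd)
    writeBin(as.integer(v), con, size = bits %/% 8L, endian = "little")
    offset <- data_off + nbytes
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF written by [write_tiff()]
#'
#' @param path file path
#' @return a list of integer matrices, one per page
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  rd2 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  rd4 <- function(off) sum(as.integer(raw[off + 1:4]) *
                             c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || rd2(2L) != 42L)
    stopf("not a little-endian TIFF: %s", path)
  ifd <- rd4(4L)
  pages <- list()
  while (ifd != 0) {
    n <- rd2(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + 12L * (i - 1L)
      tag <- rd2(e); type <- rd2(e + 2L)
      val <- if (type == .TIFF_TYPE_SHORT) rd2(e + 8L) else rd4(e + 8L)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stopf("TIFF tag %d missing", tag)
        default
      } else v
    }
    if (need(259L, 1L) != 1L) stopf("compressed TIFF not supported")
    w <- need(256L); h <- need(257L); bits <- need(258L, 8L)
    off <- need(273L)
    sz <- bits %/% 8L
    vals <- readBin(raw[(off + 1L):(off + w * h * sz)], "integer",
                    n = w * h, size = sz, signed = FALSE,
                    endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- rd4(ifd + 2L + 12L * n)
  }
  pages
}
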