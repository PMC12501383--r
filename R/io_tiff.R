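# Minimal multi-page grayscale TIFF with IEEE floating-point samples.
#
# Volumes carry physical signal amplitudes well outside [0,1], so they need
# SampleFormat = 3 (IEEE float) TIFF pages. This file implements the small
# slice of classic (non-Big) TIFF required for that: little-endian, one
# grayscale sample per pixel, 32- or 64-bit float, uncompressed strips.
# Layout convention (fixed so round trips are bit-exact and testable):
# page k is depth slice k, rows are the slow axis x (ImageLength = n_x),
# columns the fast axis y (ImageWidth = n_y).

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

write_float_tiff <- function(vol, path, bits = 32L) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L, bits %in% c(32L, 64L))
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  bps <- bits %/% 8L
  page_bytes <- nx * ny * bps
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + nz * page_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (k in seq_len(nz)) {
    # row-major page: y (width) varies fastest
    writeBin(as.vector(t(vol[, , k])), con, size = bps, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(nz)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, ny)                       # ImageWidth
    entry(257L, 4L, 1L, nx)                       # ImageLength
    entry(258L, 3L, 1L, bits)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                       # Compression = none
    entry(262L, 3L, 1L, 1L)                       # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_start + (k - 1L) * page_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    entry(278L, 4L, 1L, nx)                       # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)               # StripByteCounts
    entry(339L, 3L, 1L, 3L)                       # SampleFormat = IEEE float
    next_ifd <- if (k < nz) ifd_start + k * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4,
                               endian = "little")
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L)
    stop("unsupported TIFF header (need little-endian classic TIFF): ", path)

  pages <- list()
  ifd_off <- u32(4L)
  while (ifd_off != 0L) {
    n <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- u16(base); type <- u16(base + 2L); count <- u32(base + 4L)
      size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(size)) { tags[[as.character(tag)]] <- NULL; next }
      vals_off <- if (size * count <= 4L) base + 8L else u32(base + 8L)
      rd <- if (size == 2L) u16 else if (size == 4L) u32 else
        function(o) as.integer(raw[o + 1L])
      tags[[as.character(tag)]] <-
        vapply(seq_len(count), function(i) rd(vals_off + (i - 1L) * size), 0L)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", tag)
        default
      } else v
    }
    if (need(TIFF_TAGS[["compression"]], 1L)[1] != 1L)
      stop("compressed TIFF not supported: ", path)
    if (need(TIFF_TAGS[["sample_format"]], 1L)[1] != 3L)
      stop("TIFF sample format is not IEEE float; expected float volume: ", path)
    bits <- need(TIFF_TAGS[["bits"]])[1]
    if (!bits %in% c(32L, 64L))
      stop("unsupported float bit depth ", bits, " in ", path)
    wd <- need(TIFF_TAGS[["width"]])[1]
    ht <- need(TIFF_TAGS[["length"]])[1]
    offs <- need(TIFF_TAGS[["strip_offsets"]])
    cnts <- need(TIFF_TAGS[["strip_counts"]])
    bytes <- unlist(lapply(seq_along(offs),
                           function(i) raw[offs[i] + seq_len(cnts[i])]))
    vals <- readBin(bytes, "double", n = wd * ht, size = bits %/% 8L,
                    endian = "little")
    if (length(vals) != wd * ht) stop("truncated TIFF strip data in ", path)
    # stored row-major (y fastest) -> matrix (x rows, y cols)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ht, ncol = wd,
                                          byrow = TRUE)
    ifd_off <- u32(ifd_off + 2L + n * 12L)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), TRUE)))
    stop("TIFF pages disagree on lateral dimensions: ", path)
  array(unlist(pages), dim = c(d1[1], d1[2], length(pages)))
}
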