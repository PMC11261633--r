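# Minimal baseline-TIFF writer for 32-bit IEEE float pages.
#
# Intensity data must round-trip bit-exactly including NaN, which rules out
# integer-scaled TIFF writers; reading is done with tiff::readTIFF, which
# handles float sample format natively. Little-endian, uncompressed, one
# strip per page, tags in ascending order, metadata JSON in ImageDescription
# of the first page.

TIFF_SHORT <- 3L
TIFF_LONG <- 4L
TIFF_ASCII <- 2L

write_float_tiff <- function(pages, path, description = NULL) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  for (p in pages)
    if (!is.matrix(p) || nrow(p) != ny || ncol(p) != nx)
      stop("all pages must be matrices of identical dimensions")
  npage <- length(pages)
  strip_bytes <- ny * nx * 4L

  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  # layout: header (8) | description | page strips | IFDs
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  strip_offs <- data_off + (seq_len(npage) - 1L) * strip_bytes
  ifd0_off <- data_off + npage * strip_bytes
  n_entries <- function(i) if (i == 1L && !is.null(desc_raw)) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_offs <- ifd0_off + cumsum(c(0L, vapply(seq_len(npage - 1L), ifd_size,
                                             integer(1L))))

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wi(42L, 2L)
  wi(ifd0_off, 4L)
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (p in pages)
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")

  entry <- function(tag, type, count, value) {
    wi(tag, 2L); wi(type, 2L); wi(count, 4L)
    if (type == TIFF_SHORT && count == 1L) {
      wi(value, 2L); wi(0L, 2L)
    } else wi(value, 4L)
  }
  for (i in seq_len(npage)) {
    wi(n_entries(i), 2L)
    entry(256L, TIFF_LONG, 1L, nx)               # ImageWidth
    entry(257L, TIFF_LONG, 1L, ny)               # ImageLength
    entry(258L, TIFF_SHORT, 1L, 32L)             # BitsPerSample
    entry(259L, TIFF_SHORT, 1L, 1L)              # Compression: none
    entry(262L, TIFF_SHORT, 1L, 1L)              # Photometric: min-is-black
    if (i == 1L && !is.null(desc_raw))
      entry(270L, TIFF_ASCII, length(desc_raw), desc_off)
    entry(273L, TIFF_LONG, 1L, strip_offs[i])    # StripOffsets
    entry(277L, TIFF_SHORT, 1L, 1L)              # SamplesPerPixel
    entry(278L, TIFF_LONG, 1L, ny)               # RowsPerStrip
    entry(279L, TIFF_LONG, 1L, strip_bytes)      # StripByteCounts
    entry(339L, TIFF_SHORT, 1L, 3L)              # SampleFormat: IEEE float
    wi(if (i < npage) ifd_offs[i + 1L] else 0L, 4L)
  }
  invisible(path)
}
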