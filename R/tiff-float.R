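# Minimal single-page 32-bit-float TIFF emitter. The `tiff` package reads
# IEEE-float TIFFs (any value range) but only writes integer sample
# formats, which would quantize measure maps; this writer produces the one
# fixed layout the package needs: little-endian, uncompressed, one strip,
# SampleFormat = IEEE float. Reading back via tiff::readTIFF() is exact at
# 32-bit float precision.

tiff_type_short <- 3L
tiff_type_long <- 4L

write_ifd_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(c(tag, type)), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == tiff_type_short) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

write_float_tiff <- function(m, path) {
  stopifnot(is.matrix(m), all(is.finite(m)))
  H <- nrow(m)
  W <- ncol(m)
  data_bytes <- H * W * 4L
  con <- file(path, "wb")
  on.exit(close(con))

  # header: byte order, magic 42, offset of the (single) IFD
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + data_bytes, con, size = 4, endian = "little")
  # pixel data, row-major, at offset 8
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")

  entries <- list(
    list(256L, tiff_type_long, 1L, W),            # ImageWidth
    list(257L, tiff_type_long, 1L, H),            # ImageLength
    list(258L, tiff_type_short, 1L, 32L),         # BitsPerSample
    list(259L, tiff_type_short, 1L, 1L),          # Compression: none
    list(262L, tiff_type_short, 1L, 1L),          # Photometric: BlackIsZero
    list(273L, tiff_type_long, 1L, 8L),           # StripOffsets
    list(277L, tiff_type_short, 1L, 1L),          # SamplesPerPixel
    list(278L, tiff_type_long, 1L, H),            # RowsPerStrip
    list(279L, tiff_type_long, 1L, data_bytes),   # StripByteCounts
    list(339L, tiff_type_short, 1L, 3L)           # SampleFormat: IEEE float
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) write_ifd_entry(con, e[[1]], e[[2]], e[[3]], e[[4]])
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}
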