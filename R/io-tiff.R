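# Minimal multi-page TIFF support for 16-bit signed grayscale stacks:
# little-endian, uncompressed, one strip per page. Slice k of the volume is
# page k; TIFF rows are the y axis, pixels within a row the x axis, which
# matches R's column-major layout of an (x, y) slice. TIFF carries no
# trustworthy voxel spacing, so spacing must always be supplied when
# reading (see read_volume()).

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_byte_counts = 279L, sample_format = 339L
)

write_tiff_stack <- function(volume, path) {
  d <- dim(volume)
  vals <- round(volume$intensities)
  if (any(vals < -32768 | vals > 32767)) {
    stop_tarsalct("intensities exceed the signed 16-bit range", "format")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); # header; first IFD offset patched below
  page_bytes <- d[1] * d[2] * 2L
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  data_off <- function(k) 8L + (k - 1L) * (page_bytes + ifd_bytes)
  ifd_off <- function(k) data_off(k) + page_bytes
  w32(ifd_off(0L) + page_bytes + ifd_bytes) # = ifd of page 1
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (k in seq_len(d[3])) {
    writeBin(as.integer(vals[, , k]), con, size = 2L, endian = "little")
    w16(n_entries)
    entry(TIFF_TAGS[["width"]], 3L, 1L, d[1])
    entry(TIFF_TAGS[["length"]], 3L, 1L, d[2])
    entry(TIFF_TAGS[["bits"]], 3L, 1L, 16L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off(k))
    entry(TIFF_TAGS[["samples_per_pixel"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, d[2])
    entry(TIFF_TAGS[["strip_byte_counts"]], 4L, 1L, page_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 2L)
    w32(if (k < d[3]) ifd_off(k + 1L) else 0L)
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop_tarsalct("file too short to be a TIFF", "format")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop_tarsalct("not a TIFF file", "format"))
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(raw_all[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  if (rd(2L, "integer", 1L, 2L) != 42L) stop_tarsalct("not a TIFF file", "format")
  ifd <- rd(4L, "integer", 1L, 4L)
  slices <- list()
  dims_xy <- NULL
  while (ifd != 0L) {
    n_entries <- rd(ifd, "integer", 1L, 2L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e_off <- ifd + 2L + (i - 1L) * 12L
      tag <- rd(e_off, "integer", 1L, 2L, signed = FALSE)
      type <- rd(e_off + 2L, "integer", 1L, 2L)
      value <- if (type == 3L) rd(e_off + 8L, "integer", 1L, 2L, signed = FALSE)
               else rd(e_off + 8L, "integer", 1L, 4L)
      tags[[as.character(tag)]] <- value
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    if (!identical(g(TIFF_TAGS[["compression"]], 1L), 1L)) {
      stop_tarsalct("only uncompressed TIFF is supported", "format")
    }
    if (!identical(g(TIFF_TAGS[["bits"]], 1L), 16L)) {
      stop_tarsalct("only 16-bit TIFF is supported", "format")
    }
    w <- g(TIFF_TAGS[["width"]]); l <- g(TIFF_TAGS[["length"]])
    if (is.null(w) || is.null(l)) stop_tarsalct("TIFF page lacks dimensions", "format")
    if (is.null(dims_xy)) dims_xy <- c(w, l)
    else if (!identical(dims_xy, c(w, l))) {
      stop_tarsalct("TIFF pages have differing dimensions", "format")
    }
    signed <- identical(g(TIFF_TAGS[["sample_format"]], 1L), 2L)
    off <- g(TIFF_TAGS[["strip_offsets"]])
    vals <- rd(off, "integer", w * l, 2L, signed = signed)
    slices[[length(slices) + 1L]] <- vals
    ifd <- rd(ifd + 2L + n_entries * 12L, "integer", 1L, 4L)
  }
  if (length(slices) == 0L) stop_tarsalct("TIFF contains no pages", "format")
  array(as.numeric(unlist(slices)), c(dims_xy, length(slices)))
}
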