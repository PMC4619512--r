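# Minimal baseline TIFF codec (uncompressed grayscale, multi-page).
# Written because no TIFF reader/writer is available in the dependency stack.
# Supports 8/16-bit unsigned and 32-bit float samples, strip layout, both
# byte orders on read; writes little-endian, one strip per page.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_byte_counts = 279L, sample_format = 339L
)

read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_mark <- rawToChar(raw[1:2])
  endian <- if (order_mark == "II") "little" else if (order_mark == "MM") "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  ru16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                size = 2, signed = FALSE, endian = endian)
  ru32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                 endian = endian)
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  if (ru16(2) != 42L) stop("not a TIFF file (bad magic): ", path)

  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  read_tag_values <- function(off) {
    type <- ru16(off + 2)
    count <- ru32(off + 4)
    sz <- type_size[type] * count
    voff <- if (sz <= 4) off + 8 else ru32(off + 8)
    if (type == 3L) {
      vapply(seq_len(count) - 1L, function(i) ru16(voff + 2 * i), numeric(1))
    } else if (type == 4L) {
      vapply(seq_len(count) - 1L, function(i) ru32(voff + 4 * i), numeric(1))
    } else {
      stop("unsupported TIFF tag type: ", type)
    }
  }

  pages <- list()
  ifd <- ru32(4)
  while (ifd != 0) {
    n_entries <- ru16(ifd)
    tags <- list()
    for (e in seq_len(n_entries) - 1L) {
      off <- ifd + 2 + 12 * e
      tag <- ru16(off)
      hit <- names(TIFF_TAGS)[match(tag, TIFF_TAGS)]
      if (!is.na(hit)) tags[[hit]] <- read_tag_values(off)
    }
    for (req in c("width", "length", "strip_offsets", "strip_byte_counts")) {
      if (is.null(tags[[req]])) stop("TIFF page missing required tag: ", req)
    }
    if (!is.null(tags$compression) && tags$compression != 1)
      stop("unsupported TIFF compression: ", tags$compression)
    if (!is.null(tags$samples_per_pixel) && tags$samples_per_pixel != 1)
      stop("only single-channel grayscale TIFF is supported")
    bits <- if (is.null(tags$bits)) 8L else as.integer(tags$bits[1])
    fmt <- if (is.null(tags$sample_format)) 1L else as.integer(tags$sample_format[1])
    if (!(bits %in% c(8L, 16L) && fmt == 1L) && !(bits == 32L && fmt == 3L))
      stop("unsupported TIFF bit depth / sample format: ", bits, "/", fmt)
    data_raw <- raw(0)
    for (s in seq_along(tags$strip_offsets)) {
      so <- tags$strip_offsets[s]
      sc <- tags$strip_byte_counts[s]
      data_raw <- c(data_raw, raw[(so + 1):(so + sc)])
    }
    w <- as.integer(tags$width); h <- as.integer(tags$length)
    vals <- if (bits == 8L) {
      as.numeric(readBin(data_raw, "integer", n = w * h, size = 1,
                         signed = FALSE))
    } else if (bits == 16L) {
      as.numeric(readBin(data_raw, "integer", n = w * h, size = 2,
                         signed = FALSE, endian = endian))
    } else {
      readBin(data_raw, "numeric", n = w * h, size = 4, endian = endian)
    }
    if (length(vals) < w * h) stop("truncated TIFF strip data")
    pages[[length(pages) + 1L]] <- list(data = matrix(vals[seq_len(w * h)],
                                                      nrow = w),
                                        bits = bits)
    ifd <- ru32(ifd + 2 + 12 * n_entries)
  }
  if (length(pages) == 0) stop("TIFF file contains no pages: ", path)
  pages
}

# vol: nx x ny x nz numeric array; bits: 8, 16 (unsigned) or 32 (float).
# Values are written verbatim (caller handles scaling/rounding).
write_tiff <- function(vol, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L, 32L))
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  bytes_pp <- bits / 8L
  page_bytes <- nx * ny * bytes_pp
  n_tags <- 10L
  ifd_bytes <- 2 + 12 * n_tags + 4

  con <- file(path, "wb")
  on.exit(close(con))
  wu16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wu32 <- function(v) {
    v <- as.numeric(v)
    writeBin(as.integer(ifelse(v >= 2^31, v - 2^32, v)), con, size = 4,
             endian = "little")
  }
  writeBin(charToRaw("II"), con); wu16(42L)
  data_start <- 8
  first_ifd <- data_start + nz * page_bytes
  wu32(first_ifd)
  for (z in seq_len(nz)) {
    page <- as.vector(vol[, , z])
    if (bits == 8L) {
      writeBin(as.integer(round(page)), con, size = 1)
    } else if (bits == 16L) {
      writeBin(as.integer(round(page)), con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(page), con, size = 4, endian = "little")
    }
  }
  tag_entry <- function(tag, type, count, value) {
    wu16(tag); wu16(type); wu32(count)
    if (type == 3L) { wu16(value); wu16(0L) } else wu32(value)
  }
  for (z in seq_len(nz)) {
    wu16(n_tags)
    tag_entry(256L, 4L, 1L, nx)                       # ImageWidth
    tag_entry(257L, 4L, 1L, ny)                       # ImageLength
    tag_entry(258L, 3L, 1L, bits)                     # BitsPerSample
    tag_entry(259L, 3L, 1L, 1L)                       # Compression: none
    tag_entry(262L, 3L, 1L, 1L)                       # Photometric: min-is-black
    tag_entry(273L, 4L, 1L, data_start + (z - 1) * page_bytes) # StripOffsets
    tag_entry(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    tag_entry(278L, 4L, 1L, ny)                       # RowsPerStrip
    tag_entry(279L, 4L, 1L, page_bytes)               # StripByteCounts
    tag_entry(339L, 3L, 1L, if (bits == 32L) 3L else 1L) # SampleFormat
    wu32(if (z == nz) 0 else first_ifd + z * ifd_bytes)
  }
  invisible(path)
}
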