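# Minimal baseline TIFF reader/writer.
#
# No TIFF package is available in the target environment, so the package
# carries its own implementation of the small subset of TIFF 6.0 it needs:
# uncompressed, single-sample-per-pixel, grayscale, multi-page files with
# uint8/16/32 or float32/64 pixels, either endianness, one or more strips
# per page. Stack-level metadata (axes, channel names, calibration) is
# stored as JSON in the ImageDescription tag of the first page, so files
# round-trip through this package losslessly and remain readable by any
# standard TIFF consumer (validated against Python tifffile in the tests).

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, description = 270L, strip_offsets = 273L,
                 samples = 277L, rows_per_strip = 278L,
                 strip_bytecounts = 279L, sample_format = 339L)

tiff_dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(bits = 8L,  fmt = 1L, size = 1L),
    uint16  = list(bits = 16L, fmt = 1L, size = 2L),
    uint32  = list(bits = 32L, fmt = 1L, size = 4L),
    float32 = list(bits = 32L, fmt = 3L, size = 4L),
    float64 = list(bits = 64L, fmt = 3L, size = 8L),
    stop(sprintf("unsupported TIFF dtype '%s'", dtype)))
}

#' Write an image stack as a multi-page TIFF
#'
#' Pages are ordered frame-major (`page = (t-1) * C + c`), and a JSON record
#' with axes, shape, channel names and calibration is embedded in the
#' ImageDescription tag of the first page so that [read_stack()] recovers the
#' full `ImageStack` without a sidecar file.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param dtype pixel storage type: `"float32"` (default, lossless for
#'   simulated data), `"uint16"` or `"uint8"` (values are rounded and
#'   clipped to the type's range).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = "float32") {
  stopifnot(inherits(stack, "ImageStack"))
  info <- tiff_dtype_info(dtype)
  d <- dim(stack$data)
  nt <- d[1]; nc <- d[2]; h <- d[3]; w <- d[4]
  desc <- jsonlite::toJSON(list(pmindex = list(
    axes = "TCYX", shape = c(nt, nc, h, w), channels = stack$channels,
    pixel_size = stack$pixel_size, frame_interval = stack$frame_interval,
    bit_depth = stack$bit_depth)), auto_unbox = TRUE, digits = NA, null = "null")
  # the "pmindex " prefix keeps generic readers from mistaking the
  # description for their own JSON metadata conventions
  desc_raw <- c(charToRaw(paste0("pmindex ", as.character(desc))), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  n_pages <- nt * nc
  strip_bytes <- h * w * info$size
  strip_pad <- strip_bytes %% 2L
  strip_off <- 8L + (seq_len(n_pages) - 1L) * (strip_bytes + strip_pad)
  desc_off <- 8L + n_pages * (strip_bytes + strip_pad)
  ifd0_off <- desc_off + length(desc_raw)
  n_entries <- c(11L, rep(10L, max(0L, n_pages - 1L)))
  ifd_size <- 2L + 12L * n_entries + 4L
  ifd_off <- ifd0_off + cumsum(c(0L, ifd_size[-n_pages]))

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }

  writeBin(charToRaw("II"), con); w2(42L); w4(ifd0_off)
  for (t in seq_len(nt)) for (ch in seq_len(nc)) {
    pix <- as.vector(t(stack$data[t, ch, , ]))  # row-major
    if (info$fmt == 1L) {
      top <- 2^info$bits - 1
      pix <- pmin(pmax(round(pix), 0), top)
      if (info$size == 4L) {
        # uint32: assemble little-endian bytes by hand so values above
        # .Machine$integer.max survive
        b <- rbind(pix %% 256, (pix %/% 256) %% 256,
                   (pix %/% 65536) %% 256, (pix %/% 16777216) %% 256)
        writeBin(as.raw(as.vector(b)), con)
      } else {
        writeBin(as.integer(pix), con, size = info$size, endian = "little")
      }
    } else {
      writeBin(as.numeric(pix), con, size = info$size, endian = "little")
    }
    if (strip_pad) writeBin(as.raw(0L), con)
  }
  writeBin(desc_raw, con)
  for (p in seq_len(n_pages)) {
    w2(n_entries[p])
    entry(TIFF_TAG$width, 4L, 1L, w)
    entry(TIFF_TAG$length, 4L, 1L, h)
    entry(TIFF_TAG$bits, 3L, 1L, info$bits)
    entry(TIFF_TAG$compression, 3L, 1L, 1L)
    entry(TIFF_TAG$photometric, 3L, 1L, 1L)
    if (p == 1L) entry(TIFF_TAG$description, 2L, length(desc_raw), desc_off)
    entry(TIFF_TAG$strip_offsets, 4L, 1L, strip_off[p])
    entry(TIFF_TAG$samples, 3L, 1L, 1L)
    entry(TIFF_TAG$rows_per_strip, 4L, 1L, h)
    entry(TIFF_TAG$strip_bytecounts, 4L, 1L, strip_bytes)
    entry(TIFF_TAG$sample_format, 3L, 1L, info$fmt)
    w4(if (p < n_pages) ifd_off[p + 1L] else 0L)
  }
  invisible(path)
}

# Read one IFD at `offset`; returns list(tags = named list, next_offset).
read_ifd <- function(raw, offset, endian) {
  r2 <- function(at) readBin(raw[(at + 1):(at + 2)], "integer", size = 2L,
                             signed = FALSE, endian = endian)
  r4 <- function(at) {
    v <- readBin(raw[(at + 1):(at + 4)], "integer", size = 4L, endian = endian)
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  n <- r2(offset)
  tags <- list()
  for (i in seq_len(n)) {
    at <- offset + 2L + (i - 1L) * 12L
    tag <- r2(at); type <- r2(at + 2L); count <- r4(at + 4L)
    type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
    inline <- count * type_size <= 4
    voff <- if (inline) at + 8L else r4(at + 8L)
    vals <- if (type == 3L) {
      vapply(seq_len(count), function(k) r2(voff + (k - 1L) * 2L), numeric(1))
    } else if (type == 4L) {
      vapply(seq_len(count), function(k) r4(voff + (k - 1L) * 4L), numeric(1))
    } else if (type == 2L) {
      rawToChar(raw[(voff + 1L):(voff + count)][raw[(voff + 1L):(voff + count)] != as.raw(0L)])
    } else if (type == 1L) {
      as.numeric(raw[(voff + 1L):(voff + count)])
    } else {
      NULL
    }
    tags[[as.character(tag)]] <- vals
  }
  list(tags = tags, next_offset = r4(offset + 2L + n * 12L))
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM") "big"
    else stop("not a TIFF file (bad byte-order mark)")
  magic <- readBin(raw[3:4], "integer", size = 2L, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic number)")
  off <- readBin(raw[5:8], "integer", size = 4L, endian = endian)
  if (off < 0) off <- off + 2^32
  pages <- list(); description <- NULL
  while (off != 0) {
    ifd <- read_ifd(raw, off, endian)
    tg <- ifd$tags
    getv <- function(tag, default = NULL) tg[[as.character(tag)]] %||% default
    comp <- getv(TIFF_TAG$compression, 1L)
    if (comp != 1L) stop("only uncompressed TIFF is supported")
    if (getv(TIFF_TAG$samples, 1L) != 1L)
      stop("only single-sample (grayscale) TIFF is supported")
    w <- getv(TIFF_TAG$width); h <- getv(TIFF_TAG$length)
    bits <- getv(TIFF_TAG$bits, 8L)
    fmt <- getv(TIFF_TAG$sample_format, 1L)
    offs <- getv(TIFF_TAG$strip_offsets)
    cnts <- getv(TIFF_TAG$strip_bytecounts)
    if (is.null(w) || is.null(h) || is.null(offs))
      stop("TIFF page missing required tags")
    buf <- raw(0)
    for (k in seq_along(offs)) buf <- c(buf, raw[(offs[k] + 1L):(offs[k] + cnts[k])])
    size <- bits %/% 8L
    n_px <- as.integer(h) * as.integer(w)
    vals <- if (fmt == 3L) {
      readBin(buf, "double", n = n_px, size = size, endian = endian)
    } else if (size <= 2L) {
      readBin(buf, "integer", n = n_px, size = size, signed = (fmt == 2L),
              endian = endian)
    } else {
      v <- readBin(buf, "integer", n = n_px, size = 4L, endian = endian)
      if (fmt == 1L) v <- ifelse(v < 0, v + 2^32, v)
      v
    }
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = h, byrow = TRUE)
    if (is.null(description)) description <- getv(TIFF_TAG$description)
    off <- ifd$next_offset
  }
  list(pages = pages, description = description,
       bits = bits, sample_format = fmt)
}

#' Read a multi-page TIFF as an image stack
#'
#' Files written by [write_stack()] carry their axis layout, channel names
#' and calibration in embedded JSON and need no hints. For foreign files the
#' page layout must be disambiguated with `axis_hint`.
#'
#' @param path TIFF file path.
#' @param axis_hint one of `"TYX"` (pages are frames, single channel),
#'   `"CYX"` (pages are channels, single frame) or `"TCYX"` (pages are
#'   frame-major frame/channel pairs; requires `n_channels`). Ignored when
#'   the file carries embedded metadata.
#' @param n_channels channel count, required with `axis_hint = "TCYX"`.
#' @param channels,pixel_size,frame_interval metadata overrides for foreign
#'   files (embedded metadata wins when present).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axis_hint = NULL, n_channels = NULL,
                       channels = NULL, pixel_size = 1, frame_interval = 1) {
  tf <- read_tiff_pages(path)
  n_pages <- length(tf$pages)
  if (n_pages == 0L) stop("TIFF file contains no pages")
  h <- nrow(tf$pages[[1]]); w <- ncol(tf$pages[[1]])
  meta <- NULL
  if (!is.null(tf$description) && startsWith(tf$description, "pmindex ")) {
    parsed <- tryCatch(jsonlite::fromJSON(sub("^pmindex ", "", tf$description)),
                       error = function(e) NULL)
    meta <- parsed$pmindex
  }
  if (!is.null(meta)) {
    nt <- meta$shape[1]; nc <- meta$shape[2]
    channels <- meta$channels
    pixel_size <- meta$pixel_size %||% pixel_size
    frame_interval <- meta$frame_interval %||% frame_interval
    bit_depth <- meta$bit_depth
  } else {
    bit_depth <- if (tf$sample_format == 1L) tf$bits else NULL
    if (is.null(axis_hint)) {
      if (n_pages == 1L) {
        axis_hint <- "TYX"
      } else {
        stop(sprintf(paste0(
          "ambiguous axis layout for %d-page TIFF without embedded metadata; ",
          "pass axis_hint = \"TYX\" (%d frames, 1 channel), \"CYX\" ",
          "(1 frame, %d channels) or \"TCYX\" with n_channels"),
          n_pages, n_pages, n_pages))
      }
    }
    if (axis_hint == "TYX") { nt <- n_pages; nc <- 1L }
    else if (axis_hint == "CYX") { nt <- 1L; nc <- n_pages }
    else if (axis_hint == "TCYX") {
      if (is.null(n_channels)) stop("axis_hint = \"TCYX\" requires n_channels")
      nc <- as.integer(n_channels)
      if (n_pages %% nc != 0L)
        stop(sprintf("%d pages not divisible by %d channels", n_pages, nc))
      nt <- n_pages %/% nc
    } else stop(sprintf("unknown axis_hint '%s'", axis_hint))
  }
  if (nt * nc != n_pages)
    stop(sprintf("metadata claims %d x %d pages but file has %d", nt, nc, n_pages))
  data <- array(0, dim = c(nt, nc, h, w))
  p <- 1L
  for (t in seq_len(nt)) for (ch in seq_len(nc)) {
    data[t, ch, , ] <- tf$pages[[p]]
    p <- p + 1L
  }
  image_stack(data, channels = channels, pixel_size = pixel_size,
              frame_interval = frame_interval, bit_depth = bit_depth)
}
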