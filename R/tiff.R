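# Minimal baseline TIFF support, written in-package because no TIFF reader is
# available in the target R library set. Scope: uncompressed, single-sample
# (grayscale) striped pages, 8/16-bit unsigned or 32/64-bit float, II or MM
# byte order, one page per (channel, z) plane. This is the subset that
# ImageJ/tifffile-style scientific TIFFs use for raw fluorescence planes;
# compressed or RGB TIFFs raise a format error.

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

rd_int <- function(raw, offset, size, endian, n = 1L) {
  readBin(raw[(offset + 1):(offset + size * n)], "integer",
          n = n, size = size, signed = FALSE, endian = endian)
}

rd_u32 <- function(raw, offset, endian, n = 1L) {
  # unsigned 32-bit as double to stay safe for large offsets
  b <- readBin(raw[(offset + 1):(offset + 4L * n)], "integer",
               n = n, size = 4L, endian = endian)
  ifelse(b < 0, b + 2^32, b)
}

# Read the value vector of one IFD entry (12 bytes at `entry_off`).
tiff_entry <- function(raw, entry_off, endian) {
  tag   <- rd_int(raw, entry_off, 2L, endian)
  type  <- rd_int(raw, entry_off + 2L, 2L, endian)
  count <- rd_u32(raw, entry_off + 4L, endian)
  size  <- tiff_type_size[[as.character(type)]] %||% 1L
  nbytes <- size * count
  voff <- if (nbytes <= 4) entry_off + 8L else rd_u32(raw, entry_off + 8L, endian)
  values <- switch(as.character(type),
    `3` = rd_int(raw, voff, 2L, endian, n = count),
    `4` = rd_u32(raw, voff, endian, n = count),
    `1` = as.integer(raw[(voff + 1):(voff + count)]),
    `2` = rawToChar(raw[(voff + 1):(voff + count)][raw[(voff + 1):(voff + count)] != as.raw(0)]),
    `5` = {
      v <- rd_u32(raw, voff, endian, n = 2L * count)
      v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
    },
    NULL)
  list(tag = tag, type = type, count = count, values = values)
}

# Parse a TIFF file into a list of numeric matrices (rows = y, cols = x)
# plus the first page's ImageDescription (if any).
read_tiff <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) abort_format("not a TIFF file (too short)")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    abort_format("not a TIFF file (bad byte-order mark)")
  if (rd_int(raw, 2L, 2L, endian) != 42L) abort_format("not a TIFF file (bad magic)")
  ifd_off <- rd_u32(raw, 4L, endian)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n_entries <- rd_int(raw, ifd_off, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- tiff_entry(raw, ifd_off + 2L + (i - 1L) * 12L, endian)
      tags[[as.character(e$tag)]] <- e$values
    }
    width  <- tags[["256"]]
    height <- tags[["257"]]
    bits   <- (tags[["258"]] %||% 1L)[1]
    compression <- (tags[["259"]] %||% 1L)[1]
    spp    <- (tags[["277"]] %||% 1L)[1]
    sfmt   <- (tags[["339"]] %||% 1L)[1]
    planar <- (tags[["284"]] %||% 1L)[1]
    if (is.null(width) || is.null(height)) abort_format("TIFF page missing dimensions")
    if (compression != 1L) abort_format("only uncompressed TIFF is supported")
    if (spp != 1L || planar != 1L) abort_format("only single-sample (grayscale) TIFF is supported")
    offsets <- tags[["273"]]
    counts  <- tags[["279"]]
    if (is.null(offsets) || is.null(counts)) abort_format("TIFF page missing strip layout")
    data <- raw(0)
    for (i in seq_along(offsets)) {
      data <- c(data, raw[(offsets[i] + 1):(offsets[i] + counts[i])])
    }
    vals <- if (sfmt == 3L && bits == 32L) {
      readBin(data, "double", n = width * height, size = 4L, endian = endian)
    } else if (sfmt == 3L && bits == 64L) {
      readBin(data, "double", n = width * height, size = 8L, endian = endian)
    } else if (sfmt %in% c(1L, 4L) && bits == 8L) {
      as.numeric(as.integer(data[seq_len(width * height)]))
    } else if (sfmt %in% c(1L, 4L) && bits == 16L) {
      as.numeric(readBin(data, "integer", n = width * height, size = 2L,
                         signed = FALSE, endian = endian))
    } else {
      abort_format(sprintf("unsupported TIFF sample layout: %d-bit, format %d", bits, sfmt))
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    if (is.null(description) && !is.null(tags[["270"]])) description <- tags[["270"]]
    ifd_off <- rd_u32(raw, ifd_off + 2L + n_entries * 12L, endian)
  }
  if (length(pages) == 0) abort_format("TIFF contains no pages")
  list(pages = pages, description = description)
}

w_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
w_u32 <- function(x) {
  x <- as.numeric(x)
  writeBin(as.integer(ifelse(x >= 2^31, x - 2^32, x)), raw(), size = 4L, endian = "little")
}

tiff_entry_raw <- function(tag, type, count, value_word) {
  c(w_u16(tag), w_u16(type), w_u32(count), value_word)
}

# Write matrices as a multi-page grayscale TIFF (little endian). dtype is
# "uint8" or "float64"; float64 round-trips doubles bit-for-bit.
write_tiff <- function(path, pages, dtype = c("float64", "uint8"),
                       description = NULL) {
  dtype <- match.arg(dtype)
  stopifnot(length(pages) >= 1)
  bits <- if (dtype == "uint8") 8L else 64L
  sfmt <- if (dtype == "uint8") 1L else 3L
  bps  <- bits / 8L
  heights <- vapply(pages, nrow, integer(1))
  widths  <- vapply(pages, ncol, integer(1))
  data_raw <- lapply(pages, function(m) {
    v <- as.vector(t(m))
    if (dtype == "uint8") writeBin(as.integer(v), raw(), size = 1L)
    else writeBin(as.numeric(v), raw(), size = 8L, endian = "little")
  })
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0)) else raw(0)
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  strip_counts <- vapply(data_raw, length, integer(1))
  data_raw <- lapply(data_raw, function(d) {
    if (length(d) %% 2L == 1L) c(d, as.raw(0)) else d   # keep offsets word-aligned
  })
  data_sizes <- vapply(data_raw, length, integer(1))
  data_offsets <- 8L + cumsum(c(0L, data_sizes[-length(data_sizes)]))
  desc_offset <- 8L + sum(data_sizes)
  ifd0_offset <- desc_offset + length(desc_raw)
  n_pages <- length(pages)
  entry_counts <- ifelse(seq_len(n_pages) == 1L & length(desc_raw) > 0, 11L, 10L)
  ifd_sizes <- 2L + entry_counts * 12L + 4L
  ifd_offsets <- ifd0_offset + cumsum(c(0L, ifd_sizes[-n_pages]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(w_u16(42L), con)
  writeBin(w_u32(ifd0_offset), con)
  for (d in data_raw) writeBin(d, con)
  if (length(desc_raw)) writeBin(desc_raw, con)
  for (p in seq_len(n_pages)) {
    entries <- list(
      tiff_entry_raw(256L, 4L, 1L, w_u32(widths[p])),
      tiff_entry_raw(257L, 4L, 1L, w_u32(heights[p])),
      tiff_entry_raw(258L, 3L, 1L, c(w_u16(bits), w_u16(0L))),
      tiff_entry_raw(259L, 3L, 1L, c(w_u16(1L), w_u16(0L))),
      tiff_entry_raw(262L, 3L, 1L, c(w_u16(1L), w_u16(0L)))
    )
    if (p == 1L && length(desc_raw) > 0) {
      entries <- c(entries, list(
        tiff_entry_raw(270L, 2L, length(desc_raw), w_u32(desc_offset))))
    }
    entries <- c(entries, list(
      tiff_entry_raw(273L, 4L, 1L, w_u32(data_offsets[p])),
      tiff_entry_raw(277L, 3L, 1L, c(w_u16(1L), w_u16(0L))),
      tiff_entry_raw(278L, 4L, 1L, w_u32(heights[p])),
      tiff_entry_raw(279L, 4L, 1L, w_u32(strip_counts[p])),
      tiff_entry_raw(339L, 3L, 1L, c(w_u16(sfmt), w_u16(0L)))
    ))
    writeBin(w_u16(length(entries)), con)
    for (e in entries) writeBin(e, con)
    next_off <- if (p < n_pages) ifd_offsets[p + 1L] else 0L
    writeBin(w_u32(next_off), con)
  }
  invisible(path)
}
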