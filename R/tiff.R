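# Minimal baseline TIFF codec for uncompressed single-channel grayscale
# images. Scope is deliberately narrow (the only dialect the instrument chain
# produces): 8- or 16-bit unsigned integer samples, no compression, stripped
# or tiled layout and either byte order on read; always little-endian,
# single-strip on write. No multi-page stacks: only the first IFD is read.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

rd_uint <- function(raw, offset, size, n, endian) {
  idx <- seq.int(offset + 1L, length.out = size * n)
  if (max(idx) > length(raw)) err_unsupported("truncated TIFF file")
  if (size == 4L) {
    v <- readBin(raw[idx], "integer", n = n, size = 4L, endian = endian)
    ifelse(v < 0, v + 2^32, as.numeric(v))
  } else {
    readBin(raw[idx], "integer", n = n, size = size, endian = endian,
            signed = FALSE)
  }
}

# Value array for one IFD entry (inline when it fits in 4 bytes).
tiff_entry_values <- function(raw, entry_off, endian) {
  tag <- rd_uint(raw, entry_off, 2L, 1L, endian)
  type <- rd_uint(raw, entry_off + 2L, 2L, 1L, endian)
  count <- rd_uint(raw, entry_off + 4L, 4L, 1L, endian)
  tsize <- if (type >= 1 && type <= length(TIFF_TYPE_SIZES)) {
    TIFF_TYPE_SIZES[type]
  } else {
    1L
  }
  nbytes <- tsize * count
  voff <- if (nbytes <= 4) entry_off + 8L else rd_uint(raw, entry_off + 8L, 4L, 1L, endian)
  values <- switch(
    as.character(type),
    "1" = rd_uint(raw, voff, 1L, count, endian),
    "2" = {
      chars <- raw[seq.int(voff + 1L, length.out = count)]
      rawToChar(chars[chars != as.raw(0)])
    },
    "3" = rd_uint(raw, voff, 2L, count, endian),
    "4" = rd_uint(raw, voff, 4L, count, endian),
    "5" = {
      num <- rd_uint(raw, voff, 4L, 2L * count, endian)
      num[seq(1, 2 * count, 2)] / num[seq(2, 2 * count, 2)]
    },
    NULL
  )
  list(tag = tag, type = type, count = count, values = values)
}

tiff_read <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) err_unsupported("not a TIFF file (too short)")
  order_mark <- rawToChar(raw[1:2])
  endian <- if (order_mark == "II") {
    "little"
  } else if (order_mark == "MM") {
    "big"
  } else {
    err_unsupported("not a TIFF file (bad byte-order mark)")
  }
  if (rd_uint(raw, 2L, 2L, 1L, endian) != 42) {
    err_unsupported("not a TIFF file (bad magic number)")
  }
  ifd_off <- rd_uint(raw, 4L, 4L, 1L, endian)
  n_entries <- rd_uint(raw, ifd_off, 2L, 1L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- tiff_entry_values(raw, ifd_off + 2L + (i - 1L) * 12L, endian)
    tags[[as.character(e$tag)]] <- e$values
  }
  tag1 <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v[1]
  }

  width <- tag1(256)
  height <- tag1(257)
  if (is.null(width) || is.null(height)) {
    err_unsupported("TIFF lacks image dimensions")
  }
  compression <- tag1(259, 1)
  if (compression != 1) {
    err_unsupported(sprintf(
      "unsupported TIFF: Compression=%d (only uncompressed is supported)",
      compression
    ))
  }
  spp <- tag1(277, 1)
  if (spp != 1) {
    err_unsupported(sprintf(
      "unsupported TIFF: SamplesPerPixel=%d (only single-channel grayscale is supported)",
      spp
    ))
  }
  sample_format <- tag1(339, 1)
  if (sample_format == 3) {
    err_unsupported("unsupported TIFF: SampleFormat=3 (floating point samples)")
  }
  if (sample_format != 1) {
    err_unsupported(sprintf("unsupported TIFF: SampleFormat=%d", sample_format))
  }
  bps <- tag1(258, 1)
  if (!bps %in% c(8, 16)) {
    err_unsupported(sprintf(
      "unsupported TIFF: BitsPerSample=%d (only 8 or 16 supported)", bps
    ))
  }
  bytes_px <- as.integer(bps / 8)

  px <- matrix(0L, nrow = height, ncol = width)
  read_block <- function(offset, n) {
    rd_uint(raw, offset, bytes_px, n, endian)
  }

  if (!is.null(tags[["324"]])) {
    tw <- tag1(322)
    tl <- tag1(323)
    offs <- tags[["324"]]
    counts <- tags[["325"]]
    if (is.null(tw) || is.null(tl)) err_unsupported("tiled TIFF lacks tile size")
    tiles_across <- ceiling(width / tw)
    tiles_down <- ceiling(height / tl)
    k <- 0L
    for (ty in seq_len(tiles_down)) {
      for (tx in seq_len(tiles_across)) {
        k <- k + 1L
        vals <- read_block(offs[k], tw * tl)
        tile <- matrix(vals, nrow = tl, ncol = tw, byrow = TRUE)
        r0 <- (ty - 1L) * tl
        c0 <- (tx - 1L) * tw
        nr <- min(tl, height - r0)
        nc <- min(tw, width - c0)
        px[r0 + seq_len(nr), c0 + seq_len(nc)] <-
          tile[seq_len(nr), seq_len(nc)]
      }
    }
  } else {
    offs <- tags[["273"]]
    if (is.null(offs)) err_unsupported("TIFF lacks strip offsets")
    rps <- tag1(278, height)
    row0 <- 0L
    for (k in seq_along(offs)) {
      nr <- min(rps, height - row0)
      vals <- read_block(offs[k], nr * width)
      px[row0 + seq_len(nr), ] <- matrix(vals, nrow = nr, ncol = width,
                                         byrow = TRUE)
      row0 <- row0 + nr
    }
  }
  storage.mode(px) <- "integer"
  list(
    pixels = px,
    bits_per_sample = as.integer(bps),
    description = tags[["270"]]
  )
}

wr_u16 <- function(con, v) {
  v <- as.integer(v)
  writeBin(ifelse(v > 32767L, v - 65536L, v), con, size = 2L,
           endian = "little")
}
wr_u32 <- function(con, v) {
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}

tiff_write <- function(pixels, path, bits_per_sample, description = "") {
  stopifnot(is.matrix(pixels), bits_per_sample %in% c(8L, 16L))
  height <- nrow(pixels)
  width <- ncol(pixels)
  bytes_px <- bits_per_sample / 8L
  desc_raw <- c(charToRaw(description), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  entries <- list(
    # tag, type (3 = SHORT, 4 = LONG, 2 = ASCII), count, value
    list(256L, 4L, 1L, width),
    list(257L, 4L, 1L, height),
    list(258L, 3L, 1L, bits_per_sample),
    list(259L, 3L, 1L, 1L),   # uncompressed
    list(262L, 3L, 1L, 1L),   # BlackIsZero
    list(270L, 2L, length(desc_raw), NA),  # offset patched below
    list(273L, 4L, 1L, NA),   # strip offset patched below
    list(277L, 3L, 1L, 1L),
    list(278L, 4L, 1L, height),            # single strip
    list(279L, 4L, 1L, height * width * bytes_px),
    list(339L, 3L, 1L, 1L)    # unsigned integer samples
  )
  n <- length(entries)
  ifd_off <- 8L
  desc_off <- ifd_off + 2L + n * 12L + 4L
  strip_off <- desc_off + length(desc_raw)
  entries[[6]][[4]] <- desc_off
  entries[[7]][[4]] <- strip_off

  con <- tryCatch(file(path, "wb"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) err_io(sprintf("cannot open %s for writing", path))
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  wr_u16(con, 42L)
  wr_u32(con, ifd_off)
  wr_u16(con, n)
  for (e in entries) {
    wr_u16(con, e[[1]])
    wr_u16(con, e[[2]])
    wr_u32(con, e[[3]])
    if (e[[2]] == 3L) {        # SHORT: value left-justified in 4-byte field
      wr_u16(con, e[[4]])
      wr_u16(con, 0L)
    } else {
      wr_u32(con, e[[4]])
    }
  }
  wr_u32(con, 0L)  # no further IFDs
  writeBin(desc_raw, con)
  vals <- as.integer(t(pixels))  # TIFF sample order is row-major
  if (bits_per_sample == 8L) {
    writeBin(as.raw(vals), con)
  } else {
    wr_u16(con, vals)
  }
  invisible(path)
}
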