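# Minimal baseline TIFF codec: uncompressed, 8-bit, chunky (interleaved),
# grayscale or RGB. Kept deliberately small; anything fancier (LZW, tiles,
# planar, 16-bit) is rejected with a format error naming the path.

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

read_tiff_baseline <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readBin(con, "raw", n = 2L)
  endian <- if (identical(byte_order, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(byte_order, as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  magic <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", size = 4L, endian = endian)

  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (k in seq_len(n_entries)) {
    tag   <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    typ   <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    cnt   <- readBin(con, "integer", size = 4L, endian = endian)
    value <- readBin(con, "raw", n = 4L)
    tags[[as.character(tag)]] <- list(type = typ, count = cnt, value = value)
  }

  read_vals <- function(entry) {
    if (is.null(entry)) return(NULL)
    sz <- tiff_type_size[as.character(entry$type)]
    if (is.na(sz) || !entry$type %in% c(1L, 3L, 4L))
      stop("unsupported TIFF field type ", entry$type, " in ", path)
    total <- sz * entry$count
    if (total <= 4L) {
      raw_vals <- entry$value[seq_len(total)]
    } else {
      off <- readBin(entry$value, "integer", size = 4L, endian = endian)
      seek(con, off)
      raw_vals <- readBin(con, "raw", n = total)
    }
    readBin(raw_vals, "integer", n = entry$count, size = sz,
            signed = sz == 4L, endian = endian)   # LONGs here never exceed 2^31
  }

  need <- function(tag, default = NULL) {
    v <- read_vals(tags[[as.character(tag)]])
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, ": ", path)
      v <- default
    }
    v
  }

  width  <- need(256L)
  height <- need(257L)
  bits   <- need(258L, 8L)
  comp   <- need(259L, 1L)
  photo  <- need(262L)
  spp    <- need(277L, 1L)
  rps    <- need(278L, height)
  offs   <- need(273L)
  cnts   <- need(279L)
  planar <- need(284L, 1L)

  if (comp != 1L) stop("only uncompressed TIFF is supported: ", path)
  if (planar != 1L) stop("only chunky TIFF is supported: ", path)
  if (any(bits != 8L)) stop("only 8-bit TIFF is supported: ", path)
  if (!spp %in% c(1L, 3L)) stop("only gray/RGB TIFF is supported: ", path)
  if (!photo %in% c(0L, 1L, 2L)) stop("unsupported TIFF photometric: ", path)

  data <- raw(0)
  for (k in seq_along(offs)) {
    seek(con, offs[k])
    data <- c(data, readBin(con, "raw", n = cnts[k]))
  }
  expected <- as.numeric(width) * height * spp
  if (length(data) < expected) stop("truncated TIFF strip data: ", path)
  vals <- as.integer(data[seq_len(expected)])
  if (photo == 0L) vals <- 255L - vals          # WhiteIsZero
  if (spp == 1L) {
    matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    aperm(array(vals, dim = c(3L, width, height)), c(3L, 2L, 1L))
  }
}

write_tiff_baseline <- function(px, path) {
  d <- dim(px)
  M <- d[1]; N <- d[2]
  spp <- if (length(d) == 3L) d[3] else 1L
  data <- if (spp == 1L) {
    as.raw(as.vector(t(px)))
  } else {
    as.raw(as.vector(aperm(px, c(3L, 2L, 1L))))
  }
  con <- file(path, "wb")
  on.exit(close(con))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  data_off <- 8L
  bps_off  <- data_off + length(data)                 # extra BitsPerSample array (RGB)
  ifd_off  <- if (spp == 3L) bps_off + 6L else bps_off

  writeBin(as.raw(c(0x49, 0x49)), con); u16(42L); u32(ifd_off)
  writeBin(data, con)
  if (spp == 3L) { u16(8L); u16(8L); u16(8L) }

  entry <- function(tag, type, count, value, is_offset = FALSE) {
    u16(tag); u16(type); u32(count)
    if (type == 3L && !is_offset) { u16(value); u16(0L) } else u32(value)
  }
  n_entries <- 9L
  u16(n_entries)
  entry(256L, 4L, 1L, N)                               # ImageWidth
  entry(257L, 4L, 1L, M)                               # ImageLength
  if (spp == 3L) entry(258L, 3L, 3L, bps_off, is_offset = TRUE)
  else           entry(258L, 3L, 1L, 8L)               # BitsPerSample
  entry(259L, 3L, 1L, 1L)                              # Compression: none
  entry(262L, 3L, 1L, if (spp == 3L) 2L else 1L)       # Photometric
  entry(273L, 4L, 1L, data_off)                        # StripOffsets
  entry(277L, 3L, 1L, spp)                             # SamplesPerPixel
  entry(278L, 4L, 1L, M)                               # RowsPerStrip
  entry(279L, 4L, 1L, length(data))                    # StripByteCounts
  u32(0L)                                              # no next IFD
  invisible(path)
}
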