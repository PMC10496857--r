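# Minimal multi-page float32 TIFF codec (uncompressed, little-endian,
# one grayscale band per page, band-sequential page order). Installed
# TIFF bindings only handle data normalized to [0, 1], which cannot
# represent Mueller elements or retardance maps, so the few needed TIFF
# structures are written directly. The layout (SampleFormat = IEEE
# float, one strip per page, JSON metadata in ImageDescription of the
# first page) is readable by standard scientific TIFF readers.

.TIFF_SHORT <- 3L
.TIFF_LONG <- 4L
.TIFF_ASCII <- 2L

.tiff_entry <- function(con, tag, type, count, values) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == .TIFF_SHORT) {
    writeBin(as.integer(values[1]), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(values[1]), con, size = 4, endian = "little")
  }
}

write_float_tiff <- function(bands, path, description = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  H <- nrow(bands[[1]]); W <- ncol(bands[[1]])
  for (b in bands)
    if (nrow(b) != H || ncol(b) != W)
      stop("all bands must share one shape")
  nb <- length(bands)
  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  }
  desc_len <- length(desc_raw)
  data_size <- as.integer(H * W * 4)
  n_entries <- function(k) if (k == 1 && desc_len > 0) 11L else 10L
  ifd_size <- function(k) 2L + 12L * n_entries(k) + 4L
  # offsets: header(8) | description | [data_k | ifd_k] * nb
  off_data <- integer(nb); off_ifd <- integer(nb)
  pos <- 8L + desc_len
  for (k in seq_len(nb)) {
    off_data[k] <- pos
    off_ifd[k] <- pos + data_size
    pos <- off_ifd[k] + ifd_size(k)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(off_ifd[1]), con, size = 4, endian = "little")
  if (desc_len > 0) writeBin(desc_raw, con)
  for (k in seq_len(nb)) {
    writeBin(as.numeric(t(bands[[k]])), con, size = 4, endian = "little")
    writeBin(n_entries(k), con, size = 2, endian = "little")
    .tiff_entry(con, 256, .TIFF_LONG, 1, W)
    .tiff_entry(con, 257, .TIFF_LONG, 1, H)
    .tiff_entry(con, 258, .TIFF_SHORT, 1, 32)
    .tiff_entry(con, 259, .TIFF_SHORT, 1, 1)
    .tiff_entry(con, 262, .TIFF_SHORT, 1, 1)
    if (k == 1 && desc_len > 0)
      .tiff_entry(con, 270, .TIFF_ASCII, desc_len, 8L)
    .tiff_entry(con, 273, .TIFF_LONG, 1, off_data[k])
    .tiff_entry(con, 277, .TIFF_SHORT, 1, 1)
    .tiff_entry(con, 278, .TIFF_LONG, 1, H)
    .tiff_entry(con, 279, .TIFF_LONG, 1, data_size)
    .tiff_entry(con, 339, .TIFF_SHORT, 1, 3)
    writeBin(as.integer(if (k < nb) off_ifd[k + 1] else 0L), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

.tiff_read_values <- function(raw, pos, type, count) {
  size <- c(`2` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
  total <- size * count
  start <- if (total <= 4) pos else
    readBin(raw[pos:(pos + 3)], "integer", 1, 4, endian = "little") + 1L
  chunk <- raw[start:(start + total - 1)]
  if (type == .TIFF_ASCII) {
    return(rawToChar(chunk[chunk != as.raw(0)]))
  }
  readBin(chunk, "integer", count, size,
          signed = size > 2, endian = "little")
}

read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("format error: not a TIFF file")
  order <- rawToChar(raw[1:2])
  if (order == "MM")
    stop("format error: big-endian TIFF not supported")
  if (order != "II" ||
      readBin(raw[3:4], "integer", 1, 2, endian = "little") != 42L)
    stop("format error: not a TIFF file")
  ifd_off <- readBin(raw[5:8], "integer", 1, 4, endian = "little")
  bands <- list()
  description <- NULL
  while (ifd_off != 0) {
    p <- ifd_off + 1L
    n <- readBin(raw[p:(p + 1)], "integer", 1, 2, endian = "little")
    tags <- list()
    for (i in seq_len(n)) {
      ep <- p + 2L + (i - 1L) * 12L
      tag <- readBin(raw[ep:(ep + 1)], "integer", 1, 2, endian = "little")
      type <- readBin(raw[(ep + 2):(ep + 3)], "integer", 1, 2, endian = "little")
      count <- readBin(raw[(ep + 4):(ep + 7)], "integer", 1, 4, endian = "little")
      if (type %in% c(2L, 3L, 4L))
        tags[[as.character(tag)]] <- .tiff_read_values(raw, ep + 8L, type, count)
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop(sprintf("format error: missing TIFF tag %d", tag))
      v
    }
    W <- need(256); H <- need(257)
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("format error: compressed TIFF not supported")
    if (any(need(258) != 32) ||
        (!is.null(tags[["339"]]) && any(tags[["339"]] != 3)))
      stop("format error: expected 32-bit IEEE float samples")
    if (!is.null(tags[["277"]]) && tags[["277"]] != 1)
      stop("format error: expected one sample per pixel per page")
    if (!is.null(tags[["270"]]) && is.null(description))
      description <- tags[["270"]]
    offs <- need(273); counts <- need(279)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      chunk <- raw[(offs[s] + 1):(offs[s] + counts[s])]
      vals <- c(vals, readBin(chunk, "numeric", counts[s] / 4, 4,
                              endian = "little"))
    }
    bands[[length(bands) + 1L]] <- matrix(vals, H, W, byrow = TRUE)
    np <- p + 2L + n * 12L
    ifd_off <- readBin(raw[np:(np + 3)], "integer", 1, 4, endian = "little")
  }
  list(bands = bands, description = description)
}
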