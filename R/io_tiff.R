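# Minimal TIFF codec for the images this package exchanges: single-channel,
# 8-bit, uncompressed, stripped.  Written because no TIFF package is available
# in the supported dependency set.  The writer emits little-endian baseline
# TIFF with resolution tags carrying the pixel size (pixels per cm); the
# reader accepts either byte order and any strip layout, but only bilevel
# grayscale 8-bit uncompressed data.

TIFF_TYPE_SIZE <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8) # BYTE..DOUBLE

#' Write an 8-bit grayscale TIFF
#'
#' The physical pixel size is stored in the TIFF X/YResolution tags (pixels
#' per centimeter); [write_sidecar()] stores it losslessly alongside.
#'
#' @param image a [projection_image()] (or plain integer matrix plus
#'   `pixel_size`).
#' @param path output file.
#' @param pixel_size nm/px; taken from `image` when it is a
#'   `goldrim_image`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, pixel_size = NULL) {
  if (inherits(image, "goldrim_image")) {
    m <- image$intensities
    pixel_size <- pixel_size %||% image$pixel_size
  } else {
    m <- as.matrix(image)
    if (is.null(pixel_size)) stop_validation("pixel_size", "required")
  }
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  n_entries <- 12L
  ifd_off <- 8L
  extra_off <- ifd_off + 2L + 12L * n_entries + 4L   # two RATIONALs live here
  data_off <- extra_off + 16L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  w4(ifd_off)
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    w4(count)
    if (type == 3L) { # SHORT packed left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else w4(value)
  }
  # pixels per cm as a rational; keep the numerator within 32 bits
  res_den <- 10
  res_num <- round(1e7 / pixel_size * res_den)
  while (res_num > .Machine$integer.max && res_den > 1) {
    res_den <- res_den / 10
    res_num <- round(1e7 / pixel_size * res_den)
  }
  writeBin(n_entries, con, size = 2, endian = "little")
  entry(256, 4, 1, nc)            # ImageWidth
  entry(257, 4, 1, nr)            # ImageLength
  entry(258, 3, 1, 8)             # BitsPerSample
  entry(259, 3, 1, 1)             # Compression: none
  entry(262, 3, 1, 1)             # Photometric: BlackIsZero
  entry(273, 4, 1, data_off)      # StripOffsets
  entry(277, 3, 1, 1)             # SamplesPerPixel
  entry(278, 4, 1, nr)            # RowsPerStrip
  entry(279, 4, 1, nr * nc)       # StripByteCounts
  entry(282, 5, 1, extra_off)     # XResolution
  entry(283, 5, 1, extra_off + 8) # YResolution
  entry(296, 3, 1, 3)             # ResolutionUnit: cm
  w4(0)                           # next IFD
  w4(res_num); w4(res_den)        # XResolution rational
  w4(res_num); w4(res_den)        # YResolution rational
  writeBin(as.raw(as.vector(t(m))), con)
  invisible(path)
}

read_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1L))
}

#' Read an 8-bit grayscale uncompressed TIFF
#'
#' @param path TIFF file.
#' @param pixel_size nm/px override; when `NULL` the resolution tags are
#'   used (if absent, the pixel size must be supplied or be in a sidecar —
#'   see [read_image()]).
#' @return a [projection_image()].
#' @export
read_tiff <- function(path, pixel_size = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop_goldrim("goldrim_io_error", "not a TIFF file: %s", path)
  if (read_uint(raw, 2, 2, endian) != 42)
    stop_goldrim("goldrim_io_error", "not a TIFF file: %s", path)
  ifd <- read_uint(raw, 4, 4, endian)
  n <- read_uint(raw, ifd, 2, endian)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + 12 * (i - 1)
    tag <- read_uint(raw, e, 2, endian)
    type <- read_uint(raw, e + 2, 2, endian)
    count <- read_uint(raw, e + 4, 4, endian)
    size <- TIFF_TYPE_SIZE[type] * count
    voff <- if (size > 4) read_uint(raw, e + 8, 4, endian) else e + 8
    unit <- TIFF_TYPE_SIZE[type]
    vals <- if (type == 5) { # RATIONAL -> numeric
      vapply(seq_len(count), function(k) {
        num <- read_uint(raw, voff + 8 * (k - 1), 4, endian)
        den <- read_uint(raw, voff + 8 * (k - 1) + 4, 4, endian)
        if (den == 0) NA_real_ else num / den
      }, numeric(1))
    } else {
      vapply(seq_len(count), function(k)
        read_uint(raw, voff + unit * (k - 1), unit, endian), numeric(1))
    }
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  if (any(g(258, 8) != 8) || g(259, 1) != 1 || g(277, 1) != 1)
    stop_goldrim("goldrim_io_error",
                 "only 8-bit single-channel uncompressed TIFF is supported")
  nc <- g(256); nr <- g(257)
  offs <- g(273); counts <- g(279, nr * nc)
  bytes <- unlist(lapply(seq_along(offs), function(k)
    raw[offs[k] + seq_len(counts[k])]))
  m <- matrix(as.integer(bytes), nrow = nr, ncol = nc, byrow = TRUE)
  if (is.null(pixel_size)) {
    xres <- g(282); unit_code <- g(296, 2)
    if (!is.null(xres) && is.finite(xres[1]) && xres[1] > 0)
      pixel_size <- switch(as.character(unit_code[1]),
                           "3" = 1e7 / xres[1],      # per cm
                           "2" = 2.54e7 / xres[1],   # per inch
                           NA_real_)
  }
  if (is.null(pixel_size) || is.na(pixel_size))
    stop_goldrim("goldrim_io_error",
                 "no pixel size in %s; supply one explicitly", path)
  projection_image(m, pixel_size)
}

#' Write the calibration sidecar
#'
#' @param image a [projection_image()].
#' @param path JSON path (conventionally `<image>.json`).
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(image, path) {
  jsonlite::write_json(list(pixel_size_nm = image$pixel_size),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image (TIFF or PNG) with its pixel size
#'
#' Pixel-size precedence: explicit argument, then sidecar JSON
#' (`<image>.json`), then TIFF resolution tags.  A mismatch between an
#' explicit argument and the sidecar is reported via `message()` and the
#' argument wins.
#'
#' @param path image file (`.tif`/`.tiff`, or `.png` when the `png` package
#'   is installed).
#' @param pixel_size optional explicit nm/px.
#' @return a [projection_image()].
#' @export
read_image <- function(path, pixel_size = NULL) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  sc_px <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar)$pixel_size_nm else NULL
  if (!is.null(pixel_size) && !is.null(sc_px) &&
      abs(pixel_size - sc_px) > 1e-9)
    message("pixel size ", pixel_size, " overrides sidecar value ", sc_px)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    read_tiff(path, pixel_size = pixel_size %||% sc_px)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_goldrim("goldrim_io_error", "PNG support needs the png package")
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    px <- pixel_size %||% sc_px
    if (is.null(px))
      stop_goldrim("goldrim_io_error",
                   "no pixel size for %s; supply one or a sidecar", path)
    projection_image(round(m * 255), px)
  } else {
    stop_goldrim("goldrim_io_error", "unsupported image format: %s", path)
  }
}
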