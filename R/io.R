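#' Image metadata record
#'
#' @param width_px,height_px image dimensions in pixels (>= 1).
#' @param dpi_x,dpi_y physical resolution in dots per inch (> 0);
#'   `dpi_y` defaults to `dpi_x`.
#' @return a one-row tibble of class `image_metadata`.
#' @export
image_metadata <- function(width_px, height_px, dpi_x, dpi_y = dpi_x) {
  if (width_px < 1 || height_px < 1)
    abort_ws("image dimensions must be >= 1 px", "ws_invalid_image")
  if (dpi_x <= 0 || dpi_y <= 0)
    abort_ws("DPI must be > 0", "ws_domain_error")
  out <- tibble::tibble(width_px = as.integer(width_px),
                        height_px = as.integer(height_px),
                        dpi_x = as.numeric(dpi_x), dpi_y = as.numeric(dpi_y))
  class(out) <- c("image_metadata", class(out))
  out
}

detect_format <- function(path) {
  magic <- readBin(path, "raw", 4)
  if (length(magic) >= 4 && identical(magic[1:4],
      as.raw(c(0x89, 0x50, 0x4e, 0x47)))) return("png")
  if (length(magic) >= 3 && identical(magic[1:3],
      as.raw(c(0xff, 0xd8, 0xff)))) return("jpeg")
  if (length(magic) >= 4 &&
      (identical(magic[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(magic[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))) return("tiff")
  abort_ws(sprintf("cannot decode '%s': not a PNG, JPEG or TIFF file", path),
           "ws_decode_error")
}

# decoded [0,1] array from png/jpeg/tiff -> 8-bit matrix/array, alpha dropped
to_uint8 <- function(px) {
  d <- dim(px)
  attributes(px) <- NULL                  # drop decoder metadata attributes
  dim(px) <- d
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 2) px <- px[, , 1, drop = TRUE]            # gray+alpha
    else if (dim(px)[3] >= 3) px <- px[, , 1:3, drop = FALSE]    # drop alpha
  }
  round_half_away(px * 255)
}

# JFIF APP0 density of a JPEG file: list(units, x, y) or NULL
read_jfif_density <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  u16 <- function(i) as.integer(b[i]) * 256L + as.integer(b[i + 1])
  i <- 3  # past SOI
  while (i + 3 <= length(b) && b[i] == as.raw(0xff)) {
    marker <- as.integer(b[i + 1])
    if (marker == 0xda || marker == 0xd9) break   # SOS / EOI: stop
    len <- u16(i + 2)
    if (marker == 0xe0 && len >= 16 &&
        identical(b[(i + 4):(i + 8)],
                  as.raw(c(0x4a, 0x46, 0x49, 0x46, 0x00)))) {
      return(list(units = as.integer(b[i + 11]),
                  x = u16(i + 12), y = u16(i + 14), at = i))
    }
    i <- i + 2 + len
  }
  NULL
}

#' Read a wound photograph with its physical-resolution metadata
#'
#' Decodes a PNG, JPEG or TIFF file (format detected from magic bytes) to
#' an 8-bit pixel grid and reads the physical resolution: the PNG pHYs
#' chunk (pixels per metre x 0.0254), the JPEG JFIF density field
#' (dots/inch directly, or dots/cm x 2.54), or the TIFF resolution tags
#' (282/283/296). A missing resolution is an error unless `dpi` supplies
#' an override -- the conversion to cm^2 is meaningless without it, so it
#' is never silently defaulted. EXIF fields (including orientation) are
#' ignored; pixels are used as stored.
#'
#' @param path file path.
#' @param dpi optional numeric override (single value or `c(x, y)`) used
#'   when the file carries no resolution metadata. An override always
#'   wins over absent metadata but file metadata, when present, is kept.
#' @return list with `pixels` (matrix or `h x w x 3` array, 0--255) and
#'   `meta` (an [image_metadata()] row).
#' @export
read_wound_image <- function(path, dpi = NULL) {
  if (!file.exists(path))
    abort_ws(sprintf("file not found: '%s'", path), "ws_decode_error")
  fmt <- detect_format(path)
  dx <- dy <- NA_real_
  if (fmt == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && all(info$dpi > 0)) {
      dx <- info$dpi[1]; dy <- info$dpi[length(info$dpi)]
    }
    px <- to_uint8(px)
  } else if (fmt == "jpeg") {
    px <- to_uint8(jpeg::readJPEG(path))
    dens <- read_jfif_density(path)
    if (!is.null(dens) && dens$x > 0 && dens$y > 0) {
      if (dens$units == 1) { dx <- dens$x; dy <- dens$y }
      else if (dens$units == 2) { dx <- dens$x * 2.54; dy <- dens$y * 2.54 }
    }
  } else {
    px <- tiff::readTIFF(path, info = TRUE)
    xr <- attr(px, "x.resolution"); yr <- attr(px, "y.resolution")
    unit <- attr(px, "resolution.unit")
    if (!is.null(xr) && !is.null(yr) && xr > 0 && yr > 0) {
      mult <- if (!is.null(unit) && identical(unit, "cm")) 2.54 else 1
      if (is.null(unit) || unit %in% c("inch", "cm")) {
        dx <- xr * mult; dy <- yr * mult
      }
    }
    px <- to_uint8(px)
  }
  if (is.na(dx) || is.na(dy)) {
    if (is.null(dpi))
      abort_ws(sprintf(
        "'%s' carries no resolution metadata; pass `dpi` explicitly", path),
        "ws_missing_dpi")
    dx <- dpi[1]; dy <- dpi[length(dpi)]
  }
  d <- dim(px)
  list(pixels = px, meta = image_metadata(d[2], d[1], dx, dy))
}

# minimal little-endian uncompressed TIFF writer carrying resolution tags
# (the installed TIFF writer cannot store them)
write_tiff_dpi <- function(path, px, dpi_x, dpi_y) {
  gray <- is.matrix(px)
  h <- nrow(px); w <- ncol(px); spp <- if (gray) 1L else 3L
  # interleaved row-major pixel bytes
  if (gray) {
    bytes <- as.raw(t(px))
  } else {
    a <- aperm(px, c(3, 2, 1))   # channel fastest, then column, then row
    bytes <- as.raw(as.vector(a))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42)
  strip_off <- 8L
  n_tags <- 12L
  ifd_off <- strip_off + length(bytes)
  w4(ifd_off)
  writeBin(bytes, con)
  post <- ifd_off + 2L + n_tags * 12L + 4L   # values stored after the IFD
  bps_off <- post; rat_x <- post + 6L; rat_y <- rat_x + 8L
  tag <- function(id, type, count, value, offset = FALSE) {
    w2(id); w2(type); w4(count)
    if (offset) w4(value)
    else if (type == 3) { w2(value); w2(0) }   # SHORT padded to 4 bytes
    else w4(value)
  }
  w2(n_tags)
  tag(256, 4, 1, w)                        # ImageWidth
  tag(257, 4, 1, h)                        # ImageLength
  if (gray) tag(258, 3, 1, 8)              # BitsPerSample
  else tag(258, 3, 3, bps_off, offset = TRUE)
  tag(259, 3, 1, 1)                        # Compression: none
  tag(262, 3, 1, if (gray) 1 else 2)       # Photometric
  tag(273, 4, 1, strip_off)                # StripOffsets
  tag(277, 3, 1, spp)                      # SamplesPerPixel
  tag(278, 4, 1, h)                        # RowsPerStrip
  tag(279, 4, 1, length(bytes))            # StripByteCounts
  tag(282, 5, 1, rat_x, offset = TRUE)     # XResolution
  tag(283, 5, 1, rat_y, offset = TRUE)     # YResolution
  tag(296, 3, 1, 2)                        # ResolutionUnit: inch
  w4(0)                                    # no next IFD
  w2(8); w2(8); w2(8)                      # BitsPerSample values (pos bps_off)
  w4(round(dpi_x * 10000)); w4(10000)      # XResolution rational
  w4(round(dpi_y * 10000)); w4(10000)      # YResolution rational
  invisible(path)
}

#' Write an image with physical-resolution metadata
#'
#' Writes PNG (pHYs chunk; pixels round-trip exactly, DPI to within the
#' integer pixels-per-metre granularity, < 0.1%), TIFF (uncompressed,
#' resolution tags 282/283/296, lossless), or JPEG (quality 0.95; the
#' JFIF density field stores integer dots per inch exactly, pixels are
#' lossy). The format follows the file extension.
#'
#' @param path output path ending in `.png`, `.tif(f)`, `.jpg` or
#'   `.jpeg`.
#' @param pixels grayscale matrix or `h x w x 3` array, values 0--255.
#' @param meta an [image_metadata()] row (or anything with `dpi_x`,
#'   `dpi_y`).
#' @return `path`, invisibly.
#' @export
write_wound_image <- function(path, pixels, meta) {
  ext <- tolower(tools::file_ext(path))
  px01 <- pixels / 255
  if (ext == "png") {
    png::writePNG(px01, path, dpi = c(meta$dpi_x, meta$dpi_y))
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff_dpi(path, pixels, meta$dpi_x, meta$dpi_y)
  } else if (ext %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(px01, path, quality = 0.95)
    patch_jfif_density(path, round(meta$dpi_x), round(meta$dpi_y))
  } else {
    abort_ws(sprintf("unsupported extension '.%s' (png, tiff, jpeg)", ext),
             "ws_format_error")
  }
  invisible(path)
}

# set the JFIF APP0 density of a freshly written JPEG to dots-per-inch
patch_jfif_density <- function(path, xdpi, ydpi) {
  b <- readBin(path, "raw", file.size(path))
  dens <- read_jfif_density(path)
  if (is.null(dens))
    abort_ws("JPEG written without a JFIF APP0 segment", "ws_format_error")
  i <- dens$at
  be16 <- function(v) as.raw(c(v %/% 256, v %% 256))
  b[i + 11] <- as.raw(1)                   # units: dots per inch
  b[(i + 12):(i + 13)] <- be16(xdpi)
  b[(i + 14):(i + 15)] <- be16(ydpi)
  writeBin(b, path)
  invisible(path)
}
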