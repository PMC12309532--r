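#' Calibrated 8-bit grayscale image
#'
#' The unit of all processing: a 2-D integer raster of 8-bit intensities
#' (0-255) together with the physical pixel size in micrometres per pixel
#' edge and a provenance string.
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`; rows are image
#'   rows (y), columns are image columns (x).
#' @param pixel_size Micrometres per pixel edge; strictly positive, finite.
#' @param source_id Provenance string (file path or generator seed tag).
#' @return An object of class `calibrated_image` with elements `pixels`,
#'   `pixel_size` and `source_id`.
#' @examples
#' img <- calibrated_image(matrix(0L, 4, 4), pixel_size = 0.5)
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, pixel_size, source_id = "<in-memory>") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("intensities must lie in [0, 255]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive finite number (um/pixel)")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         source_id = as.character(source_id)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, source: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$source_id))
  invisible(x)
}

#' Convert an RGB raster to 8-bit grayscale
#'
#' Collapses colour to intensity by the unweighted channel mean
#' `(R + G + B) / 3`, rounded half-up and clipped to `[0, 255]`; this is the
#' plain "8-bit" conversion convention for RGB micrographs. ITU-R BT.601
#' luma weights (0.299, 0.587, 0.114) are available for sensitivity
#' analysis. Grayscale input (a plain matrix) passes through unchanged.
#'
#' @param rgb Either a `height x width x 3` array with channel values in
#'   `[0, 255]`, or an already-8-bit grayscale matrix (returned as is).
#' @param weights `"mean"` (default) for the unweighted channel mean, or
#'   `"itu601"` for BT.601 luma weights.
#' @return Integer matrix of 8-bit intensities.
#' @examples
#' to_8bit_gray(array(c(30, 60, 90), dim = c(1, 1, 3)))  # -> 60
#' @export
to_8bit_gray <- function(rgb, weights = c("mean", "itu601")) {
  weights <- match.arg(weights)
  if (is.matrix(rgb)) {
    storage.mode(rgb) <- "integer"
    if (anyNA(rgb) || min(rgb) < 0L || max(rgb) > 255L)
      stop("grayscale intensities must lie in [0, 255]")
    return(rgb)
  }
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("`rgb` must be a height x width x 3 array or a grayscale matrix")
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stop("channel values must lie in [0, 255]")
  w <- if (weights == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  g <- rgb[, , 1] * w[1] + rgb[, , 2] * w[2] + rgb[, , 3] * w[3]
  g <- floor(g + 0.5)  # round half-up, documented so oracles match exactly
  matrix(as.integer(pmin(255, pmax(0, g))), dim(rgb)[1], dim(rgb)[2])
}

# pixel size (um/px) from readTIFF resolution attributes, or NULL
.pixel_size_from_tags <- function(info) {
  xres <- attr(info, "x.resolution")
  unit <- attr(info, "resolution.unit")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  if (is.null(unit)) return(NULL)
  um_per_unit <- switch(unit, cm = 10000, inch = 25400, NULL)
  if (is.null(um_per_unit)) return(NULL)
  # quantise to 1e-6 um: the package's writer stores calibration at that
  # precision, making write -> load round-trips exact
  round(um_per_unit / xres * 1e6) / 1e6
}

#' Read a slide image from TIFF with physical calibration
#'
#' Reads a grayscale or RGB TIFF, converts RGB to 8-bit grayscale via
#' [to_8bit_gray()], and establishes the micrometre-per-pixel calibration.
#' An explicit `pixel_size_override` always wins; otherwise the TIFF
#' resolution tags (pixels per cm or inch) are used; with neither, the read
#' fails rather than guessing, since a wrong pixel size silently corrupts
#' every physical-unit gate downstream. Of multi-page/pyramidal files only
#' the first (highest-resolution) page is read.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_override Optional micrometres per pixel; takes
#'   precedence over file metadata.
#' @param weights Colour-to-gray weights, see [to_8bit_gray()].
#' @return A [calibrated_image()].
#' @export
load_slide <- function(path, pixel_size_override = NULL,
                       weights = c("mean", "itu601")) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(
    tiff::readTIFF(path, info = TRUE, as.is = TRUE),
    error = function(e) stop("unsupported or unreadable TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.list(img)) img <- img[[1L]]  # multi-page: keep the first page
  # the reader rescales some encodings to [0, 1] doubles even with as.is
  if (is.double(img) && max(img) <= 1) img <- round(img * 255)
  if (!is.null(pixel_size_override)) {
    ps <- pixel_size_override
    if (!is.numeric(ps) || length(ps) != 1L || !is.finite(ps) || ps <= 0)
      stop("`pixel_size_override` must be a single positive number (um/px)")
  } else {
    ps <- .pixel_size_from_tags(img)
    if (is.null(ps))
      stop("no pixel-size calibration: '", path, "' carries no usable TIFF ",
           "resolution metadata and no `pixel_size_override` was given")
  }
  gray <- if (length(dim(img)) == 3L) {
    to_8bit_gray(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 weights = weights)
  } else {
    if (max(img) > 255L) stop("unsupported sample format: not 8-bit data in '",
                              path, "'")
    to_8bit_gray(matrix(as.integer(img), nrow(img), ncol(img)))
  }
  calibrated_image(gray, ps, source_id = path)
}

#' Write a calibrated image as a grayscale TIFF
#'
#' Writes a single-strip, uncompressed 8-bit grayscale TIFF with the pixel
#' size stored in the standard XResolution/YResolution rational tags
#' (resolution unit: cm), so that [load_slide()] recovers `pixels` and
#' `pixel_size` exactly. Calibration is stored to 1e-6 um precision.
#'
#' @param image A [calibrated_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  # pixels per cm as a rational; calibration quantised to 1e-6 um
  num0 <- 1e10; den0 <- round(image$pixel_size * 1e6)
  if (den0 < 1) stop("pixel size below the 1e-6 um calibration precision")
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  d <- gcd(num0, den0)
  rnum <- num0 / d; rden <- den0 / d
  if (rnum >= 2^32 || rden >= 2^32) {
    # reduced exact form overflows uint32: store pixels-per-cm to 1/1000
    rnum <- round(num0 / den0 * 1000); rden <- 1000
  }
  con <- file(path, "wb"); on.exit(close(con))
  w32 <- function(x) {  # unsigned 32-bit
    x <- ifelse(x >= 2^31, x - 2^32, x)
    writeBin(as.integer(x), con, size = 4, endian = "little")
  }
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)
  ntags <- 12L
  off_xres <- 8L + 2L + ntags * 12L + 4L
  off_yres <- off_xres + 8L
  off_data <- off_yres + 8L
  w16(ntags)
  tag <- function(id, type, count, value) {
    w16(id); w16(type); w32(count); w32(value)
  }
  tag(256, 4, 1, w)          # ImageWidth
  tag(257, 4, 1, h)          # ImageLength
  tag(258, 3, 1, 8)          # BitsPerSample
  tag(259, 3, 1, 1)          # Compression: none
  tag(262, 3, 1, 1)          # PhotometricInterpretation: BlackIsZero
  tag(273, 4, 1, off_data)   # StripOffsets
  tag(277, 3, 1, 1)          # SamplesPerPixel
  tag(278, 4, 1, h)          # RowsPerStrip
  tag(279, 4, 1, w * h)      # StripByteCounts
  tag(282, 5, 1, off_xres)   # XResolution
  tag(283, 5, 1, off_yres)   # YResolution
  tag(296, 3, 1, 3)          # ResolutionUnit: cm
  w32(0L)
  w32(rnum); w32(rden); w32(rnum); w32(rden)
  writeBin(as.raw(t(px)), con)  # row-major strip
  invisible(path)
}
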