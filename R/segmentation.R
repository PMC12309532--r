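#' Binary foreground mask
#'
#' Foreground (`TRUE`) marks adipocyte lumens. The mask keeps the source
#' image's dimensions and calibration, plus the intensity level that
#' produced it.
#'
#' @param pixels Logical matrix, `TRUE` = foreground.
#' @param pixel_size Micrometres per pixel, copied from the source image.
#' @param threshold_used Intensity level in `[0, 255]` that generated the
#'   mask.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size, threshold_used = NA_integer_) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  if (anyNA(pixels)) stop("mask must not contain NA")
  if (!is.na(threshold_used) &&
      (threshold_used < 0 || threshold_used > 255))
    stop("`threshold_used` must lie in [0, 255]")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         threshold_used = threshold_used),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d px, %.4g um/px, %.3g%% foreground, threshold %s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    100 * mean(x$pixels), format(x$threshold_used)))
  invisible(x)
}

#' Intensity histogram of a calibrated image
#'
#' @param image A [calibrated_image()].
#' @return Integer vector of 256 counts for intensities 0..255.
#' @export
image_histogram <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  tabulate(as.vector(image$pixels) + 1L, nbins = 256L)
}

#' Triangle (Zack) automatic threshold
#'
#' Geometric histogram thresholding: a line is drawn from the histogram
#' peak to the farthest nonzero bin on the peak's longer-tail side, and the
#' level returned is the bin whose histogram height lies at maximal
#' perpendicular distance below that line. The method adapts to staining
#' and illumination differences because only histogram shape matters,
#' which is why it suits batch processing of unevenly stained slides.
#'
#' Conventions (fixed so results are reproducible bit-for-bit): the peak is
#' the lowest modal bin; the tail side is whichever side of the peak has
#' the farther extreme nonzero bin, with exact ties resolved toward the
#' foreground side implied by `background` (bright for `"dark"`
#' backgrounds); distance ties along the line resolve to the lowest bin
#' index. The returned level `L` is meant for a strict comparison:
#' foreground is `intensity > L` on a dark background (see
#' [apply_threshold()]). A histogram with a single nonzero bin returns
#' that bin's index.
#'
#' @param histogram Integer vector of 256 non-negative counts
#'   (intensities 0..255), at least one nonzero.
#' @param background `"dark"` (bright foreground, the H&E lumen case) or
#'   `"bright"`.
#' @return Threshold level in `[0, 255]`.
#' @export
triangle_threshold <- function(histogram, background = c("dark", "bright")) {
  background <- match.arg(background)
  h <- as.numeric(histogram)
  if (length(h) != 256L || anyNA(h) || any(h < 0))
    stop("`histogram` must be 256 non-negative counts")
  nz <- which(h > 0)
  if (length(nz) == 0L) stop("degenerate histogram: all counts are zero")
  if (length(nz) == 1L) return(nz - 1L)
  peak <- which.max(h)  # lowest modal bin
  left <- peak - min(nz)
  right <- max(nz) - peak
  tail <- if (right > left) max(nz)
    else if (left > right) min(nz)
    else if (background == "dark") max(nz) else min(nz)
  if (tail == peak) return(peak - 1L)
  between <- if (peak < tail) (peak + 1L):(tail - 1L) else (tail + 1L):(peak - 1L)
  if (length(between) == 0L) return(min(peak, tail) - 1L)
  # perpendicular distance from (b, h[b]) to the peak->tail line
  x1 <- peak; y1 <- h[peak]; x2 <- tail; y2 <- h[tail]
  d <- abs((y2 - y1) * between - (x2 - x1) * h[between] +
             x2 * y1 - y2 * x1) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  between[which.max(d)] - 1L  # which.max takes the lowest index on ties
}

#' Apply an intensity threshold to a calibrated image
#'
#' With a dark background, pixels strictly greater than `level` become
#' foreground (bright lipid lumens); the comparison flips to strictly less
#' than `level` for a bright background.
#'
#' @param image A [calibrated_image()].
#' @param level Intensity level in `[0, 255]`.
#' @param background `"dark"` or `"bright"`.
#' @return A [binary_mask()] with `threshold_used = level`.
#' @export
apply_threshold <- function(image, level, background = c("dark", "bright")) {
  background <- match.arg(background)
  stopifnot(inherits(image, "calibrated_image"))
  if (level < 0 || level > 255) stop("`level` must lie in [0, 255]")
  fg <- if (background == "dark") image$pixels > level else image$pixels < level
  binary_mask(fg, image$pixel_size, threshold_used = as.integer(level))
}

#' Binary erosion with a 3x3 square structuring element
#'
#' Out-of-bounds neighbours count as background, so foreground touching the
#' image border always erodes. One iteration mirrors one "Erode" pass of
#' the slide-processing recipe.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param iterations Number of erosion passes (default 1).
#' @return Same type as `mask`.
#' @export
erode <- function(mask, iterations = 1L) {
  if (iterations < 1L) stop("`iterations` must be >= 1")
  if (inherits(mask, "binary_mask")) {
    out <- cpp_erode(mask$pixels, as.integer(iterations))
    binary_mask(out, mask$pixel_size, mask$threshold_used)
  } else {
    cpp_erode(mask, as.integer(iterations))
  }
}

#' Remove bright or dark outlier pixels by circular-median comparison
#'
#' For every pixel, the median over the disk neighbourhood of the given
#' radius (offsets at Euclidean distance <= radius, centre included;
#' radius 2.5 px -> 21-pixel kernel, 5.5 px -> 97-pixel kernel) is
#' computed, clamping the neighbourhood at image borders. A pixel is
#' replaced by that median only when it deviates from it by more than
#' `threshold` in the stated direction, which despeckles noise while
#' leaving coherent structures untouched. Even-sized border neighbourhoods
#' use the lower median.
#'
#' @param pixels Integer matrix of 8-bit intensities, or a
#'   [calibrated_image()].
#' @param radius Neighbourhood radius in pixels (> 0).
#' @param threshold Intensity deviation in `[0, 255]` beyond which a pixel
#'   is replaced.
#' @param which `"bright"` removes pixels brighter than their local median;
#'   `"dark"` the reverse.
#' @return Same type as `pixels`.
#' @export
remove_outliers <- function(pixels, radius, threshold = 50,
                            which = c("bright", "dark")) {
  which <- match.arg(which)
  if (radius <= 0) stop("`radius` must be > 0")
  if (threshold < 0 || threshold > 255) stop("`threshold` must lie in [0, 255]")
  if (inherits(pixels, "calibrated_image")) {
    out <- cpp_remove_outliers(pixels$pixels, radius, threshold,
                               which == "bright")
    calibrated_image(out, pixels$pixel_size, pixels$source_id)
  } else {
    m <- pixels
    storage.mode(m) <- "integer"
    cpp_remove_outliers(m, radius, threshold, which == "bright")
  }
}

#' Segmentation parameters
#'
#' Defaults reproduce the fixed whole-slide recipe: triangle threshold with
#' dark background, then erode, remove bright outliers (radius 2.5 px,
#' threshold 50), erode again, and remove bright outliers (radius 5.5 px,
#' threshold 50).
#'
#' @param erode_iterations_per_pass Erosion passes per erode step.
#' @param outlier_pass_radii Radii (px) of successive outlier-removal
#'   passes.
#' @param outlier_threshold Intensity deviation for outlier replacement.
#' @param outlier_which `"bright"` or `"dark"`.
#' @param background Threshold polarity; `"dark"` makes bright lumens
#'   foreground.
#' @param manual_threshold_override Optional manual level in `[0, 255]`
#'   bypassing the automatic threshold.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(erode_iterations_per_pass = 1L,
                       outlier_pass_radii = c(2.5, 5.5),
                       outlier_threshold = 50,
                       outlier_which = c("bright", "dark"),
                       background = c("dark", "bright"),
                       manual_threshold_override = NULL) {
  outlier_which <- match.arg(outlier_which)
  background <- match.arg(background)
  if (any(outlier_pass_radii <= 0)) stop("radii must be positive")
  if (outlier_threshold < 0 || outlier_threshold > 255)
    stop("`outlier_threshold` must lie in [0, 255]")
  if (!is.null(manual_threshold_override) &&
      (manual_threshold_override < 0 || manual_threshold_override > 255))
    stop("`manual_threshold_override` must lie in [0, 255]")
  structure(
    list(erode_iterations_per_pass = as.integer(erode_iterations_per_pass),
         outlier_pass_radii = outlier_pass_radii,
         outlier_threshold = outlier_threshold,
         outlier_which = outlier_which,
         background = background,
         manual_threshold_override = manual_threshold_override),
    class = "seg_params"
  )
}

#' Segment adipocyte lumens from a calibrated grayscale image
#'
#' Runs the full fixed operator sequence: automatic triangle threshold (or
#' the manual override), strict thresholding, one erosion, outlier removal
#' at the first radius, a second erosion, and outlier removal at the second
#' radius. Between morphological steps the mask is handled as an 0/255
#' 8-bit raster so the outlier filter sees the same data a generic
#' median-despeckle pass would.
#'
#' @param image A [calibrated_image()].
#' @param params A [seg_params()] object.
#' @return A [binary_mask()] of lumen foreground; `threshold_used` records
#'   the automatic or manual level.
#' @export
segment <- function(image, params = seg_params()) {
  stopifnot(inherits(image, "calibrated_image"), inherits(params, "seg_params"))
  level <- if (!is.null(params$manual_threshold_override)) {
    as.integer(params$manual_threshold_override)
  } else {
    triangle_threshold(image_histogram(image), background = params$background)
  }
  mask <- apply_threshold(image, level, background = params$background)
  fg <- mask$pixels
  for (radius in params$outlier_pass_radii) {
    fg <- cpp_erode(fg, params$erode_iterations_per_pass)
    raster <- matrix(0L, nrow(fg), ncol(fg))
    raster[fg] <- 255L
    raster <- cpp_remove_outliers(raster, radius, params$outlier_threshold,
                                  params$outlier_which == "bright")
    fg <- raster > 127L
  }
  binary_mask(fg, image$pixel_size, threshold_used = as.integer(level))
}
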