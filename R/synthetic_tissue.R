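#' Parameters for the synthetic adipose-tissue generator
#'
#' Describes an H&E-like appearance model: bright near-circular lipid
#' lumens separated by thin dark membranes, degraded by Gaussian staining
#' noise and a linear illumination gradient. Default sizes emulate human
#' white adipose tissue at 20x scanning (0.5 um/px) with diameters drawn
#' from a truncated normal around 65 +/- 10 um, bounded by the 20-225 um
#' window the particle gates imply.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_cells Target number of cells to place.
#' @param diameter_mean,diameter_sd Mean and SD (um) of the truncated
#'   normal diameter distribution.
#' @param diameter_min,diameter_max Truncation bounds (um), `min < max`.
#' @param membrane_thickness Minimum membrane (inter-lumen) thickness in
#'   um.
#' @param lumen_intensity,membrane_intensity Mean 8-bit levels of lumens
#'   and of membrane/stroma background.
#' @param noise_sd Gaussian intensity noise SD.
#' @param illumination_gradient Fractional edge-to-edge intensity change
#'   across the image width (0 = uniform illumination).
#' @param damaged_fraction Proportion of cells rendered with a membrane
#'   breach toward a neighbour, merging lumens as collapsed membranes do in
#'   damaged tissue.
#' @param harmonic_amplitude Maximum relative amplitude of the low-order
#'   radial harmonics perturbing each cell outline (<= 0.1 keeps
#'   circularity realistic, near but below 1).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(width = 4000L, height = 4000L, pixel_size = 0.5,
                          n_cells = 300L, diameter_mean = 65,
                          diameter_sd = 10, diameter_min = 20,
                          diameter_max = 225, membrane_thickness = 2.5,
                          lumen_intensity = 220, membrane_intensity = 90,
                          noise_sd = 8, illumination_gradient = 0.1,
                          damaged_fraction = 0.05,
                          harmonic_amplitude = 0.05, seed = 1L) {
  stopifnot(width >= 1, height >= 1, pixel_size > 0, n_cells >= 0,
            diameter_min > 0, diameter_min < diameter_max, diameter_sd >= 0,
            membrane_thickness >= 0, damaged_fraction >= 0,
            damaged_fraction <= 1, harmonic_amplitude >= 0,
            harmonic_amplitude <= 0.5)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size = pixel_size, n_cells = as.integer(n_cells),
         diameter_mean = diameter_mean, diameter_sd = diameter_sd,
         diameter_min = diameter_min, diameter_max = diameter_max,
         membrane_thickness = membrane_thickness,
         lumen_intensity = lumen_intensity,
         membrane_intensity = membrane_intensity, noise_sd = noise_sd,
         illumination_gradient = illumination_gradient,
         damaged_fraction = damaged_fraction,
         harmonic_amplitude = harmonic_amplitude, seed = as.integer(seed)),
    class = "tissue_params"
  )
}

# truncated normal via inverse-CDF sampling
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic adipose-tissue image with known ground truth
#'
#' Places non-overlapping near-circular cells by dart throwing (minimum
#' centre separation: sum of radii plus membrane thickness), largest
#' first, with diameters drawn from the configured truncated normal.
#' Lumens render bright over a membrane-intensity background; each outline
#' is perturbed by low-order radial harmonics so circularity spans
#' realistic values just below 1. A fraction of cells get a membrane
#' breach: a lumen-bright corridor to the nearest cell, fusing the pair
#' into one oversized blob the way collapsed membranes do (both cells are
#' flagged damaged). Finally a linear illumination gradient and Gaussian
#' noise are applied. Output is deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' If dart throwing cannot place all `n_cells` within the attempt budget
#' (200 per cell) the image is returned with fewer cells and the shortfall
#' is recorded in `attr(truth, "placement_shortfall")`.
#'
#' @param params A [tissue_params()].
#' @param rgb If `TRUE`, return an H&E-coloured `height x width x 3` array
#'   (pinkish membranes, near-white lumens) instead of a grayscale
#'   [calibrated_image()]; useful for exercising colour-to-gray
#'   conversion.
#' @return List with `image` (a [calibrated_image()], or an RGB array when
#'   `rgb = TRUE`) and `truth`, a data frame with one row per placed cell:
#'   `cell_id`, `x_px`, `y_px` (1-based pixel coordinates of the centre),
#'   `diameter_um`, `damaged`, `interior` (fully inside the image).
#'   `truth` carries attributes `params` and `seed`.
#' @export
generate_tissue <- function(params = tissue_params(), rgb = FALSE) {
  stopifnot(inherits(params, "tissue_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    saved <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", saved, envir = globalenv()))
  }
  set.seed(params$seed)
  W <- params$width; H <- params$height; ps <- params$pixel_size
  memb_px <- params$membrane_thickness / ps
  n <- params$n_cells
  d_um <- sort(.rtruncnorm(n, params$diameter_mean, params$diameter_sd,
                           params$diameter_min, params$diameter_max),
               decreasing = TRUE)  # largest first packs more reliably
  r_px <- d_um / 2 / ps
  cx <- numeric(0); cy <- numeric(0); rr <- numeric(0); dd <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      x <- runif(1, 1, W); y <- runif(1, 1, H)
      if (length(cx) == 0 ||
          all((cx - x)^2 + (cy - y)^2 >= (rr + r_px[i] + memb_px)^2)) {
        cx <- c(cx, x); cy <- c(cy, y)
        rr <- c(rr, r_px[i]); dd <- c(dd, d_um[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  k <- length(cx)
  img <- matrix(params$membrane_intensity, H, W)
  amp <- params$harmonic_amplitude
  a2 <- runif(k, 0, amp); a3 <- runif(k, 0, amp)
  ph2 <- runif(k, 0, 2 * pi); ph3 <- runif(k, 0, 2 * pi)
  for (i in seq_len(k)) {
    rmax <- rr[i] * (1 + a2[i] + a3[i]) + 1
    x0 <- max(1L, floor(cx[i] - rmax)); x1 <- min(W, ceiling(cx[i] + rmax))
    y0 <- max(1L, floor(cy[i] - rmax)); y1 <- min(H, ceiling(cy[i] + rmax))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- matrix(xs - cx[i], length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys - cy[i], length(ys), length(xs))
    theta <- atan2(dy, dx)
    redge <- rr[i] * (1 + a2[i] * cos(2 * theta + ph2[i]) +
                        a3[i] * cos(3 * theta + ph3[i]))
    inside <- dx * dx + dy * dy <= redge * redge
    block <- img[ys, xs, drop = FALSE]
    block[inside] <- params$lumen_intensity
    img[ys, xs] <- block
  }
  damaged <- rep(FALSE, k)
  n_dam <- round(params$damaged_fraction * k)
  if (n_dam > 0 && k >= 2) {
    breach <- sample.int(k, n_dam)
    for (i in breach) {
      others <- setdiff(seq_len(k), i)
      j <- others[which.min((cx[others] - cx[i])^2 + (cy[others] - cy[i])^2)]
      damaged[c(i, j)] <- TRUE
      # lumen-bright corridor between the two centres
      steps <- ceiling(2 * sqrt((cx[j] - cx[i])^2 + (cy[j] - cy[i])^2))
      tfrac <- seq(0, 1, length.out = max(2L, steps))
      px <- cx[i] + tfrac * (cx[j] - cx[i])
      py <- cy[i] + tfrac * (cy[j] - cy[i])
      half <- max(1, round(0.15 * min(rr[i], rr[j])))
      for (o in -half:half) {
        xs <- pmin(W, pmax(1, round(px + o)))
        ys <- pmin(H, pmax(1, round(py)))
        img[cbind(ys, xs)] <- params$lumen_intensity
        xs <- pmin(W, pmax(1, round(px)))
        ys <- pmin(H, pmax(1, round(py + o)))
        img[cbind(ys, xs)] <- params$lumen_intensity
      }
    }
  }
  if (params$illumination_gradient != 0) {
    ramp <- 1 + params$illumination_gradient *
      ((seq_len(W) - 1) / max(1, W - 1) - 0.5)
    img <- sweep(img, 2, ramp, `*`)
  }
  if (params$noise_sd > 0) img <- img + rnorm(length(img), 0, params$noise_sd)
  img <- matrix(as.integer(pmin(255, pmax(0, floor(img + 0.5)))), H, W)
  truth <- data.frame(
    cell_id = seq_len(k), x_px = cx, y_px = cy, diameter_um = dd,
    damaged = damaged,
    interior = cx - rr >= 1 & cx + rr <= W & cy - rr >= 1 & cy + rr <= H)
  attr(truth, "params") <- params
  attr(truth, "seed") <- params$seed
  attr(truth, "placement_shortfall") <- n - k
  source_id <- sprintf("synthetic-seed-%d", params$seed)
  image <- if (rgb) {
    gr <- as.numeric(img)
    arr <- array(0L, dim = c(H, W, 3L))
    arr[, , 1] <- as.integer(pmin(255, pmax(0, floor(gr + 35 + 0.5))))
    arr[, , 2] <- as.integer(pmin(255, pmax(0, floor(gr * 0.62 + 0.5))))
    arr[, , 3] <- as.integer(pmin(255, pmax(0, floor(gr * 0.80 + 0.5))))
    arr
  } else {
    calibrated_image(img, ps, source_id = source_id)
  }
  list(image = image, truth = truth)
}

#' Match detected particles to generator ground truth
#'
#' Greedy one-to-one nearest-centroid matching under a distance cap:
#' repeatedly pair the globally closest unmatched (particle, true cell)
#' whose centre distance is at most `max_centroid_distance`.
#'
#' @param particles Particle table (typically the retained rows from
#'   [filter_particles()]) with `centroid_x`, `centroid_y` (px) and
#'   `area_um2`.
#' @param truth Ground-truth table from [generate_tissue()].
#' @param pixel_size Micrometres per pixel of the analysed image.
#' @param max_centroid_distance Matching cap in um (default 15).
#' @return List: `matches` (columns `cell_id`, `label`, `distance_um`,
#'   `true_diameter_um`, `measured_diameter_um`, `error_um`), `recall`,
#'   `precision` (`NA` when no particles were supplied),
#'   `mean_signed_error_um`, `mean_abs_error_um`.
#' @export
match_to_ground_truth <- function(particles, truth, pixel_size,
                                  max_centroid_distance = 15) {
  if (!is.null(particles$retained)) particles <- particles[particles$retained, ]
  np <- nrow(particles); nt <- nrow(truth)
  empty <- data.frame(cell_id = integer(), label = integer(),
                      distance_um = numeric(), true_diameter_um = numeric(),
                      measured_diameter_um = numeric(), error_um = numeric())
  if (np == 0L || nt == 0L) {
    return(list(matches = empty, recall = if (nt > 0) 0 else NA_real_,
                precision = if (np > 0) 0 else NA_real_,
                mean_signed_error_um = NA_real_,
                mean_abs_error_um = NA_real_))
  }
  dx <- outer(truth$x_px, particles$centroid_x, `-`)
  dy <- outer(truth$y_px, particles$centroid_y, `-`)
  dist_um <- sqrt(dx^2 + dy^2) * pixel_size
  dist_um[dist_um > max_centroid_distance] <- Inf
  ti <- integer(0); pj <- integer(0); dm <- numeric(0)
  while (any(is.finite(dist_um))) {
    idx <- arrayInd(which.min(dist_um), dim(dist_um))
    ti <- c(ti, idx[1]); pj <- c(pj, idx[2])
    dm <- c(dm, dist_um[idx[1], idx[2]])
    dist_um[idx[1], ] <- Inf
    dist_um[, idx[2]] <- Inf
  }
  meas <- area_to_diameter(particles$area_um2[pj])
  matches <- data.frame(
    cell_id = truth$cell_id[ti], label = particles$label[pj],
    distance_um = dm, true_diameter_um = truth$diameter_um[ti],
    measured_diameter_um = meas,
    error_um = meas - truth$diameter_um[ti])
  list(matches = matches,
       recall = nrow(matches) / nt,
       precision = nrow(matches) / np,
       mean_signed_error_um = mean(matches$error_um),
       mean_abs_error_um = mean(abs(matches$error_um)))
}
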