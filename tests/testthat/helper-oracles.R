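# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. Deliberately naive and separate from the package
# code paths.

# triangle threshold: direct perpendicular-distance maximisation over bins
oracle_triangle <- function(h, background = "dark") {
  h <- as.numeric(h)
  nz <- which(h > 0)
  if (length(nz) == 1L) return(nz - 1L)
  peak <- which.max(h)
  left <- peak - min(nz); right <- max(nz) - peak
  tail <- if (right > left) max(nz) else if (left > right) min(nz)
    else if (background == "dark") max(nz) else min(nz)
  if (tail == peak) return(peak - 1L)
  lo <- min(peak, tail); hi <- max(peak, tail)
  if (hi - lo < 2L) return(lo - 1L)
  cand <- (lo + 1L):(hi - 1L)
  # distance of point p to segment line through a, b via normalised normal
  a <- c(peak, h[peak]); b <- c(tail, h[tail])
  nvec <- c(-(b[2] - a[2]), b[1] - a[1])
  nvec <- nvec / sqrt(sum(nvec^2))
  d <- vapply(cand, function(bin) abs(sum((c(bin, h[bin]) - a) * nvec)), 0)
  cand[which.max(d)] - 1L
}

# 3x3 erosion: per-pixel minimum over the padded neighbourhood
oracle_erode <- function(m, iterations = 1L) {
  for (it in seq_len(iterations)) {
    H <- nrow(m); W <- ncol(m)
    p <- matrix(FALSE, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- m
    out <- matrix(FALSE, H, W)
    for (r in 1:H) for (c in 1:W)
      out[r, c] <- all(p[r:(r + 2), c:(c + 2)])
    m <- out
  }
  m
}

# circular-median outlier removal: per-pixel gather + lower median
oracle_remove_outliers <- function(img, radius, threshold, which = "bright") {
  H <- nrow(img); W <- ncol(img)
  R <- floor(radius)
  offs <- expand.grid(dr = -R:R, dc = -R:R)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- img
  for (r in 1:H) for (c in 1:W) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    v <- img[cbind(rr[ok], cc[ok])]
    med <- sort(v)[floor((length(v) - 1) / 2) + 1]
    x <- img[r, c]
    if (which == "bright" && x - med > threshold) out[r, c] <- med
    if (which == "dark" && med - x > threshold) out[r, c] <- med
  }
  out
}

# connected components by BFS flood fill in raster order
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (r in 1:H) for (c in 1:W) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# rasterised disk mask: pixels whose centre lies within `radius` of centre
disk_mask <- function(radius, pad = 3L) {
  n <- 2L * ceiling(radius) + 2L * pad + 1L
  ctr <- (n + 1) / 2
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)
  d2 <= radius^2
}

random_mask <- function(h = 64L, w = 64L, p = 0.5) {
  matrix(runif(h * w) < p, h, w)
}

random_image <- function(h = 64L, w = 64L) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# bimodal intensity histogram with noisy peaks
random_bimodal_hist <- function() {
  lo <- sample(30:90, 1); hi <- sample(150:230, 1)
  x <- c(round(rnorm(3000, lo, sample(5:15, 1))),
         round(rnorm(sample(c(500, 1500, 5000), 1), hi, sample(5:15, 1))))
  tabulate(pmin(255, pmax(0, x)) + 1L, nbins = 256L)
}

# small synthetic slide for pipeline-level tests
small_tissue <- function(seed, n_cells = 40L, width = 1000L, height = 1000L,
                         diameter_mean = 45, diameter_sd = 6,
                         damaged_fraction = 0, noise_sd = 8) {
  generate_tissue(tissue_params(
    width = width, height = height, pixel_size = 0.5, n_cells = n_cells,
    diameter_mean = diameter_mean, diameter_sd = diameter_sd,
    damaged_fraction = damaged_fraction, noise_sd = noise_sd, seed = seed))
}

# QC-band fixture: 2000x2000 px, 40 +/- 6 um cells, no damage
qc_fixture_params <- function(n_cells, seed) {
  tissue_params(width = 2000L, height = 2000L, pixel_size = 0.5,
                n_cells = n_cells, diameter_mean = 40, diameter_sd = 6,
                damaged_fraction = 0, seed = seed)
}
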