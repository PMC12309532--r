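test_that("triangle threshold separates two spike populations", {
  h <- integer(256); h[51] <- 1000L; h[201] <- 1000L  # intensities 50, 200
  lvl <- triangle_threshold(h, "dark")
  expect_gt(lvl, 50)
  expect_lt(lvl, 200)
})

test_that("triangle threshold degenerate cases", {
  h <- integer(256); h[101] <- 42L
  expect_equal(triangle_threshold(h), 100)
  expect_error(triangle_threshold(integer(256)), "degenerate")
  expect_error(triangle_threshold(1:10), "256")
})

test_that("triangle threshold matches the brute-force geometry and is
           invariant to uniform count scaling", {
  set.seed(101)
  for (i in 1:40) {
    h <- random_bimodal_hist()
    lvl <- triangle_threshold(h, "dark")
    expect_identical(lvl, oracle_triangle(h, "dark"))
    expect_identical(triangle_threshold(h * 7L, "dark"), lvl)
  }
})

test_that("thresholding is strict and polarity-aware", {
  img <- calibrated_image(matrix(10L, 4, 4), 1)
  expect_true(all(apply_threshold(img, 5, "dark")$pixels))
  expect_false(any(apply_threshold(img, 10, "dark")$pixels))
  expect_true(all(apply_threshold(img, 11, "bright")$pixels))
  two <- calibrated_image(matrix(c(40L, 220L), 10, 10), 1)
  lvl <- triangle_threshold(image_histogram(two), "dark")
  expect_identical(apply_threshold(two, lvl, "dark")$pixels, two$pixels > lvl)
})

test_that("erosion removes specks, keeps 3x3 centre, never grows", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  expect_false(any(erode(m)))
  m2 <- matrix(FALSE, 7, 7); m2[3:5, 3:5] <- TRUE
  e <- erode(m2)
  expect_identical(which(e), which(matrix(seq_len(49), 7, 7) == 25))
  set.seed(5)
  for (i in 1:10) {
    m3 <- random_mask()
    expect_lte(sum(erode(m3)), sum(m3))
  }
})

test_that("N erosions of an M-wide bar leave max(M - 2N, 0) width", {
  for (M in c(3L, 5L, 8L)) for (N in 1:4) {
    bar <- matrix(FALSE, 30, 30)
    bar[3:28, 10:(9 + M)] <- TRUE
    widths <- rowSums(erode(bar, N))
    expect_equal(max(widths), max(M - 2 * N, 0))
  }
})

test_that("erosion matches the per-pixel neighbourhood-minimum oracle", {
  set.seed(11)
  for (i in 1:15) {
    m <- random_mask()
    expect_identical(erode(m), oracle_erode(m))
  }
})

test_that("outlier removal despeckles but preserves coherent structure", {
  img <- matrix(0L, 20, 20); img[10, 10] <- 255L
  out <- remove_outliers(img, 2.5, 50, "bright")
  expect_equal(out[10, 10], 0L)
  block <- matrix(0L, 40, 40); block[11:30, 11:30] <- 255L
  out <- remove_outliers(block, 2.5, 50, "bright")
  # interior and straight edges keep their local median of 255; only the
  # four single-pixel corners see a background-dominated neighbourhood
  corners <- cbind(c(11, 11, 30, 30), c(11, 30, 11, 30))
  expect_identical(out[-(corners[, 1] + 40 * (corners[, 2] - 1))],
                   block[-(corners[, 1] + 40 * (corners[, 2] - 1))])
  expect_true(all(out[corners] == 0L))
})

test_that("outlier removal is one-sided: bright never raises, dark never
           lowers", {
  set.seed(21)
  for (i in 1:10) {
    img <- random_image(32, 32)
    expect_true(all(remove_outliers(img, 2.5, 30, "bright") <= img))
    expect_true(all(remove_outliers(img, 2.5, 30, "dark") >= img))
  }
})

test_that("outlier removal matches the brute-force circular-median oracle", {
  set.seed(31)
  for (i in 1:6) {
    img <- matrix(sample(c(0L, 255L), 64 * 64, TRUE), 64, 64)
    expect_identical(remove_outliers(img, 5.5, 50, "bright"),
                     oracle_remove_outliers(img, 5.5, 50, "bright"))
    img2 <- random_image(40, 40)
    expect_identical(remove_outliers(img2, 2.5, 40, "dark"),
                     oracle_remove_outliers(img2, 2.5, 40, "dark"))
  }
})

test_that("disk kernel sizes match the Euclidean membership rule", {
  count_kernel <- function(radius) {
    R <- floor(radius)
    sum(outer((-R):R, (-R):R, function(a, b) a^2 + b^2) <= radius^2)
  }
  expect_equal(count_kernel(2.5), 21)
  expect_equal(count_kernel(5.5), 97)
})

test_that("segment composes the fixed operator sequence deterministically", {
  gen <- small_tissue(seed = 301)
  m1 <- segment(gen$image)
  m2 <- segment(gen$image)
  expect_identical(m1$pixels, m2$pixels)
  expect_identical(m1$threshold_used, m2$threshold_used)
  # manual override bypasses the automatic threshold
  mo <- segment(gen$image, seg_params(manual_threshold_override = 150))
  expect_identical(mo$threshold_used, 150L)
  same <- segment(gen$image,
                  seg_params(manual_threshold_override = m1$threshold_used))
  expect_identical(same$pixels, m1$pixels)
})

test_that("segment survives blank input and recovers known lumens", {
  blank <- calibrated_image(matrix(128L, 64, 64), 0.5)
  mb <- segment(blank)
  expect_false(any(mb$pixels))
  # per-cell overlap against ground truth on a clean fixture
  gen <- small_tissue(seed = 302, n_cells = 30L)
  mask <- segment(gen$image)
  tr <- gen$truth[!gen$truth$damaged & gen$truth$interior, ]
  jac <- vapply(seq_len(nrow(tr)), function(i) {
    r <- tr$diameter_um[i] / 2 / 0.5
    xs <- pmax(1, floor(tr$x_px[i] - r - 4)):pmin(1000, ceiling(tr$x_px[i] + r + 4))
    ys <- pmax(1, floor(tr$y_px[i] - r - 4)):pmin(1000, ceiling(tr$y_px[i] + r + 4))
    dx <- matrix(xs - tr$x_px[i], length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys - tr$y_px[i], length(ys), length(xs))
    truecell <- dx^2 + dy^2 <= r^2
    got <- mask$pixels[ys, xs]
    sum(truecell & got) / sum(truecell | got)
  }, 0)
  expect_gte(median(jac), 0.7)
  expect_gte(mean(jac >= 0.5), 0.9)
})
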