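test_that("equivalent circular diameter: gates and circle identity", {
  expect_equal(area_to_diameter(315), 20.027, tolerance = 1e-4)
  expect_equal(area_to_diameter(40000), 225.676, tolerance = 1e-5)
  expect_equal(area_to_diameter(pi * 25^2), 50)
  d <- seq(5, 250, by = 5)
  expect_equal(area_to_diameter(pi * (d / 2)^2), d)       # inverse identity
  expect_true(all(diff(area_to_diameter(seq(10, 5e4, 100))) > 0))
  expect_error(area_to_diameter(0), "positive")
  expect_error(area_to_diameter(-3), "positive")
})

test_that("cell-count QC gate bands and monotonicity", {
  expect_identical(qc_gate(c(95, 150, 500)),
                   c("excluded", "inspect", "ok"))
  expect_identical(qc_gate(c(99, 100, 199, 200)),
                   c("excluded", "inspect", "inspect", "ok"))
  rank <- c(excluded = 0, inspect = 1, ok = 2)
  expect_true(all(diff(rank[qc_gate(0:400)]) >= 0))
})

test_that("sample summary: mean, n-1 SD and QC from retained particles", {
  p <- data.frame(area_um2 = pi * (c(60, 70, 80) / 2)^2, retained = TRUE)
  m <- summarize_sample("s1", "omental", p)
  expect_equal(m$mean_diameter, 70)
  expect_equal(m$sd_diameter, 10)
  expect_equal(m$n_cells, 3L)
  expect_identical(m$qc_status, "excluded")  # 3 cells is far below 100
  empty <- summarize_sample("s2", "omental", p[0, ])
  expect_equal(empty$n_cells, 0L)
  expect_identical(empty$qc_status, "excluded")
  expect_true(is.na(empty$mean_diameter))
  const <- data.frame(area_um2 = rep(2000, 500), retained = TRUE)
  mc <- summarize_sample("s3", "sc", const)
  expect_equal(mc$mean_diameter, area_to_diameter(2000))
  expect_equal(mc$sd_diameter, 0)
  expect_identical(mc$qc_status, "ok")
})

test_that("consolidate keeps excluded rows but blanks their summaries", {
  mk <- function(id, n) summarize_sample(
    id, "omental",
    data.frame(area_um2 = rep(3000, n), retained = TRUE))
  out <- consolidate(list(mk("a", 250), mk("b", 150), mk("c", 40)))
  expect_equal(nrow(out$summary), 3)
  expect_identical(out$summary$qc_status, c("ok", "inspect", "excluded"))
  expect_true(is.na(out$summary$mean_diameter_um[3]))
  expect_false(anyNA(out$summary$mean_diameter_um[1:2]))
  expect_identical(unique(out$diameters$sample_id), c("a", "b"))
  expect_equal(nrow(out$diameters), 400)
  # empty input and duplicate ids
  expect_equal(nrow(consolidate(list())$summary), 0)
  expect_error(consolidate(list(mk("a", 10), mk("a", 10))), "duplicate")
})

test_that("manual rethresholding reruns the pipeline and flags the result", {
  gen <- small_tissue(seed = 303, n_cells = 25L)
  auto <- analyze_slide(gen$image, sample_id = "s")
  # level 255 on a dark-background threshold gives an empty mask
  dead <- rethreshold_sample(gen$image, 255, sample_id = "s")
  expect_equal(dead$measurement$n_cells, 0L)
  expect_identical(dead$measurement$qc_status, "excluded")
  # re-running at the automatic level reproduces the automatic result
  same <- rethreshold_sample(gen$image, auto$mask$threshold_used,
                             sample_id = "s")
  expect_identical(same$particles$area_um2, auto$particles$area_um2)
  expect_true(same$measurement$rethresholded)
  expect_false(auto$measurement$rethresholded)
})

test_that("manual threshold can rescue a slide the automatic level misses", {
  # low-contrast slide (faint lumens just above the stroma) with a large
  # saturated artefact: the saturation spike captures the histogram peak,
  # the automatic level lands just under 255 and misses every lumen
  gen <- generate_tissue(tissue_params(
    width = 2000L, height = 2000L, pixel_size = 0.5, n_cells = 230L,
    diameter_mean = 40, diameter_sd = 6, lumen_intensity = 130,
    membrane_intensity = 95, noise_sd = 4, illumination_gradient = 0,
    damaged_fraction = 0, seed = 305))
  px <- gen$image$pixels
  px[1:700, 1:700] <- 255L  # saturated artefact (torn/empty region)
  img <- calibrated_image(px, 0.5, "faint")
  auto <- analyze_slide(img, sample_id = "faint")
  manual <- rethreshold_sample(img, 112, sample_id = "faint")
  expect_lt(auto$measurement$n_cells, 100)
  expect_identical(auto$measurement$qc_status, "excluded")
  expect_gte(manual$measurement$n_cells, 200)
  expect_identical(manual$measurement$qc_status, "ok")
  expect_true(manual$measurement$rethresholded)
})

test_that("run_batch writes one consolidated summary for a directory", {
  tmp <- withr::local_tempdir()
  indir <- file.path(tmp, "slides"); dir.create(indir)
  for (s in 1:2) {
    gen <- small_tissue(seed = 310 + s, n_cells = 30L)
    write_slide(gen$image, file.path(indir, sprintf("sample%d.tif", s)))
  }
  outdir <- file.path(tmp, "out")
  res <- run_batch(indir, outdir)
  summ <- read.csv(file.path(outdir, "summary.csv"))
  expect_equal(nrow(summ), 2)
  expect_identical(summ$sample_id, c("sample1", "sample2"))
  parts <- read.csv(file.path(outdir, "particles", "sample1.csv"))
  expect_equal(summ$n_cells[1], sum(parts$retained))
})
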