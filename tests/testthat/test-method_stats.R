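test_that("Bland-Altman mean difference and limits of agreement", {
  same <- bland_altman(c(70, 75, 80), c(70, 75, 80))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)
  shifted <- bland_altman(c(60, 70, 80), c(63, 73, 83))
  expect_equal(shifted$mean_difference, 3)
  expect_equal(shifted$sd_difference, 0)
  expect_equal(shifted$loa_lower, 3)
  ba <- bland_altman(c(1, 2, 3), c(2, 4, 6))  # d = (1,2,3): mean 2, SD 1
  expect_equal(ba$mean_difference, 2)
  expect_equal(ba$loa_lower, 0.04)
  expect_equal(ba$loa_upper, 3.96)
})

test_that("limits of agreement are exactly symmetric about the mean", {
  set.seed(61)
  for (i in 1:25) {
    a <- rnorm(sample(4:40, 1), 70, 10)
    b <- a + rnorm(length(a), -12, 5)
    ba <- bland_altman(a, b)
    expect_identical(ba$loa_lower, ba$mean_difference - 1.96 * ba$sd_difference)
    expect_equal((ba$loa_lower + ba$loa_upper) / 2, ba$mean_difference)
    # same difference as the paired t-test on the same pairs
    expect_equal(paired_t(a, b)$mean_difference, ba$mean_difference)
  }
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("paired t: textbook statistic and zero-variance edges", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- paired_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(const$mean_difference, 2)
  expect_true(is.infinite(const$t))
  expect_true(const$zero_variance)
  set.seed(62)
  a <- rnorm(20, 70, 8); b <- a + rnorm(20, -5, 3)
  got <- paired_t(a, b)
  d <- b - a  # direct formula as independent check
  tref <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, tref)
  expect_equal(got$p, 2 * pt(-abs(tref), length(d) - 1))
})

test_that("correlations: Pearson and Spearman conventions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlations(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlations(x, -x, "pearson")$r, -1)
  expect_equal(correlations(x, x^3, "spearman")$r, 1)
  expect_lt(correlations(x, x^3, "pearson")$r, 1)
  expect_error(correlations(x, rep(1, 5)), "constant")
  expect_error(correlations(1:2, 2:3), "at least 3")
})

test_that("Meng's Z: null, antisymmetry and step-by-step formula", {
  null <- meng_z(0.5, 0.5, r12 = 0.3, n = 100)
  expect_equal(null$z, 0)
  expect_equal(null$p, 1)
  got <- meng_z(0.5, 0.3, r12 = 0.4, n = 100)
  # independent evaluation of the published formula
  z1 <- atanh(0.5); z2 <- atanh(0.3)
  rb2 <- (0.5^2 + 0.3^2) / 2
  f <- min(1, (1 - 0.4) / (2 * (1 - rb2)))
  h <- (1 - f * rb2) / (1 - rb2)
  zref <- (z1 - z2) * sqrt((100 - 3) / (2 * (1 - 0.4) * h))
  expect_equal(got$z, zref)
  expect_equal(got$p, 2 * pnorm(-abs(zref)))
  swapped <- meng_z(0.3, 0.5, r12 = 0.4, n = 100)
  expect_equal(swapped$z, -got$z)
  expect_equal(swapped$p, got$p)
  expect_error(meng_z(0.5, 0.3, 0.4, n = 3), "exceed 3")
  expect_error(meng_z(1, 0.3, 0.4, n = 10), "strictly inside")
})

test_that("HOMA-IR equation", {
  expect_equal(homa_ir(22.5, 1.0), 1)
  expect_equal(homa_ir(10, 5.4), 2.4)
  expect_equal(homa_ir(25, 4.5), 5)
  expect_error(homa_ir(0, 5), "positive")
})

test_that("VAI sex-specific equations and monotonicity", {
  bmi <- 30
  expect_equal(vai("male", 39.68 + 1.88 * bmi, bmi, 1.03, 1.31), 1)
  expect_equal(vai("female", 36.58 + 1.89 * bmi, bmi, 0.81, 1.52), 1)
  # direct evaluation at study-typical values
  ref <- (135 / (39.68 + 1.88 * 49)) * (1.64 / 1.03) * (1.31 / 1.18)
  expect_equal(vai("male", 135, 49, 1.64, 1.18), ref)
  # increasing in TG and WC, decreasing in HDL over a positive grid
  tg <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(vai(rep("female", 10), 110, 40, tg, 1.2)) > 0))
  wc <- seq(80, 180, by = 10)
  expect_true(all(diff(vai(rep("male", 11), wc, 40, 1.5, 1.2)) > 0))
  hdl <- seq(0.6, 2.2, by = 0.2)
  expect_true(all(diff(vai(rep("male", 9), 110, 40, 1.5, hdl)) < 0))
  expect_error(vai("male", -1, 30, 1, 1), "positive")
})

test_that("clinical index columns are appended to a record table", {
  clin <- data.frame(
    sex = c("male", "female"), wc_cm = c(135, 110), bmi = c(49, 42),
    tg_mmol_l = c(1.64, 1.2), hdl_mmol_l = c(1.18, 1.4),
    insulin_uu_ml = c(25, 10), glucose_mmol_l = c(4.5, 5.4))
  out <- add_clinical_indices(clin)
  expect_equal(out$homa_ir, c(5, 2.4))
  expect_equal(out$vai[1], vai("male", 135, 49, 1.64, 1.18))
  expect_error(add_clinical_indices(clin[, -1]), "lacks columns")
})
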