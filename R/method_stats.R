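#' Paired measurements from two sizing methods
#'
#' Aligned per-sample values (typically mean adipocyte diameters in um)
#' from a reference method (`method_a`, e.g. manual sizing) and a test
#' method (`method_b`, e.g. automated sizing). All comparison statistics
#' define the difference as `method_b - method_a`.
#'
#' @param method_a,method_b Numeric vectors of equal length (>= 2), aligned
#'   by sample.
#' @param sample_ids Optional identifiers.
#' @return A list of class `paired_measurements`.
#' @export
paired_measurements <- function(method_a, method_b, sample_ids = NULL) {
  if (length(method_a) != length(method_b))
    stop("`method_a` and `method_b` must have equal length")
  if (length(method_a) < 2L) stop("need at least 2 pairs")
  if (anyNA(method_a) || anyNA(method_b)) stop("pairs must not contain NA")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(method_a))
  structure(
    list(sample_ids = as.character(sample_ids),
         method_a = as.numeric(method_a), method_b = as.numeric(method_b)),
    class = "paired_measurements"
  )
}

.as_pairs <- function(pairs, method_b) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  if (is.data.frame(pairs))
    return(paired_measurements(pairs$method_a, pairs$method_b,
                               pairs$sample_id))
  paired_measurements(pairs, method_b)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two measurement methods via the paired differences
#' `d = method_b - method_a`: their mean (the bias), their sample standard
#' deviation (n - 1) and the conventional 95% limits of agreement
#' `mean +/- 1.96 * SD`. The limits are by construction symmetric about
#' the mean difference. Strong correlation alone does not demonstrate
#' agreement; the limits quantify how far individual samples may disagree.
#'
#' @param pairs A [paired_measurements()] object, or a data frame with
#'   columns `method_a` and `method_b`, or a numeric vector (with
#'   `method_b` supplied as the second argument).
#' @param method_b Second method's values when `pairs` is a plain vector.
#' @return An object of class `agreement_result`: `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`, `n`, plus the `means` and
#'   `differences` used (for plotting difference against pairwise mean).
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 4, 6))
#' @export
bland_altman <- function(pairs, method_b = NULL) {
  p <- .as_pairs(pairs, method_b)
  d <- p$method_b - p$method_a
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  if (length(d) == 1 || !is.finite(s)) s <- 0
  structure(
    list(mean_difference = m, sd_difference = s,
         loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
         n = length(d),
         means = (p$method_a + p$method_b) / 2, differences = d),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n = %d, mean difference %.2f, LoA [%.2f, %.2f]\n",
    x$n, x$mean_difference, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference (`method_b - method_a`) against pairwise mean, with the mean
#' difference and 95% limits of agreement as horizontal lines.
#'
#' @param x An [bland_altman()] result.
#' @param xlab,ylab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @importFrom graphics abline plot
#' @export
plot_bland_altman <- function(x, xlab = "Mean of methods (um)",
                              ylab = "Difference, B - A (um)",
                              main = "Bland-Altman agreement", ...) {
  stopifnot(inherits(x, "agreement_result"))
  plot(x$means, x$differences, xlab = xlab, ylab = ylab, main = main, ...)
  abline(h = x$mean_difference, lty = 1)
  abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Paired t-test on method differences
#'
#' Standard paired t statistic on `d = method_b - method_a` with n - 1
#' degrees of freedom (delegated to [stats::t.test()]), with the two
#' degenerate zero-variance cases handled explicitly: identical methods
#' give `t = 0, p = 1` by convention, and a constant nonzero difference is
#' flagged with an infinite t (p = 0).
#'
#' @inheritParams bland_altman
#' @return List: `t`, `p`, `mean_difference`, `df`, `zero_variance`.
#' @export
paired_t <- function(pairs, method_b = NULL) {
  p <- .as_pairs(pairs, method_b)
  d <- p$method_b - p$method_a
  n <- length(d)
  if (sd(d) == 0) {
    m <- mean(d)
    return(list(t = if (m == 0) 0 else Inf * sign(m),
                p = if (m == 0) 1 else 0,
                mean_difference = m, df = n - 1L, zero_variance = TRUE))
  }
  tt <- stats::t.test(p$method_b, p$method_a, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = unname(tt$estimate), df = unname(tt$parameter),
       zero_variance = FALSE)
}

#' Correlation between two methods
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value, via [stats::cor.test()].
#'
#' @inheritParams bland_altman
#' @param kind `"pearson"` or `"spearman"`.
#' @return List: `r`, `p`, `n`, `kind`.
#' @export
correlations <- function(pairs, method_b = NULL,
                         kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  p <- .as_pairs(pairs, method_b)
  if (length(p$method_a) < 3L) stop("need at least 3 pairs for correlation")
  if (sd(p$method_a) == 0 || sd(p$method_b) == 0)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(
    cor.test(p$method_a, p$method_b, method = kind, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(p$method_a),
       kind = kind)
}

#' Meng's Z-test for correlated correlation coefficients
#'
#' Tests whether two predictors correlate differently with a common
#' criterion when the predictors are themselves correlated - e.g. whether
#' automated and manual mean cell diameter relate differently to a
#' metabolic marker measured on the same samples. Both correlations are
#' Fisher z-transformed; with `rbar2 = (r1^2 + r2^2) / 2`,
#' `f = min(1, (1 - r12) / (2 * (1 - rbar2)))` and
#' `h = (1 - f * rbar2) / (1 - rbar2)`, the statistic is
#' `Z = (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))`, referred to the
#' standard normal (two-sided). `f` is clipped at 1 as in the original
#' method.
#'
#' @param r1,r2 Correlations of predictor 1 and predictor 2 with the
#'   common criterion; each strictly inside (-1, 1).
#' @param r12 Correlation between the two predictors, strictly inside
#'   (-1, 1). This must be supplied explicitly: it is a property of the
#'   data, not of the two criterion correlations.
#' @param n Number of samples (> 3).
#' @return List: `z`, `p` (two-sided).
#' @examples
#' meng_z(0.5, 0.3, r12 = 0.4, n = 100)
#' @export
meng_z <- function(r1, r2, r12, n) {
  if (n <= 3) stop("`n` must exceed 3")
  if (any(abs(c(r1, r2, r12)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Homoeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `fasting insulin (uU/mL) * fasting glucose (mmol/L) / 22.5`.
#'
#' @param fasting_insulin Fasting insulin in uU/mL (> 0); vectorised.
#' @param fasting_glucose Fasting glucose in mmol/L (> 0); vectorised.
#' @return HOMA-IR index.
#' @examples
#' homa_ir(22.5, 1.0)  # 1
#' @export
homa_ir <- function(fasting_insulin, fasting_glucose) {
  if (any(!is.finite(fasting_insulin)) || any(fasting_insulin <= 0) ||
      any(!is.finite(fasting_glucose)) || any(fasting_glucose <= 0))
    stop("insulin and glucose must be positive")
  fasting_insulin * fasting_glucose / 22.5
}

#' Visceral adiposity index (VAI)
#'
#' Sex-specific composite of waist circumference (cm), BMI (kg/m^2),
#' triglycerides and HDL-cholesterol (both mmol/L):
#' males `(WC / (39.68 + 1.88 * BMI)) * (TG / 1.03) * (1.31 / HDL)`,
#' females `(WC / (36.58 + 1.89 * BMI)) * (TG / 0.81) * (1.52 / HDL)`.
#'
#' @param sex `"male"` or `"female"`; vectorised.
#' @param waist_circumference Waist circumference in cm (> 0).
#' @param bmi Body mass index in kg/m^2 (> 0).
#' @param tg Triglycerides in mmol/L (> 0).
#' @param hdl HDL-cholesterol in mmol/L (> 0).
#' @return VAI index.
#' @examples
#' vai("male", waist_circumference = 39.68 + 1.88 * 30, bmi = 30,
#'     tg = 1.03, hdl = 1.31)  # 1
#' @export
vai <- function(sex, waist_circumference, bmi, tg, hdl) {
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  vals <- c(waist_circumference, bmi, tg, hdl)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("waist circumference, BMI, TG and HDL must be positive")
  ifelse(sex == "male",
         (waist_circumference / (39.68 + 1.88 * bmi)) * (tg / 1.03) *
           (1.31 / hdl),
         (waist_circumference / (36.58 + 1.89 * bmi)) * (tg / 0.81) *
           (1.52 / hdl))
}

#' Append clinical indices to a clinical-record table
#'
#' Adds `homa_ir` and `vai` columns to a data frame with columns `sex`,
#' `wc_cm`, `bmi`, `tg_mmol_l`, `hdl_mmol_l`, `insulin_uu_ml`,
#' `glucose_mmol_l`.
#'
#' @param clinical Clinical-record data frame.
#' @return The data frame with `homa_ir` and `vai` appended.
#' @export
add_clinical_indices <- function(clinical) {
  need <- c("sex", "wc_cm", "bmi", "tg_mmol_l", "hdl_mmol_l",
            "insulin_uu_ml", "glucose_mmol_l")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  clinical$homa_ir <- homa_ir(clinical$insulin_uu_ml, clinical$glucose_mmol_l)
  clinical$vai <- vai(clinical$sex, clinical$wc_cm, clinical$bmi,
                      clinical$tg_mmol_l, clinical$hdl_mmol_l)
  clinical
}
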