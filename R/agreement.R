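#' Bland-Altman agreement analysis between two measurement methods
#'
#' Computes the mean difference (bias) between a test and a reference
#' method, the limits of agreement (LOA), and confidence intervals for the
#' bias and for each limit of agreement.
#'
#' Differences are `test - reference`, so a positive bias means the test
#' method overestimates. Conventions:
#' \itemize{
#'   \item bias = mean(d); bias SD = sample SD of d (n-1 denominator);
#'     bias SEM = SD/sqrt(n).
#'   \item LOA = bias +- z * SD with z = 1.96 for 95% limits.
#'   \item LOA SEM = SD * sqrt(1/n + z^2 / (2 (n-1))).
#'   \item All confidence intervals use a Student t quantile with n-1 df:
#'     bias CI = bias +- t * bias SEM, LOA CI = LOA +- t * LOA SEM.
#' }
#' The mixed z/t convention (a fixed normal quantile for the limits
#' themselves, t-based confidence intervals around them) matches the
#' classical Bland-Altman presentation for moderate n.
#'
#' @param reference Numeric vector, reference-method measurements.
#' @param test Numeric vector, test-method measurements (same length).
#' @param z Quantile defining the limits of agreement (default 1.96).
#' @param conf Confidence level for the intervals (default 0.95).
#' @return Object of class `bland_altman`: a list with `n`, `z`, `bias`,
#'   `bias_sd`, `bias_sem`, `bias_ci`, `loa_lower`, `loa_upper`, `loa_sem`,
#'   `loa_lower_ci`, `loa_upper_ci` (all in the measurement's units).
#' @examples
#' ref <- c(50, 55, 60, 48, 52)
#' tst <- ref + c(5, 7, 4, 6, 8)
#' bland_altman(ref, tst)
#' @export
bland_altman <- function(reference, test, z = 1.96, conf = 0.95) {
  if (length(reference) != length(test))
    stop("reference and test must have the same length")
  if (length(test) < 3)
    stop("Bland-Altman analysis needs at least 3 paired measurements")
  if (any(!is.finite(reference)) || any(!is.finite(test)))
    stop("measurements must be finite")
  d <- test - reference
  out <- bland_altman_from_summary(mean(d), stats::sd(d), length(d),
                                   z = z, conf = conf)
  out$diffs <- d
  out$means <- (test + reference) / 2
  out
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against paired means, with the bias and
#' the limits of agreement drawn as horizontal lines. Only available for
#' results computed from raw data (not from summary statistics).
#'
#' @param x A `bland_altman` object from [bland_altman()].
#' @param xlab,ylab,main Axis and title labels.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (test - reference)",
                              main = "Bland-Altman plot", ...) {
  if (is.null(x$diffs))
    stop("no raw data: result was built from summary statistics")
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, main = main,
                 pch = 16, col = "grey30", ...)
  graphics::abline(h = x$bias, col = "blue", lwd = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "red", lty = 2)
  invisible(x)
}

#' Bland-Altman quantities from summary statistics
#'
#' Reconstructs every derived Bland-Altman quantity (SEMs, limits of
#' agreement, confidence intervals) from the three sufficient statistics:
#' the bias, the SD of the paired differences, and n. Uses exactly the
#' formulas of [bland_altman()], with which it agrees to machine precision
#' on the same data.
#'
#' @param bias Mean of the paired differences (test - reference).
#' @param sd Sample SD of the differences (n-1 denominator), positive.
#' @param n Number of pairs, at least 3.
#' @inheritParams bland_altman
#' @return Object of class `bland_altman`; see [bland_altman()].
#' @examples
#' bland_altman_from_summary(6.13, 7.51, 96)
#' @export
bland_altman_from_summary <- function(bias, sd, n, z = 1.96, conf = 0.95) {
  if (!is.numeric(bias) || length(bias) != 1 || !is.finite(bias))
    stop("bias must be a single finite number")
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0)
    stop("sd must be a single non-negative number")
  if (n < 3) stop("n must be at least 3")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  bias_sem <- sd / sqrt(n)
  loa_sem <- sd * sqrt(1 / n + z^2 / (2 * (n - 1)))
  loa_lower <- bias - z * sd
  loa_upper <- bias + z * sd
  structure(list(
    n = as.integer(n),
    z = z,
    conf = conf,
    bias = bias,
    bias_sd = sd,
    bias_sem = bias_sem,
    bias_ci = c(bias - tq * bias_sem, bias + tq * bias_sem),
    loa_lower = loa_lower,
    loa_upper = loa_upper,
    loa_sem = loa_sem,
    loa_lower_ci = c(loa_lower - tq * loa_sem, loa_lower + tq * loa_sem),
    loa_upper_ci = c(loa_upper - tq * loa_sem, loa_upper + tq * loa_sem)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 2, ...) {
  f <- function(v) formatC(v, format = "f", digits = digits)
  cat("Bland-Altman agreement (test - reference), n =", x$n, "\n")
  cat("  Bias:      ", f(x$bias), " (SD ", f(x$bias_sd),
      ", SEM ", f(x$bias_sem), ")\n", sep = "")
  cat("  Bias ", 100 * x$conf, "% CI: [", f(x$bias_ci[1]), ", ",
      f(x$bias_ci[2]), "]\n", sep = "")
  cat("  Lower LOA: ", f(x$loa_lower), " [", f(x$loa_lower_ci[1]), ", ",
      f(x$loa_lower_ci[2]), "]\n", sep = "")
  cat("  Upper LOA: ", f(x$loa_upper), " [", f(x$loa_upper_ci[1]), ", ",
      f(x$loa_upper_ci[2]), "]  (z = ", x$z, ", LOA SEM ", f(x$loa_sem),
      ")\n", sep = "")
  invisible(x)
}

#' Over/under-estimation ratio summary
#'
#' Partitions the per-subject ratios `test/reference` at 1 and summarises
#' each side: the percentage of subjects (rounded to integer percent) and
#' the min, max, mean and median ratio. Ratios exactly equal to 1 fall in
#' neither partition; they are counted separately as ties.
#'
#' @param test Numeric vector of test-method values.
#' @param reference Numeric vector of reference-method values, positive.
#' @return A list with `n`, `n_under`, `n_over`, `n_tie`, `pct_under`,
#'   `pct_over`, and `under`/`over` data frames of min/max/mean/median
#'   (NA when the partition is empty).
#' @examples
#' ratio_summary(c(0.9, 0.95, 1.1, 1.2) * 50, rep(50, 4))
#' @export
ratio_summary <- function(test, reference) {
  if (length(test) != length(reference))
    stop("test and reference must have the same length")
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference values must be positive and finite")
  r <- test / reference
  part <- function(v) {
    if (length(v) == 0)
      return(data.frame(min = NA_real_, max = NA_real_,
                        mean = NA_real_, median = NA_real_))
    data.frame(min = min(v), max = max(v),
               mean = mean(v), median = stats::median(v))
  }
  under <- r[r < 1]
  over <- r[r > 1]
  n <- length(r)
  list(
    n = n,
    n_under = length(under),
    n_over = length(over),
    n_tie = n - length(under) - length(over),
    pct_under = round(100 * length(under) / n),
    pct_over = round(100 * length(over) / n),
    under = part(under),
    over = part(over)
  )
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return The square of the Pearson correlation coefficient.
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)^2
}

#' Ordinary least squares fit with a 95% confidence band
#'
#' Fits `y ~ x` by OLS and returns the slope, intercept, r-squared, and a
#' pointwise confidence band for the mean response, as drawn on standard
#' correlation scatter plots.
#'
#' @inheritParams correlation_r2
#' @param conf Confidence level for the band (default 0.95).
#' @param band_at x values at which to evaluate the band; defaults to an
#'   even grid over the range of `x`.
#' @return A list with `slope`, `intercept`, `r2`, and `band` (data frame
#'   with columns `x`, `fit`, `lwr`, `upr`).
#' @export
linear_fit <- function(x, y, conf = 0.95, band_at = NULL) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant x: fit undefined")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  if (is.null(band_at))
    band_at <- seq(min(x), max(x), length.out = 50)
  pr <- stats::predict(fit, newdata = data.frame(x = band_at),
                       interval = "confidence", level = conf)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    band = data.frame(x = band_at, fit = pr[, "fit"],
                      lwr = pr[, "lwr"], upr = pr[, "upr"])
  )
}

#' Per-sex cohort summary table
#'
#' Summarises each body-composition variable per sex as mean, SD and range,
#' optionally with a two-sided Welch two-sample t-test p-value between the
#' sexes. With a single subject in a sex, the SD is reported as NA.
#'
#' @param data Data frame with a `sex` column (`"male"`/`"female"`) and the
#'   numeric columns to summarise.
#' @param variables Character vector of column names to summarise; defaults
#'   to every numeric column except identifiers.
#' @param p_values Compute Welch t-test p-values per variable (default
#'   TRUE; requires both sexes present with n >= 2 each).
#' @return Data frame with one row per variable and sex: `variable`, `sex`,
#'   `n`, `mean`, `sd`, `min`, `max`, and `p_value` (NA when not computable).
#' @export
cohort_table <- function(data, variables = NULL, p_values = TRUE) {
  if (!"sex" %in% names(data)) stop("data must have a 'sex' column")
  if (nrow(data) < 1) stop("empty cohort")
  if (is.null(variables)) {
    num <- vapply(data, is.numeric, logical(1))
    variables <- setdiff(names(data)[num], c("patient_id"))
  }
  rows <- list()
  for (v in variables) {
    pv <- NA_real_
    if (p_values) {
      xm <- data[[v]][data$sex == "male"]
      xf <- data[[v]][data$sex == "female"]
      if (length(xm) >= 2 && length(xf) >= 2 &&
          (stats::sd(xm) > 0 || stats::sd(xf) > 0))
        pv <- stats::t.test(xm, xf)$p.value
    }
    for (s in intersect(c("male", "female"), unique(data$sex))) {
      x <- data[[v]][data$sex == s]
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, sex = s, n = length(x),
        mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        min = min(x), max = max(x),
        p_value = pv
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round to the reporting precision
#'
#' Half-even rounding (R's default) to a given number of decimals, used for
#' all table output so reported values match the usual publication
#' convention: 1 decimal for kg, 2 for SEMs and ratios.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, digits = 1) round(x, digits)
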