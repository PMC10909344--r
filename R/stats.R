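#' Standardized-major-axis fit with a one-sample slope test
#'
#' SMA (reduced major axis) line fitting: the slope estimate is
#' `sign(cor(x, y)) * sd(y) / sd(x)`, appropriate when both axes carry
#' sampling error — here, a metric computed from captured samples regressed
#' against the same metric in the full population.  The hypothesis that the
#' true slope equals `test_slope` is assessed through the correlation r
#' between the residual scores `y - b0 * x` and the axis scores
#' `y + b0 * x` evaluated at `b0 = test_slope`: under the null this
#' correlation is zero, and `F = (n - 2) * r^2 / (1 - r^2)` is referred to
#' an F(1, n - 2) distribution.  The confidence interval for the slope uses
#' the standard pivot `B = F_crit * (1 - r_xy^2) / (n - 2)`, giving
#' `slope * (sqrt(B + 1) +/- sqrt(B))`.
#'
#' Pairs with a missing value in either vector are dropped.
#'
#' @param x Metric values from the full population (reference axis).
#' @param y Metric values from the captured samples.
#' @param test_slope Hypothesized slope (default 1, the 1:1 line).
#' @param alpha Significance level for the confidence interval.
#' @return An `sma_test` object: `slope`, `ci_low`, `ci_high`, `r` (the
#'   residual-axis test correlation), `r_xy` (raw correlation), `p_value`,
#'   `f_stat`, `n`, `test_slope`.
#' @export
sma_slope_test <- function(x, y, test_slope = 1, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("SMA slope test needs at least 3 complete pairs",
                  call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("SMA slope test undefined for zero-variance input", call. = FALSE)
  r_xy <- stats::cor(x, y)
  slope <- if (r_xy < 0) -sy / sx else sy / sx
  crit <- stats::qf(1 - alpha, 1, n - 2)
  B <- crit * (1 - r_xy^2) / (n - 2)
  ci <- slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
  res_scores <- y - test_slope * x
  axis_scores <- y + test_slope * x
  if (stats::sd(res_scores) == 0 || stats::sd(axis_scores) == 0) {
    r <- 0
  } else {
    r <- stats::cor(res_scores, axis_scores)
  }
  f_stat <- (n - 2) * r^2 / (1 - r^2)
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, ci_low = min(ci), ci_high = max(ci),
                 r = r, r_xy = r_xy, p_value = p, f_stat = f_stat,
                 n = n, test_slope = test_slope),
            class = "sma_test")
}

#' @export
print.sma_test <- function(x, ...) {
  cat(sprintf("SMA slope = %.4f (%.4f, %.4f), n = %d\n",
              x$slope, x$ci_low, x$ci_high, x$n))
  cat(sprintf("  H0 slope = %g: F = %.4f, r = %.4f, p = %.4g\n",
              x$test_slope, x$f_stat, x$r, x$p_value))
  invisible(x)
}

#' Fligner-Killeen test of sampled versus reference variance
#'
#' Median-centered nonparametric test of homogeneity of variances between a
#' sampled-metric vector and the full-population reference vector, used to
#' ask whether sampling inflates the spread of an outcome across runs.
#'
#' @param sample_values Metric values from captured samples (one per run).
#' @param reference_values Metric values from the full populations.
#' @return List: `statistic` (median chi-squared), `df`, `p_value`.
#' @export
variance_test <- function(sample_values, reference_values) {
  sample_values <- sample_values[is.finite(sample_values)]
  reference_values <- reference_values[is.finite(reference_values)]
  if (length(sample_values) < 2 || length(reference_values) < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  ft <- stats::fligner.test(
    x = c(sample_values, reference_values),
    g = factor(rep(c("sample", "reference"),
                   c(length(sample_values), length(reference_values)))))
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

#' Welch t-test separating control and biased detection differences
#'
#' Compares the per-run CJS detection-probability differences (infected
#' minus uninfected) between control sampling and a biased sampling variant.
#' A clear separation shows the mark-recapture diagnostic detects the
#' injected capture bias.
#'
#' @param delta_p_control Per-run `delta_p` values under control sampling.
#' @param delta_p_biased Per-run `delta_p` values under biased sampling.
#' @return List: `t`, `df` (Welch-Satterthwaite), `p_value`,
#'   `mean_control`, `mean_biased`.
#' @export
delta_p_group_test <- function(delta_p_control, delta_p_biased) {
  delta_p_control <- delta_p_control[is.finite(delta_p_control)]
  delta_p_biased <- delta_p_biased[is.finite(delta_p_biased)]
  if (length(delta_p_control) < 2 || length(delta_p_biased) < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  tt <- stats::t.test(delta_p_control, delta_p_biased)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_control = mean(delta_p_control),
       mean_biased = mean(delta_p_biased))
}

#' Residual-versus-detection-difference diagnostic regression
#'
#' Step 1: ordinary least-squares of the sampled metric on the
#' full-population metric; the residuals measure how far a run's sampled
#' value sits from its expectation at that parameter value.  Step 2:
#' ordinary least-squares of those residuals on the absolute CJS
#' detection-probability difference.  A positive slope means large measured
#' capture bias flags runs whose metric is distorted.
#'
#' @param full_values Full-population metric values per run.
#' @param sampled_values Sampled metric values per run.
#' @param abs_delta_p Absolute CJS `delta_p` per run.
#' @return List: `slope`, `p_value`, `f_stat`, `df`, `adj_r_squared`, `n`.
#' @export
residual_bias_diagnostic <- function(full_values, sampled_values,
                                     abs_delta_p) {
  stopifnot(length(full_values) == length(sampled_values),
            length(full_values) == length(abs_delta_p))
  keep <- is.finite(full_values) & is.finite(sampled_values) &
    is.finite(abs_delta_p)
  full_values <- full_values[keep]
  sampled_values <- sampled_values[keep]
  abs_delta_p <- abs_delta_p[keep]
  n <- length(full_values)
  if (n < 3) stop("diagnostic regression needs at least 3 complete rows",
                  call. = FALSE)
  if (stats::sd(full_values) == 0 || stats::sd(abs_delta_p) == 0)
    stop("diagnostic regression undefined for zero-variance input",
         call. = FALSE)
  res <- stats::residuals(stats::lm(sampled_values ~ full_values))
  fit <- stats::lm(res ~ abs_delta_p)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p_value = sm$coefficients[2, 4],
       f_stat = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[3]),
       adj_r_squared = sm$adj.r.squared,
       n = n)
}
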