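#' Fit the linear aging baseline to a monthly series
#'
#' Ordinary least squares of the monthly outcome value on the month index
#' `t = 1..n`, with intercept. In a chronically ill cohort both admission
#' counts and LOS drift upward over time; this line is the "baseline"
#' against which seasonal deviations are measured. Also returns standard
#' goodness-of-fit diagnostics and the classical 95% prediction interval
#' for a new monthly observation at each month (t-quantile with n - 2
#' degrees of freedom, including the leverage term).
#'
#' @param series A [monthly_series()] object, or any data frame with a
#'   `value` column; length must be >= 3.
#' @param level Prediction-interval coverage (default 0.95).
#' @return A `trend_fit` list: `slope`, `intercept`, `r2`, `adj_r2`, `rss`,
#'   `rmse` (residual standard error), `fitted`, `pred_lower`,
#'   `pred_upper`, `n`, and the underlying `lm` fit as `model`.
#' @export
fit_linear_trend <- function(series, level = 0.95) {
  value <- series$value
  n <- length(value)
  if (n < 3) stop_data("need at least 3 months to fit a trend, got %d", n)
  t <- seq_len(n)
  fit <- stats::lm(value ~ t, data = data.frame(t = t, value = value))
  s <- summary(fit)
  # predict() warns that in-sample prediction intervals refer to future
  # responses; that is exactly the intended use here
  pred <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level))
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = s$r.squared,
      adj_r2 = s$adj.r.squared,
      rss = sum(stats::residuals(fit)^2),
      rmse = s$sigma,
      fitted = unname(pred[, "fit"]),
      pred_lower = unname(pred[, "lwr"]),
      pred_upper = unname(pred[, "upr"]),
      level = level,
      n = n,
      model = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Linear baseline over %d months: slope=%.4g, intercept=%.4g (R2=%.3f, adj R2=%.3f, RMSE=%.4g)\n",
    x$n, x$slope, x$intercept, x$r2, x$adj_r2, x$rmse))
  invisible(x)
}
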