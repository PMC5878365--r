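#' Percentage deviation of a monthly series from its fitted baseline
#'
#' Replaces absolute outcome values with
#' `100 * (value_t - fitted_t) / fitted_t`, the percentage distance of each
#' monthly observation from the detrending line. A baseline that touches
#' zero makes the percentage unstable, so any month whose fitted value
#' falls at or below `eps` (default `1e-9 *` mean fitted value) is an
#' error, never a silent drop.
#'
#' @param series The [monthly_series()] the fit was computed from.
#' @param fit The matching [fit_linear_trend()] result.
#' @param eps Degeneracy threshold on the fitted values.
#' @return A `deviation_series` data frame with `year`, `month`,
#'   `deviation` (percent).
#' @export
percent_deviation <- function(series, fit, eps = NULL) {
  if (length(fit$fitted) != nrow(series)) {
    stop_data("fit has %d fitted values but series has %d months",
              length(fit$fitted), nrow(series))
  }
  if (is.null(eps)) eps <- 1e-9 * mean(fit$fitted)
  bad <- which(fit$fitted <= eps)
  if (length(bad) > 0) {
    stop_data("baseline is degenerate (fitted <= %g) at month %d-%02d",
              eps, series$year[bad[1]], series$month[bad[1]])
  }
  out <- data.frame(
    year = series$year, month = series$month,
    deviation = 100 * (series$value - fit$fitted) / fit$fitted
  )
  structure(out,
            subgroup = attr(series, "subgroup"),
            outcome = attr(series, "outcome"),
            class = c("deviation_series", "data.frame"))
}

#' Average deviations into a yearly seasonal profile
#'
#' Averages the percentage deviations at each calendar month across the
#' years of the window, yielding the 12-point seasonal variation trend for
#' one climate subgroup, together with the across-years sample standard
#' deviation per calendar month.
#'
#' @param devs A [percent_deviation()] result spanning a whole number of
#'   years (>= 2, so the SD is defined).
#' @param zone Optional zone label carried on the result.
#' @return A `seasonal_profile` data frame with `month` (1-12), `mean_dev`,
#'   `sd_dev` (percent) and attributes `zone`, `n_years`.
#' @export
seasonal_profile <- function(devs, zone = attr(devs, "subgroup")) {
  n <- nrow(devs)
  if (n %% 12 != 0) {
    stop_data("deviation series must span whole years, got %d months", n)
  }
  n_years <- n %/% 12
  if (n_years < 2) stop_data("need >= 2 years to form a seasonal profile")
  by_month <- split(devs$deviation, devs$month)
  if (length(by_month) != 12 || any(lengths(by_month) != n_years)) {
    stop_data("each calendar month must appear exactly once per year")
  }
  out <- data.frame(
    month = as.integer(names(by_month)),
    mean_dev = vapply(by_month, mean, numeric(1)),
    sd_dev = vapply(by_month, stats::sd, numeric(1))
  )
  out <- out[order(out$month), ]
  rownames(out) <- NULL
  structure(out, zone = zone, n_years = n_years,
            class = c("seasonal_profile", "data.frame"))
}

#' @export
print.seasonal_profile <- function(x, ...) {
  cat(sprintf("Seasonal profile (%s, %d years): mean %% deviation from baseline\n",
              attr(x, "zone") %||% "unlabelled", attr(x, "n_years")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Peak absolute seasonal deviation
#'
#' The maximum over calendar months of `|mean_dev|`, with the across-years
#' SD at the peaking month. Ties break toward the earliest calendar month.
#'
#' @param profile A [seasonal_profile()].
#' @return List with `peak` (percent, >= 0), `sd` (percent), `month`.
#' @export
peak_deviation <- function(profile) {
  i <- which.max(abs(profile$mean_dev))  # which.max takes the first maximum
  list(peak = abs(profile$mean_dev[i]), sd = profile$sd_dev[i],
       month = profile$month[i])
}
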