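#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test for a location difference between two samples. For
#' combined sample sizes up to 20 the p-value is exact: the null
#' distribution of the rank sum is enumerated over all assignments of the
#' (mid)ranks to the first sample, so ties are handled exactly, and the
#' two-sided p is twice the smaller tail (capped at 1). For larger samples
#' the normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Combined sample size at or below which the exact
#'   enumeration is used (default 20).
#' @return A `season_comparison` list: `statistic` (rank sum of `x`),
#'   `p_value`, `test`, `method` ("exact" or "normal"), `n` (c(nx, ny)).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop_data("both samples must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  n <- nx + ny
  if (n <= exact_max) {
    sums <- utils::combn(n, nx, FUN = function(idx) sum(r[idx]))
    p_low <- mean(sums <= w + 1e-9)
    p_high <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- nx * (n + 1) / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence of a shift
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(statistic = w, p_value = p, test = "wilcoxon_rank_sum",
                 method = method, n = c(nx, ny)),
            class = "season_comparison")
}

#' Two-sided pooled-variance two-sample t test
#'
#' @param x,y Numeric samples, each with at least 2 observations and
#'   positive pooled variance.
#' @return A `season_comparison` list: `statistic` (t), `p_value`, `test`,
#'   `df`, `n`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_data("each sample needs >= 2 observations for a t test")
  }
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled <= 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(statistic = 0, p_value = 1, test = "t_test",
                            df = length(x) + length(y) - 2,
                            n = c(length(x), length(y))),
                       class = "season_comparison"))
    }
    stop_data("pooled variance is zero but means differ: t statistic undefined")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 test = "t_test", df = unname(tt$parameter),
                 n = c(length(x), length(y))),
            class = "season_comparison")
}

#' @export
print.season_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g, p=%.4g (n=%d,%d)\n",
              x$test, x$statistic, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' Mean LOS per admission by season
#'
#' @param los Named numeric vector of per-season LOS totals (days).
#' @param admissions Matching per-season admission counts.
#' @param digits Decimal places for the reported ratio (default 2, the
#'   conventional reporting precision); use `NULL` for full precision.
#' @return Named numeric vector of mean LOS per admission; `NA` (with a
#'   warning) for seasons with zero admissions.
#' @examples
#' los_per_admission(c(summer = 714, winter = 1007),
#'                   c(summer = 176, winter = 216))
#' @export
los_per_admission <- function(los, admissions, digits = 2) {
  if (length(los) != length(admissions)) {
    stop_data("los and admissions must have equal length")
  }
  out <- ifelse(admissions > 0, los / admissions, NA_real_)
  if (any(admissions == 0)) {
    warning("seasons with zero admissions yield undefined LOS per admission")
  }
  names(out) <- names(los) %||% names(admissions)
  if (is.null(digits)) out else round(out, digits)
}

#' Per-patient admission and LOS totals over a window
#'
#' @param admissions,patients As in [monthly_series()].
#' @param window Optional [month_window()]; records outside it are dropped.
#' @return Data frame with `patient_id`, `n_admissions`, `total_los`, one
#'   row per patient (patients without admissions get zeros).
#' @export
patient_totals <- function(admissions, patients, window = NULL) {
  rec <- admissions
  if (!is.null(window)) {
    idx <- window_indices(window)
    a <- month_index(as.integer(format(rec$admit_date, "%Y")),
                     as.integer(format(rec$admit_date, "%m")))
    rec <- rec[a >= idx[1] & a <= idx[length(idx)], , drop = FALSE]
  }
  f <- factor(rec$patient_id, levels = patients$patient_id)
  data.frame(
    patient_id = patients$patient_id,
    n_admissions = as.integer(table(f)),
    total_los = as.numeric(tapply_sum(as.integer(f), rec$los_days,
                                      nrow(patients)))
  )
}

#' Regression of total LOS on total admissions across patients
#'
#' Fits total LOS days against admission count per patient by OLS and
#' reports the Pearson correlation; in simple regression `r2` equals the
#' squared correlation. The slope estimates the marginal LOS days per
#' additional admission.
#'
#' @param totals A [patient_totals()] data frame (or any data frame with
#'   `n_admissions` and `total_los`), at least 3 patients with variation in
#'   admission counts.
#' @return List with `slope`, `intercept`, `r2`, `correlation`, `n`, and
#'   the `lm` fit as `model`.
#' @export
los_admissions_regression <- function(totals) {
  if (nrow(totals) < 3) stop_data("need >= 3 patients for the LOS regression")
  if (stats::var(totals$n_admissions) == 0) {
    stop_data("admission counts have zero variance: regression undefined")
  }
  fit <- stats::lm(total_los ~ n_admissions, data = totals)
  r <- stats::cor(totals$n_admissions, totals$total_los)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared,
       correlation = r,
       n = nrow(totals),
       model = fit)
}
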