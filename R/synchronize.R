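#' Build a recruitment schedule for test patients
#'
#' @param zone Character vector of climate zones, one per test patient.
#' @param commencement_month Calendar months (1-12) when each patient's
#'   telemonitoring began.
#' @param months_monitored Integer months of follow-up per patient
#'   (>= 1); scalar values are recycled.
#' @return A `recruitment_schedule` data frame.
#' @export
recruitment_schedule <- function(zone, commencement_month, months_monitored = 12L) {
  n <- length(zone)
  if (length(commencement_month) != n) {
    stop_config("zone and commencement_month must have equal length")
  }
  if (any(commencement_month < 1 | commencement_month > 12)) {
    stop_config("commencement_month must be a calendar month in 1..12")
  }
  months_monitored <- rep_len(as.integer(months_monitored), n)
  if (any(months_monitored < 1)) stop_config("months_monitored must be >= 1")
  structure(
    data.frame(zone = zone,
               commencement_month = as.integer(commencement_month),
               months_monitored = months_monitored,
               stringsAsFactors = FALSE),
    class = c("recruitment_schedule", "data.frame")
  )
}

#' Synchronized seasonal profile over months since commencement
#'
#' Pools each climate zone's yearly seasonal profile across test patients
#' with heterogeneous commencement months: the synchronized value at month
#' `i` after commencement is the mean, over all patients still monitored at
#' month `i`, of their zone profile evaluated at the calendar month their
#' `i`-th monitoring month falls in (wrapping over December). Because
#' patients start in different calendar months, their individual seasonal
#' excursions enter at different phases and largely cancel, which is what
#' attenuates seasonal confounding of a pre/post intervention comparison.
#'
#' For patient `k` with commencement calendar month `c_k`, the contribution
#' at month `i` is `P_zone(k)[((c_k + i - 2) mod 12) + 1]`; a patient
#' contributes at month `i` iff `months_monitored >= i`.
#'
#' @param profiles Named list mapping zone to its [seasonal_profile()]
#'   (or any data frame with `month`, `mean_dev`).
#' @param schedule A [recruitment_schedule()].
#' @return A `synchronized_profile` data frame with `month_after_start`
#'   (1-12), `sync_dev` (percent, `NA` where no patient is monitored),
#'   `n_patients`; the per-patient contribution matrix is attached as
#'   attribute `contributions` (patients x 12, `NA` past follow-up).
#' @export
synchronized_profile <- function(profiles, schedule) {
  missing_zone <- setdiff(unique(schedule$zone), names(profiles))
  if (length(missing_zone) > 0) {
    stop_config("no seasonal profile for zone(s): %s",
                paste(missing_zone, collapse = ", "))
  }
  n <- nrow(schedule)
  if (n == 0) stop_data("empty recruitment schedule")
  contrib <- matrix(NA_real_, nrow = n, ncol = 12)
  for (k in seq_len(n)) {
    prof <- profiles[[schedule$zone[k]]]
    mean_dev <- prof$mean_dev[order(prof$month)]
    i_max <- min(12L, schedule$months_monitored[k])
    i <- seq_len(i_max)
    cal <- rotate_month(schedule$commencement_month[k], i - 1L)
    contrib[k, i] <- mean_dev[cal]
  }
  n_at <- colSums(!is.na(contrib))
  sync <- ifelse(n_at > 0, colMeans(contrib, na.rm = TRUE), NA_real_)
  structure(
    data.frame(month_after_start = 1:12, sync_dev = sync,
               n_patients = as.integer(n_at)),
    contributions = contrib,
    class = c("synchronized_profile", "data.frame")
  )
}

#' @export
print.synchronized_profile <- function(x, ...) {
  cat(sprintf("Synchronized seasonal profile (%d patients at month 1)\n",
              x$n_patients[1]))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Peak residual deviation of a synchronized profile
#'
#' Maximum of `|sync_dev|` over the months after commencement where at
#' least one patient is monitored, with the SD across the per-patient
#' contributions at the peaking month. This is the residual seasonal
#' confound left after synchronization.
#'
#' @param sp A [synchronized_profile()].
#' @return List with `peak` (percent), `sd` (percent, `NA` when only one
#'   patient contributes), `month_after_start`.
#' @export
max_sync_deviation <- function(sp) {
  ok <- which(!is.na(sp$sync_dev))
  if (length(ok) == 0) stop_data("synchronized profile has no defined month")
  i <- ok[which.max(abs(sp$sync_dev[ok]))]
  contrib <- attr(sp, "contributions")
  sd_at <- if (!is.null(contrib)) stats::sd(contrib[, i], na.rm = TRUE) else NA_real_
  list(peak = abs(sp$sync_dev[i]), sd = sd_at, month_after_start = sp$month_after_start[i])
}
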