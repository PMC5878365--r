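#' Define a window of consecutive calendar months
#'
#' @param start_year,start_month First month of the window.
#' @param n_months Number of consecutive months (>= 1).
#' @return A `month_window` list used by [monthly_series()] and
#'   [run_pipeline()].
#' @export
month_window <- function(start_year, start_month, n_months) {
  if (start_month < 1 || start_month > 12) stop_config("start_month must be in 1..12")
  if (n_months < 1) stop_config("n_months must be >= 1")
  structure(list(start_year = as.integer(start_year),
                 start_month = as.integer(start_month),
                 n_months = as.integer(n_months)),
            class = "month_window")
}

window_indices <- function(window) {
  month_index(window$start_year, window$start_month) + seq_len(window$n_months) - 1L
}

#' Sum an outcome into a monthly series for a patient subgroup
#'
#' Sums either the number of admissions or the total LOS days over all
#' patients passing the filter, within each calendar month of the window.
#' Months with no admissions contribute 0, never a gap. Admissions are
#' attributed wholly to the calendar month of their admission date, even
#' when the stay spans a month boundary.
#'
#' @param admissions Data frame with `patient_id`, `admit_date` (`Date`),
#'   `los_days`.
#' @param patients Data frame with `patient_id`, `zone`, `group`; every
#'   admission must reference a known patient.
#' @param outcome `"admissions"` (counts) or `"los"` (summed days).
#' @param window A [month_window()]; records outside it are excluded (a
#'   message reports how many).
#' @param zone,group Optional filters on the patient table.
#' @return A `monthly_series` data frame with columns `year`, `month`,
#'   `value` and attributes `outcome`, `subgroup`, `window`.
#' @export
monthly_series <- function(admissions, patients,
                           outcome = c("admissions", "los"),
                           window, zone = NULL, group = NULL) {
  outcome <- match.arg(outcome)
  if (!inherits(window, "month_window")) stop_config("window must be a month_window")
  unknown <- setdiff(admissions$patient_id, patients$patient_id)
  if (length(unknown) > 0) {
    stop_data("admissions reference %d unknown patient id(s), e.g. %s",
              length(unknown), unknown[1])
  }
  keep <- rep(TRUE, nrow(patients))
  if (!is.null(zone)) keep <- keep & patients$zone %in% zone
  if (!is.null(group)) keep <- keep & patients$group %in% group
  rec <- admissions[admissions$patient_id %in% patients$patient_id[keep], , drop = FALSE]

  idx <- window_indices(window)
  adm_y <- as.integer(format(rec$admit_date, "%Y"))
  adm_m <- as.integer(format(rec$admit_date, "%m"))
  adm_idx <- month_index(adm_y, adm_m)
  in_win <- adm_idx >= idx[1] & adm_idx <= idx[length(idx)]
  if (any(!in_win)) {
    message(sprintf("monthly_series: excluded %d record(s) outside the window",
                    sum(!in_win)))
    rec <- rec[in_win, , drop = FALSE]
    adm_idx <- adm_idx[in_win]
  }
  pos <- adm_idx - idx[1] + 1L
  w <- if (outcome == "los") rec$los_days else rep(1, nrow(rec))
  value <- as.numeric(tapply_sum(pos, w, length(idx)))

  out <- data.frame(year = index_year(idx), month = index_month(idx), value = value)
  structure(out,
            outcome = outcome,
            subgroup = paste0(
              if (is.null(zone)) "all" else paste(zone, collapse = "+"),
              if (is.null(group)) "" else paste0("/", paste(group, collapse = "+"))),
            window = window,
            class = c("monthly_series", "data.frame"))
}

# length-n bincount of weights w at positions pos (1..n)
tapply_sum <- function(pos, w, n) {
  out <- numeric(n)
  if (length(pos)) {
    s <- tapply(w, factor(pos, levels = seq_len(n)), sum)
    out <- as.numeric(ifelse(is.na(s), 0, s))
  }
  out
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("Monthly %s series, subgroup %s: %d months from %d-%02d\n",
              attr(x, "outcome"), attr(x, "subgroup"), nrow(x),
              x$year[1], x$month[1]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Map a calendar month to its season for a climate zone
#'
#' Southern-hemisphere conventions: for `temperate` and `colder` zones,
#' summer = Dec-Feb, autumn = Mar-May, winter = Jun-Aug, spring = Sep-Nov.
#' The `subtropical` zone has two seasons: the wet season labelled
#' "summer" (Nov-Apr) and the dry season labelled "winter" (May-Oct).
#'
#' @param month Integer vector, months in 1..12.
#' @param zone One of `"subtropical"`, `"temperate"`, `"colder"`.
#' @return Character vector of season labels.
#' @export
assign_season <- function(month, zone) {
  zone <- match.arg(zone, c("subtropical", "temperate", "colder"))
  if (any(month < 1 | month > 12)) stop_config("month must be in 1..12")
  if (zone == "subtropical") {
    ifelse(month >= 11 | month <= 4, "summer", "winter")
  } else {
    four <- c("summer", "summer", "autumn", "autumn", "autumn",
              "winter", "winter", "winter", "spring", "spring", "spring",
              "summer")
    four[month]
  }
}

season_levels <- function(zone) {
  if (zone == "subtropical") c("summer", "winter")
  else c("summer", "autumn", "winter", "spring")
}

#' Seasonal admission and LOS summary by climate zone
#'
#' Cross-tabulates admissions and total LOS by zone and season (using each
#' zone's own season map), with percentage shares of the zone total per
#' season and of the grand total per zone.
#'
#' @param admissions,patients As in [monthly_series()].
#' @return A `season_table` list with data frames `by_season` (zone,
#'   season, admissions, los, admissions_pct, los_pct), `by_zone` (zone
#'   totals and shares of the grand total) and `total`.
#' @export
season_table <- function(admissions, patients) {
  if (nrow(admissions) == 0) stop_data("no admission records: season table is empty")
  unknown <- setdiff(admissions$patient_id, patients$patient_id)
  if (length(unknown) > 0) {
    stop_data("admissions reference %d unknown patient id(s)", length(unknown))
  }
  zone <- patients$zone[match(admissions$patient_id, patients$patient_id)]
  m <- as.integer(format(admissions$admit_date, "%m"))

  rows <- list()
  for (z in unique(patients$zone)) {
    zm <- m[zone == z]
    zl <- admissions$los_days[zone == z]
    season <- assign_season(zm, z)
    for (s in season_levels(z)) {
      rows[[length(rows) + 1L]] <- data.frame(
        zone = z, season = s,
        admissions = sum(season == s),
        los = sum(zl[season == s]),
        stringsAsFactors = FALSE
      )
    }
  }
  by_season <- do.call(rbind, rows)
  zone_tot <- stats::aggregate(cbind(admissions, los) ~ zone, by_season, sum)
  by_season$admissions_pct <- 100 * by_season$admissions /
    zone_tot$admissions[match(by_season$zone, zone_tot$zone)]
  by_season$los_pct <- 100 * by_season$los /
    zone_tot$los[match(by_season$zone, zone_tot$zone)]
  total <- c(admissions = sum(zone_tot$admissions), los = sum(zone_tot$los))
  zone_tot$admissions_pct <- 100 * zone_tot$admissions / total[["admissions"]]
  zone_tot$los_pct <- 100 * zone_tot$los / total[["los"]]
  structure(list(by_season = by_season, by_zone = zone_tot, total = total),
            class = "season_table")
}

#' @export
print.season_table <- function(x, digits = 1, ...) {
  cat("Seasonal variation in hospital admissions and LOS\n")
  df <- x$by_season
  df$admissions_pct <- round(df$admissions_pct, digits)
  df$los_pct <- round(df$los_pct, digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Totals: %d admissions, %d LOS days\n",
              x$total[["admissions"]], x$total[["los"]]))
  invisible(x)
}

#' Percentage shares of seasonal totals
#'
#' @param totals Named numeric vector of per-season totals.
#' @param digits Decimal places for the reported share (default 1, as used
#'   for admission shares; LOS shares of a grand total are conventionally
#'   reported with 2).
#' @return Named numeric vector of percentage shares summing to 100 within
#'   rounding.
#' @export
season_shares <- function(totals, digits = 1) {
  if (length(totals) == 0 || sum(totals) <= 0) {
    stop_data("season totals must be non-empty with a positive sum")
  }
  round(100 * totals / sum(totals), digits)
}
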