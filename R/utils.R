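# Internal helpers shared across modules: calendar-month arithmetic and
# classed error conditions. Calendar months are (year, month 1-12) pairs;
# internally a month is a single integer index so that arithmetic is
# closed-form and needs no date library.

# linear month index: Jan of year 0 -> 0
month_index <- function(year, month) {
  12L * as.integer(year) + as.integer(month) - 1L
}

index_year <- function(idx) as.integer(idx %/% 12L)

index_month <- function(idx) as.integer(idx %% 12L) + 1L

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2L & leap] <- 29L
  d
}

# rotate a calendar month by k months, staying in 1..12
rotate_month <- function(month, k) {
  ((as.integer(month) + as.integer(k) - 1L) %% 12L) + 1L
}

stop_classed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "seasonsync_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) stop_classed("seasonsync_config_error", msg, ...)
stop_data <- function(msg, ...) stop_classed("seasonsync_data_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
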