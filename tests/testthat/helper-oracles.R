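# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain loops / closed forms, sharing no code with
# the package internals they verify.

# double-loop brute force for the synchronized profile
brute_force_sync <- function(profiles, schedule) {
  sync <- rep(NA_real_, 12)
  n_at <- integer(12)
  for (i in 1:12) {
    total <- 0
    count <- 0
    for (k in seq_len(nrow(schedule))) {
      if (schedule$months_monitored[k] >= i) {
        cal <- ((schedule$commencement_month[k] + i - 2) %% 12) + 1
        prof <- profiles[[schedule$zone[k]]]
        total <- total + prof$mean_dev[prof$month == cal]
        count <- count + 1
      }
    }
    n_at[i] <- count
    if (count > 0) sync[i] <- total / count
  }
  list(sync_dev = sync, n_at_month = n_at)
}

# exact two-sided rank-sum p by explicit enumeration of label assignments
enum_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  idx_sets <- utils::combn(length(r), nx)
  n_sets <- ncol(idx_sets)
  low <- high <- 0
  for (j in seq_len(n_sets)) {
    w <- sum(r[idx_sets[, j]])
    if (w <= w_obs + 1e-9) low <- low + 1
    if (w >= w_obs - 1e-9) high <- high + 1
  }
  min(1, 2 * min(low / n_sets, high / n_sets))
}

# closed-form simple OLS via the normal equations
ols_normal_equations <- function(y) {
  t <- seq_along(y)
  n <- length(y)
  st <- sum(t); sy <- sum(y); sty <- sum(t * y); stt <- sum(t^2)
  slope <- (n * sty - st * sy) / (n * stt - st^2)
  intercept <- (sy - slope * st) / n
  list(slope = slope, intercept = intercept)
}

# a 12-month sinusoidal seasonal profile of given amplitude (percent)
sin_profile <- function(amplitude, phase = 0) {
  m <- 1:12
  data.frame(month = m,
             mean_dev = amplitude * sin(2 * pi * (m - 1) / 12 + phase),
             sd_dev = 0)
}

# small cohort config used across tests; any cohort_config argument can be
# overridden via ...
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = c(temperate = 10), n_test = c(temperate = 4),
         base_rate = 0.5, aging_slope = 0,
         month_multipliers = list(temperate = rep(1, 12)), seed = 11),
    list(...)
  )
  do.call(cohort_config, args)
}
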