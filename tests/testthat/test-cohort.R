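test_that("degenerate configurations are rejected", {
  expect_error(small_config(base_rate = 0), class = "seasonsync_config_error")
  expect_error(small_config(n_months = 6), class = "seasonsync_config_error")
  expect_error(small_config(los_dispersion = 0), class = "seasonsync_config_error")
  expect_error(small_config(los_mean = 0.5), class = "seasonsync_config_error")
  expect_error(
    cohort_config(n_patients = c(temperate = 5), n_test = c(temperate = 9)),
    class = "seasonsync_config_error"
  )
  expect_error(
    small_config(month_multipliers = list(temperate = c(rep(1, 11), -1))),
    class = "seasonsync_config_error"
  )
})

test_that("generation is reproducible from the seed, byte-for-byte", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "admissions.csv")),
                   readLines(file.path(d2, "admissions.csv")))
  c2 <- generate_cohort(small_config(seed = 12))
  expect_false(identical(a$admissions, c2$admissions))
})

test_that("seasonality-free cohort recovers the configured admission rate", {
  # ~10,800 patient-months; flat multipliers and no aging, so every
  # patient-month has Poisson mean base_rate
  cfg <- cohort_config(
    n_patients = c(temperate = 300), n_test = c(temperate = 0),
    base_rate = 0.4, aging_slope = 0,
    month_multipliers = list(temperate = rep(1, 12)), seed = 21
  )
  coh <- generate_cohort(cfg)
  n_pm <- 300 * cfg$n_months
  rate_hat <- nrow(coh$admissions) / n_pm
  se <- sqrt(cfg$base_rate / n_pm)
  expect_lt(abs(rate_hat - cfg$base_rate), 3 * se)
})

test_that("empirical LOS mean matches los_mean at large admission counts", {
  cfg <- cohort_config(
    n_patients = c(temperate = 300), n_test = c(temperate = 0),
    base_rate = 1.2, aging_slope = 0, los_mean = 6.3, los_dispersion = 1.2,
    month_multipliers = list(temperate = rep(1, 12)), seed = 22
  )
  coh <- generate_cohort(cfg)
  expect_gt(nrow(coh$admissions), 1e4)
  se <- stats::sd(coh$admissions$los_days) / sqrt(nrow(coh$admissions))
  expect_lt(abs(mean(coh$admissions$los_days) - 6.3), 3 * se)
  expect_true(all(coh$admissions$los_days >= 1))
})

test_that("cohort structure respects group, zone and commencement rules", {
  coh <- generate_cohort(cohort_config(seed = 5))
  expect_equal(nrow(coh$patients), 136)
  expect_equal(sum(coh$patients$group == "test"), 61)
  expect_equal(as.vector(table(coh$patients$zone)[c("subtropical", "temperate", "colder")]),
               c(37, 31, 68))
  # commencement present iff test
  expect_true(all(!is.na(coh$patients$commencement_month[coh$patients$group == "test"])))
  expect_true(all(is.na(coh$patients$commencement_month[coh$patients$group == "control"])))
  # all admissions within the configured window
  expect_true(all(format(coh$admissions$admit_date, "%Y") %in% c("2010", "2011", "2012")))
  # commencements fall in the 15-month window starting Jan 2013
  ci <- 12 * coh$patients$commencement_year + coh$patients$commencement_month - 1
  ci <- ci[!is.na(ci)]
  expect_true(all(ci >= 12 * 2013 & ci <= 12 * 2013 + 14))
})

test_that("commencement distributions follow their contracts", {
  # uniform with window 1: everyone commences in month 1
  expect_equal(generate_commencements("uniform", list(window = 1), 10, seed = 1),
               rep(1L, 10))
  # uniform over the 15-month trial window for 61 patients stays in range
  u <- generate_commencements("uniform", list(window = 15), 61, seed = 2)
  expect_length(u, 61)
  expect_true(all(u >= 1 & u <= 15))
  # observed list is returned verbatim
  obs <- c(3L, 3L, 7L, 1L)
  expect_identical(generate_commencements("observed", list(months = obs), 4), obs)
  expect_error(generate_commencements("observed", list(months = obs), 5),
               class = "seasonsync_config_error")
  # parameter validation
  expect_error(generate_commencements("poisson", list(lambda = 0, window = 15), 5),
               class = "seasonsync_config_error")
  expect_error(generate_commencements("uniform", list(window = 0), 5),
               class = "seasonsync_config_error")
})

test_that("poisson commencement draws have mean lambda before window mapping", {
  # with a window far beyond the draw range, the +1 shift is the only mapping
  x <- generate_commencements("poisson", list(lambda = 6.5, window = 1000),
                              10000, seed = 3)
  se <- sqrt(6.5 / 10000)
  expect_lt(abs(mean(x - 1) - 6.5), 3 * se)
  # clamping confines draws to the window
  y <- generate_commencements("poisson", list(lambda = 6.5, window = 15),
                              10000, seed = 4)
  expect_true(all(y >= 1 & y <= 15))
  expect_true(any(y == 15))  # mass beyond the window piles at its end
})
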