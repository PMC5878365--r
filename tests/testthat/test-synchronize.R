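test_that("single January patient monitored 12 months reproduces the zone profile", {
  p <- sin_profile(40)
  sched <- recruitment_schedule("z", 1, 12)
  sp <- synchronized_profile(list(z = p), sched)
  expect_equal(sp$sync_dev, p$mean_dev, tolerance = 1e-12)
  expect_equal(sp$n_patients, rep(1L, 12))
})

test_that("antiphase commencements cancel a sinusoidal profile exactly", {
  p <- sin_profile(100)
  sched <- recruitment_schedule(c("z", "z"), c(2, 8), 12)  # 6 months apart
  sp <- synchronized_profile(list(z = p), sched)
  expect_equal(sp$sync_dev, rep(0, 12), tolerance = 1e-12)
})

test_that("synchronized profile matches brute force on random schedules", {
  set.seed(301)
  profiles <- list(
    subtropical = sin_profile(80, phase = 0.4),
    temperate = sin_profile(120, phase = 2.1),
    colder = sin_profile(30, phase = 4.0)
  )
  for (r in 1:30) {
    n <- sample(1:10, 1)
    sched <- recruitment_schedule(
      sample(names(profiles), n, replace = TRUE),
      sample(1:12, n, replace = TRUE),
      sample(1:15, n, replace = TRUE)
    )
    sp <- synchronized_profile(profiles, sched)
    bf <- brute_force_sync(profiles, sched)
    expect_equal(sp$sync_dev, bf$sync_dev, tolerance = 1e-12)
    expect_equal(sp$n_patients, bf$n_at_month)
    # follow-up attrition makes patient counts non-increasing
    expect_true(all(diff(sp$n_patients) <= 0))
  }
})

test_that("61-patient schedule equals the double-loop brute force", {
  set.seed(302)
  profiles <- list(a = sin_profile(100), b = sin_profile(55, phase = 1.2))
  sched <- recruitment_schedule(
    sample(c("a", "b"), 61, replace = TRUE),
    sample(1:12, 61, replace = TRUE),
    sample(6:20, 61, replace = TRUE)
  )
  sp <- synchronized_profile(profiles, sched)
  bf <- brute_force_sync(profiles, sched)
  expect_equal(sp$sync_dev, bf$sync_dev, tolerance = 1e-12)
})

test_that("sync values are convex combinations of single-zone profile values", {
  set.seed(303)
  p <- sin_profile(70, phase = 0.9)
  sched <- recruitment_schedule(rep("z", 25), sample(1:12, 25, replace = TRUE),
                                sample(3:14, 25, replace = TRUE))
  sp <- synchronized_profile(list(z = p), sched)
  ok <- !is.na(sp$sync_dev)
  expect_true(all(sp$sync_dev[ok] >= min(p$mean_dev) - 1e-12))
  expect_true(all(sp$sync_dev[ok] <= max(p$mean_dev) + 1e-12))
})

test_that("months with no monitored patient are NA, and missing zones error", {
  p <- sin_profile(10)
  sched <- recruitment_schedule("z", 4, 3)  # only 3 months of follow-up
  sp <- synchronized_profile(list(z = p), sched)
  expect_true(all(is.na(sp$sync_dev[4:12])))
  expect_equal(sp$n_patients[4:12], rep(0L, 9))
  expect_error(synchronized_profile(list(other = p), sched),
               class = "seasonsync_config_error")
})

test_that("peak residual deviation scans all defined months", {
  p <- sin_profile(10)
  sp <- synchronized_profile(list(z = p), recruitment_schedule("z", 1, 12))
  flat <- synchronized_profile(
    list(z = data.frame(month = 1:12, mean_dev = 0, sd_dev = 0)),
    recruitment_schedule("z", 1, 12))
  expect_equal(max_sync_deviation(flat)$peak, 0)

  single <- synchronized_profile(
    list(z = data.frame(month = 1:12, mean_dev = c(-7, rep(0, 11)), sd_dev = 0)),
    recruitment_schedule("z", 1, 1))
  expect_equal(max_sync_deviation(single)$peak, 7)

  set.seed(304)
  for (r in 1:20) {
    prof <- data.frame(month = 1:12, mean_dev = rnorm(12, sd = 25), sd_dev = 0)
    sched <- recruitment_schedule(rep("z", 8), sample(1:12, 8, replace = TRUE),
                                  sample(1:12, 8, replace = TRUE))
    sp <- synchronized_profile(list(z = prof), sched)
    mx <- max_sync_deviation(sp)
    expect_equal(mx$peak, max(abs(sp$sync_dev), na.rm = TRUE))
  }
})

test_that("uniform commencements attenuate a sinusoid; same-month commencements do not", {
  amp <- 100
  p <- sin_profile(amp)
  peaks <- vapply(1:20, function(r) {
    months <- generate_commencements("uniform", list(window = 12), 1200,
                                     seed = 400 + r)
    sp <- synchronized_profile(list(z = p),
                               recruitment_schedule(rep("z", 1200), months, 12))
    max_sync_deviation(sp)$peak
  }, numeric(1))
  expect_lt(mean(peaks), 0.15 * amp)

  all_same <- synchronized_profile(list(z = p),
                                   recruitment_schedule(rep("z", 50), rep(3, 50), 12))
  expect_equal(max_sync_deviation(all_same)$peak, amp, tolerance = 1e-9)
})
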