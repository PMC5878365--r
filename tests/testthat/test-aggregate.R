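make_patients <- function(ids, zone = "temperate") {
  data.frame(patient_id = ids, group = "control", zone = zone,
             stringsAsFactors = FALSE)
}

test_that("monthly series sums outcomes per calendar month, zero-filling gaps", {
  pats <- make_patients("A")
  w <- month_window(2010, 1, 6)
  empty <- monthly_series(data.frame(patient_id = character(),
                                     admit_date = as.Date(character()),
                                     los_days = integer()),
                          pats, "admissions", w)
  expect_equal(empty$value, rep(0, 6))

  adm <- data.frame(
    patient_id = "A",
    admit_date = as.Date(c("2010-03-02", "2010-03-15", "2010-03-29")),
    los_days = c(2L, 3L, 5L)
  )
  counts <- monthly_series(adm, pats, "admissions", w)
  los <- monthly_series(adm, pats, "los", w)
  expect_equal(counts$value, c(0, 0, 3, 0, 0, 0))
  expect_equal(los$value, c(0, 0, 10, 0, 0, 0))
  expect_equal(counts$month, 1:6)
  expect_equal(counts$year, rep(2010, 6))
})

test_that("records outside the window are excluded with a message; unknown patients error", {
  pats <- make_patients("A")
  adm <- data.frame(patient_id = "A",
                    admit_date = as.Date(c("2009-12-31", "2010-01-05")),
                    los_days = c(1L, 1L))
  expect_message(
    s <- monthly_series(adm, pats, "admissions", month_window(2010, 1, 3)),
    "excluded 1"
  )
  expect_equal(sum(s$value), 1)
  adm_bad <- data.frame(patient_id = "GHOST",
                        admit_date = as.Date("2010-01-05"), los_days = 1L)
  expect_error(monthly_series(adm_bad, pats, "admissions", month_window(2010, 1, 3)),
               class = "seasonsync_data_error")
})

test_that("conservation: series totals equal in-window record totals for any filter", {
  coh <- generate_cohort(cohort_config(seed = 31))
  w <- month_window(2010, 1, 36)
  for (z in c("subtropical", "temperate", "colder")) {
    in_zone <- coh$patients$patient_id[coh$patients$zone == z]
    n_rec <- sum(coh$admissions$patient_id %in% in_zone)
    los_tot <- sum(coh$admissions$los_days[coh$admissions$patient_id %in% in_zone])
    expect_equal(sum(monthly_series(coh$admissions, coh$patients,
                                    "admissions", w, zone = z)$value), n_rec)
    expect_equal(sum(monthly_series(coh$admissions, coh$patients,
                                    "los", w, zone = z)$value), los_tot)
  }
})

test_that("season maps follow the southern-hemisphere conventions", {
  expect_equal(assign_season(6, "temperate"), "winter")
  expect_equal(assign_season(12, "temperate"), "summer")
  expect_equal(assign_season(1, "subtropical"), "summer")
  expect_equal(assign_season(5, "subtropical"), "winter")
  expect_equal(assign_season(10, "colder"), "spring")
  # partition: every month maps to exactly one season per zone
  for (z in c("subtropical", "temperate", "colder")) {
    s <- assign_season(1:12, z)
    expect_length(s, 12)
    expect_true(all(!is.na(s)))
  }
  expect_error(assign_season(6, "tropical"))
  expect_error(assign_season(13, "temperate"), class = "seasonsync_config_error")
})

test_that("season table reproduces published per-zone totals from expanded records", {
  fix <- season_records_from_totals(season_totals_example())
  st <- season_table(fix$admissions, fix$patients)
  zt <- st$by_zone
  expect_equal(zt$admissions[zt$zone == "colder"], 443)
  expect_equal(zt$admissions[zt$zone == "temperate"], 119)
  expect_equal(zt$admissions[zt$zone == "subtropical"], 255)
  expect_equal(zt$los[zt$zone == "colder"], 2178)
  expect_equal(zt$los[zt$zone == "temperate"], 478)
  expect_equal(zt$los[zt$zone == "subtropical"], 971)
  expect_equal(unname(st$total), c(817, 3627))
  # season totals sum to subgroup totals; within-zone shares sum to 100
  agg <- stats::aggregate(admissions ~ zone, st$by_season, sum)
  expect_equal(agg$admissions[match(zt$zone, agg$zone)], zt$admissions)
  shares <- stats::aggregate(admissions_pct ~ zone, st$by_season, sum)
  expect_equal(shares$admissions_pct, rep(100, 3), tolerance = 1e-12)
})

test_that("single-season input gives a 100% share; empty input errors", {
  pats <- make_patients(c("A", "B"))
  adm <- data.frame(patient_id = c("A", "B"),
                    admit_date = as.Date(c("2010-07-01", "2010-07-20")),
                    los_days = c(3L, 4L))
  st <- season_table(adm, pats)
  bs <- st$by_season
  expect_equal(bs$admissions_pct[bs$season == "winter"], 100)
  expect_equal(bs$admissions_pct[bs$season != "winter"], rep(0, 3))
  expect_error(season_table(adm[0, ], pats), class = "seasonsync_data_error")
})
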