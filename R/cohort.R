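#' Cosine calendar-month multipliers
#'
#' Convenience constructor for a 12-vector of positive seasonal multipliers
#' with mean exactly 1: `1 + amplitude * cos(2 * pi * (m - peak_month) / 12)`.
#' Used as the default generative seasonal effect per climate zone.
#'
#' @param peak_month Calendar month (1-12) at which the multiplier peaks.
#' @param amplitude Peak fractional excess over baseline; must satisfy
#'   `0 <= amplitude < 1` so all multipliers stay positive.
#' @return Numeric vector of length 12 (January first).
#' @export
cosine_multipliers <- function(peak_month, amplitude) {
  if (amplitude < 0 || amplitude >= 1) {
    stop_config("amplitude must be in [0, 1), got %g", amplitude)
  }
  1 + amplitude * cos(2 * pi * ((1:12) - peak_month) / 12)
}

default_month_multipliers <- function() {
  # winter/spring predominance in the south-eastern zones, a mild autumn
  # bump in the coldest zone, dry-season (austral winter) excess in the
  # subtropical zone; amplitudes sized to the per-zone season contrasts of
  # a multi-site Australian chronic-disease cohort
  list(
    subtropical = cosine_multipliers(7, 0.25),
    temperate   = cosine_multipliers(10, 0.35),
    colder      = cosine_multipliers(4, 0.05)
  )
}

#' Configuration for a synthetic hospitalization cohort
#'
#' Defines the generative model for a cohort of chronically ill patients:
#' monthly admission counts per patient are Poisson with mean
#' `base_rate * multiplier(zone, calendar month) * (1 + aging_slope * t)`,
#' where `t = 1..n_months` indexes months since the window start; each
#' admission's length of stay is `1 + NegBinom(mu = los_mean - 1,
#' size = los_dispersion)` so LOS is an integer of at least one day.
#'
#' Defaults emulate a 136-patient three-zone cohort observed over 36 months
#' (2010-2012) with 817 admissions in total, an average LOS per admission
#' near 6.3 days among multiply admitted patients, and test-group
#' commencement dates spread over a 15-month intervention window following
#' the baseline years.
#'
#' @param n_patients Named integer vector, patients per climate zone.
#' @param n_test Named integer vector, how many patients per zone belong to
#'   the telemonitoring test group (the rest are controls); test patients
#'   receive commencement dates.
#' @param start_year,start_month First calendar month of the observation
#'   window.
#' @param n_months Window length in months (>= 12; default 36 = 3 years).
#' @param base_rate Expected admissions per patient per month (> 0) at the
#'   start of the window, before the aging trend; the default is calibrated
#'   so that the expected total over the default window is about 817
#'   admissions (817 / (136 patients x 36 months) divided by the mean aging
#'   factor 1 + aging_slope * (n_months + 1) / 2).
#' @param aging_slope Fractional increase in admission rate per month of
#'   follow-up (>= 0), modelling secular deterioration of a chronically ill
#'   cohort.
#' @param month_multipliers Named list (one entry per zone) of 12 positive
#'   multipliers, January first. All multipliers equal to 1 defines a
#'   seasonality-free cohort.
#' @param los_mean Expected LOS days per admission (>= 1).
#' @param los_dispersion Negative-binomial size parameter (> 0); smaller
#'   values give more overdispersed stays.
#' @param commencement List with elements `dist` ("uniform", "poisson",
#'   "point" or "observed") and the parameters that
#'   [generate_commencements()] expects; commencement months are drawn on a
#'   window starting the month after the observation window ends.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = c(subtropical = 37, temperate = 31, colder = 68),
                          n_test = c(subtropical = 21, temperate = 17, colder = 23),
                          start_year = 2010, start_month = 1,
                          n_months = 36,
                          base_rate = 817 / (136 * 36) / 1.0925,
                          aging_slope = 0.005,
                          month_multipliers = NULL,
                          los_mean = 6.3,
                          los_dispersion = 1.2,
                          commencement = list(dist = "uniform", window = 15),
                          seed = 1L) {
  zones <- names(n_patients)
  if (is.null(zones) || any(!nzchar(zones))) {
    stop_config("n_patients must be a named vector of per-zone counts")
  }
  if (is.null(month_multipliers)) {
    month_multipliers <- default_month_multipliers()[zones]
    if (any(vapply(month_multipliers, is.null, logical(1)))) {
      stop_config("no default month_multipliers for zones outside {subtropical, temperate, colder}; supply month_multipliers")
    }
  }
  cfg <- structure(
    list(
      n_patients = n_patients, n_test = n_test,
      start_year = as.integer(start_year), start_month = as.integer(start_month),
      n_months = as.integer(n_months),
      base_rate = base_rate, aging_slope = aging_slope,
      month_multipliers = month_multipliers,
      los_mean = los_mean, los_dispersion = los_dispersion,
      commencement = commencement, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$base_rate <= 0) stop_config("base_rate must be > 0, got %g", cfg$base_rate)
  if (cfg$n_months < 12) stop_config("n_months must be >= 12, got %d", cfg$n_months)
  if (cfg$aging_slope < 0) stop_config("aging_slope must be >= 0")
  if (cfg$los_mean < 1) stop_config("los_mean must be >= 1 day, got %g", cfg$los_mean)
  if (cfg$los_dispersion <= 0) stop_config("los_dispersion must be > 0")
  if (cfg$start_month < 1 || cfg$start_month > 12) stop_config("start_month must be in 1..12")
  zones <- names(cfg$n_patients)
  if (!setequal(names(cfg$month_multipliers), zones)) {
    stop_config("month_multipliers must have one entry per zone")
  }
  if (!all(zones %in% names(cfg$n_test))) {
    stop_config("n_test must name every zone in n_patients")
  }
  for (z in zones) {
    m <- cfg$month_multipliers[[z]]
    if (length(m) != 12 || any(!is.finite(m)) || any(m <= 0)) {
      stop_config("month_multipliers[[%s]] must be 12 positive finite values", z)
    }
    if (cfg$n_test[[z]] > cfg$n_patients[[z]]) {
      stop_config("n_test exceeds n_patients in zone %s", z)
    }
  }
  cfg
}

#' Draw intervention commencement months
#'
#' Returns one window-relative commencement month (1 = first month of the
#' recruitment window) per patient under the requested recruitment
#' distribution.
#'
#' * `"uniform"`: independent discrete-uniform draws on `1..window`
#'   (the `unidrnd(window, 1, n)` call shape).
#' * `"poisson"`: independent Poisson(`lambda`) draws per patient
#'   (the `poissrnd(lambda, 1, n)` call shape); a raw draw of `k` is mapped
#'   to month `k + 1` and then clamped into `1..window`, so zero draws land
#'   in month 1 and draws beyond the window land in its last month.
#' * `"point"`: every patient commences in month `month`.
#' * `"observed"`: the supplied `months` vector is returned verbatim.
#'
#' @param dist Distribution name.
#' @param params List of parameters: `window` (uniform, poisson), `lambda`
#'   (poisson), `month` (point), `months` (observed).
#' @param n_patients Number of commencement months to return.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Integer vector of length `n_patients`, values in `1..window`.
#' @export
generate_commencements <- function(dist = c("uniform", "poisson", "point", "observed"),
                                   params = list(), n_patients, seed = NULL) {
  dist <- match.arg(dist)
  draw <- function() {
    switch(dist,
      uniform = {
        w <- params$window
        if (is.null(w) || w < 1) stop_config("uniform recruitment needs window >= 1")
        # inversion from one uniform per patient: paired simulations that
        # share a root seed then use common random numbers patient-by-patient
        1L + as.integer(floor(stats::runif(n_patients) * as.integer(w)))
      },
      poisson = {
        lambda <- params$lambda
        w <- params$window
        if (is.null(lambda) || lambda <= 0) stop_config("poisson recruitment needs lambda > 0")
        if (is.null(w) || w < 1) stop_config("poisson recruitment needs window >= 1")
        pmin(stats::qpois(stats::runif(n_patients), lambda) + 1L, as.integer(w))
      },
      point = {
        m <- params$month
        if (is.null(m) || m < 1) stop_config("point recruitment needs month >= 1")
        rep(as.integer(m), n_patients)
      },
      observed = {
        months <- params$months
        if (is.null(months)) stop_config("observed recruitment needs a months vector")
        if (length(months) != n_patients) {
          stop_config("observed months has length %d, expected %d",
                      length(months), n_patients)
        }
        as.integer(months)
      }
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic patient cohort with admission histories
#'
#' Simulates patients and their hospital admissions under the generative
#' model described in [cohort_config()]. Monthly admission counts per
#' patient are Poisson with a multiplicative calendar-month seasonal effect
#' and a linear aging trend; admission days are uniform within the month;
#' LOS is 1 + negative-binomial. Test patients get a commencement month
#' drawn on the recruitment window that starts immediately after the
#' observation window.
#'
#' @param config A [cohort_config()] object.
#' @return A list with two data frames:
#' \describe{
#'   \item{patients}{`patient_id`, `group` ("test"/"control"), `zone`,
#'     `age_years`, `sex`, `commencement_year`, `commencement_month`
#'     (`NA` for controls).}
#'   \item{admissions}{`patient_id`, `admit_date` (`Date`), `los_days`.}
#' }
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' nrow(coh$patients)
#' head(coh$admissions)
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  zones <- names(cfg$n_patients)
  zone <- rep(zones, times = cfg$n_patients)
  n <- length(zone)
  patient_id <- sprintf("P%04d", seq_len(n))
  group <- unlist(lapply(zones, function(z) {
    rep(c("test", "control"), c(cfg$n_test[[z]], cfg$n_patients[[z]] - cfg$n_test[[z]]))
  }), use.names = FALSE)

  # truncated-normal ages (cohort inclusion requires age >= 50)
  age <- stats::qnorm(stats::runif(n, stats::pnorm(50, 72.2, 9.4), 1), 72.2, 9.4)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.58, 0.42))

  start_idx <- month_index(cfg$start_year, cfg$start_month)
  is_test <- group == "test"
  comm_rel <- generate_commencements(cfg$commencement$dist, cfg$commencement,
                                     sum(is_test), seed = NULL)
  comm_idx <- start_idx + cfg$n_months + comm_rel - 1L
  commencement_year <- rep(NA_integer_, n)
  commencement_month <- rep(NA_integer_, n)
  commencement_year[is_test] <- index_year(comm_idx)
  commencement_month[is_test] <- index_month(comm_idx)

  patients <- data.frame(
    patient_id = patient_id, group = group, zone = zone,
    age_years = round(age, 1), sex = sex,
    commencement_year = commencement_year,
    commencement_month = commencement_month,
    stringsAsFactors = FALSE
  )

  # vectorized monthly Poisson counts over the patient x month grid
  t_idx <- seq_len(cfg$n_months)
  cal_month <- index_month(start_idx + t_idx - 1L)
  mult <- vapply(zone, function(z) cfg$month_multipliers[[z]][cal_month],
                 numeric(cfg$n_months))            # n_months x n patients
  rate <- cfg$base_rate * mult * (1 + cfg$aging_slope * t_idx)
  counts <- stats::rpois(length(rate), as.vector(rate))

  rec_month <- rep(rep(t_idx, n), counts)          # month-of-window per admission
  rec_patient <- rep(rep(patient_id, each = cfg$n_months), counts)
  n_adm <- length(rec_month)

  adm_idx <- start_idx + rec_month - 1L
  y <- index_year(adm_idx)
  m <- index_month(adm_idx)
  dim_days <- days_in_month(y, m)
  day <- pmin(dim_days, 1L + as.integer(stats::runif(n_adm) * dim_days))
  los <- 1L + stats::rnbinom(n_adm, size = cfg$los_dispersion, mu = cfg$los_mean - 1)

  admissions <- data.frame(
    patient_id = rec_patient,
    admit_date = as.Date(sprintf("%04d-%02d-%02d", y, m, day)),
    los_days = los,
    stringsAsFactors = FALSE
  )
  admissions <- admissions[order(admissions$admit_date, admissions$patient_id), ]
  rownames(admissions) <- NULL
  list(patients = patients, admissions = admissions)
}
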