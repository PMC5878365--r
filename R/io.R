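#' Read patient-level admission records from CSV
#'
#' Expects columns `patient_id`, `admit_date` (ISO-8601 `YYYY-MM-DD`),
#' `los_days`. Malformed rows (unparseable date, negative or missing LOS)
#' are dropped with a message naming their line numbers; if more than 1%
#' of rows are malformed the file is rejected.
#'
#' @param path CSV file with a header row.
#' @return Data frame of validated admission records.
#' @export
read_admissions <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "admit_date", "los_days")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop_data("missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    return(data.frame(patient_id = character(), admit_date = as.Date(character()),
                      los_days = integer(), stringsAsFactors = FALSE))
  }
  date <- as.Date(as.character(df$admit_date), format = "%Y-%m-%d")
  los <- suppressWarnings(as.numeric(df$los_days))
  bad <- is.na(date) | is.na(los) | los < 0 | los != round(los)
  if (any(bad)) {
    # +1 for the header line
    message(sprintf("read_admissions: rejected %d malformed row(s) at line(s) %s",
                    sum(bad), paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
    if (mean(bad) > 0.01) {
      stop_data("more than 1%% of rows are malformed (%d of %d)", sum(bad), nrow(df))
    }
  }
  data.frame(patient_id = as.character(df$patient_id)[!bad],
             admit_date = date[!bad],
             los_days = as.integer(los[!bad]),
             stringsAsFactors = FALSE)
}

#' Read the patient table from CSV
#'
#' Expects columns `patient_id`, `group`, `zone`, and optionally
#' `age_years`, `sex`, `commencement_year`, `commencement_month`.
#'
#' @param path CSV file with a header row.
#' @return Data frame of patients.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "zone")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop_data("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(duplicated(df$patient_id))) stop_data("duplicated patient_id values")
  bad_comm <- df$group == "test" & is.na(df$commencement_month %||% NA)
  if (length(bad_comm) > 0 && any(bad_comm, na.rm = TRUE)) {
    message(sprintf("read_patients: %d test patient(s) lack a commencement month",
                    sum(bad_comm, na.rm = TRUE)))
  }
  df
}

#' Write cohort tables to CSV
#'
#' @param cohort List with `patients` and `admissions` data frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             admissions = file.path(dir, "admissions.csv"))
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  adm <- cohort$admissions
  adm$admit_date <- format(adm$admit_date, "%Y-%m-%d")
  utils::write.csv(adm, paths["admissions"], row.names = FALSE)
  invisible(paths)
}

#' Run the full seasonal-variation analysis pipeline
#'
#' Executes, in order: cohort loading (or synthetic generation), monthly
#' aggregation per climate zone, linear baseline fits, percentage-deviation
#' seasonal profiles, the synchronized profile over the test patients'
#' commencement months, and the recruitment-distribution Monte-Carlo.
#' All artifacts are written as CSV under `output_dir` together with a run
#' log recording the seed and row counts. Any stage failure aborts with
#' the stage name.
#'
#' @param config A list, or path to a YAML file, with elements:
#' \describe{
#'   \item{input}{List with `admissions` and `patients` CSV paths
#'     (mutually exclusive with `generator`).}
#'   \item{generator}{List of [cohort_config()] arguments for a synthetic
#'     cohort (mutually exclusive with `input`).}
#'   \item{window}{List with `start_year`, `start_month`, `n_months`;
#'     defaults to the generator window or 36 months from the earliest
#'     admission.}
#'   \item{outcome}{`"los"` (default) or `"admissions"`.}
#'   \item{simulation}{Optional list: `dist`, `params`, `n_reps`,
#'     `n_patients` for [run_recruitment_simulation()]; defaults to
#'     discrete-uniform recruitment over a 15-month window, 100 replicates,
#'     as many patients as the schedule has.}
#'   \item{output_dir}{Where to write artifacts (required).}
#'   \item{seed}{Root seed for all randomness (default 1).}
#' }
#' @return Invisibly, a list with the per-zone series, fits, profiles, the
#'   synchronized profile, and the simulation result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop_config("config$output_dir is required")
  if (is.null(config$input) == is.null(config$generator)) {
    stop_config("exactly one of config$input or config$generator must be given")
  }
  seed <- as.integer(config$seed %||% 1L)
  outcome <- config$outcome %||% "los"
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("run_pipeline: ", line)
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$generator)) {
      gen_args <- config$generator
      gen_args$seed <- gen_args$seed %||% seed
      # YAML parses named vectors as lists; flatten them back
      for (fld in c("n_patients", "n_test")) {
        if (!is.null(gen_args[[fld]])) gen_args[[fld]] <- unlist(gen_args[[fld]])
      }
      if (!is.null(gen_args$month_multipliers)) {
        gen_args$month_multipliers <- lapply(gen_args$month_multipliers, as.numeric)
      }
      generate_cohort(do.call(cohort_config, gen_args))
    } else {
      list(patients = read_patients(config$input$patients),
           admissions = read_admissions(config$input$admissions))
    }
  })
  note("seed=%d; %d patients, %d admissions", seed,
       nrow(cohort$patients), nrow(cohort$admissions))

  window <- stage("window", {
    if (!is.null(config$window)) {
      do.call(month_window, config$window)
    } else if (!is.null(config$generator)) {
      g <- config$generator
      month_window(g$start_year %||% 2010, g$start_month %||% 1, g$n_months %||% 36)
    } else {
      first <- min(cohort$admissions$admit_date)
      month_window(as.integer(format(first, "%Y")),
                   as.integer(format(first, "%m")), 36)
    }
  })

  zones <- unique(cohort$patients$zone)
  series <- fits <- devs <- profiles <- stats::setNames(vector("list", length(zones)), zones)
  for (z in zones) {
    series[[z]] <- stage("aggregate", monthly_series(
      cohort$admissions, cohort$patients, outcome = outcome,
      window = window, zone = z))
    fits[[z]] <- stage("trend", fit_linear_trend(series[[z]]))
    devs[[z]] <- stage("seasonal", percent_deviation(series[[z]], fits[[z]]))
    profiles[[z]] <- stage("seasonal", seasonal_profile(devs[[z]], zone = z))
  }
  stab <- stage("aggregate", season_table(cohort$admissions, cohort$patients))

  sync <- stage("synchronize", {
    test <- cohort$patients[cohort$patients$group == "test" &
                              !is.na(cohort$patients$commencement_month), ,
                            drop = FALSE]
    if (nrow(test) == 0) NULL else {
      synchronized_profile(profiles, recruitment_schedule(
        test$zone, test$commencement_month,
        test$months_monitored %||% 12L))
    }
  })

  sim_cfg <- config$simulation %||%
    list(dist = "uniform", params = list(window = 15), n_reps = 100)
  sim <- stage("simulate", run_recruitment_simulation(
    profiles,
    n_patients = sim_cfg$n_patients %||%
      max(1L, sum(cohort$patients$group == "test")),
    dist = sim_cfg$dist, params = sim_cfg$params %||% list(),
    n_reps = sim_cfg$n_reps %||% 100, seed = seed))

  stage("write", {
    ms <- do.call(rbind, lapply(zones, function(z) {
      cbind(subgroup = z, outcome = outcome, series[[z]])
    }))
    utils::write.csv(ms, file.path(out_dir, "monthly_series.csv"), row.names = FALSE)
    utils::write.csv(stab$by_season, file.path(out_dir, "season_table.csv"),
                     row.names = FALSE)
    tf <- do.call(rbind, lapply(zones, function(z) {
      f <- fits[[z]]
      data.frame(subgroup = z, slope = f$slope, intercept = f$intercept,
                 r2 = f$r2, adj_r2 = f$adj_r2, rss = f$rss, rmse = f$rmse)
    }))
    utils::write.csv(tf, file.path(out_dir, "trend_fits.csv"), row.names = FALSE)
    sp <- do.call(rbind, lapply(zones, function(z) {
      cbind(zone = z, as.data.frame(profiles[[z]]))
    }))
    names(sp)[names(sp) == "mean_dev"] <- "mean_dev_pct"
    names(sp)[names(sp) == "sd_dev"] <- "sd_dev_pct"
    utils::write.csv(sp, file.path(out_dir, "seasonal_profile.csv"), row.names = FALSE)
    if (!is.null(sync)) {
      utils::write.csv(as.data.frame(sync), file.path(out_dir, "sync_profile.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(
      data.frame(replicate = seq_along(sim$peaks), peak_dev_pct = sim$peaks),
      file.path(out_dir, "sim_result.csv"), row.names = FALSE)
    note("simulation (%s): mean peak %.3f%% (SD %.3f%%)",
         sim$dist, sim$mean_peak, sim$sd_peak)
    writeLines(c(sprintf("seasonsync %s | R %s",
                         as.character(utils::packageVersion("seasonsync")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 log),
               file.path(out_dir, "run_log.txt"))
  })

  invisible(list(cohort = cohort, window = window, series = series, fits = fits,
                 profiles = profiles, season_table = stab, sync = sync, sim = sim))
}
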