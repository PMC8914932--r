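#' Read and write the sensing/simulation configuration
#'
#' One JSON file governs the calibration coefficients, the tactel layout,
#' the sensing and IMU thresholds, the calibration-inverse branch, and the
#' simulator parameters. `read_config()` returns ready-to-use objects;
#' `write_config()` serializes them. A reference configuration matching
#' the package defaults is bundled at
#' `system.file("extdata", "default_config.json", package = "spfgait")`.
#'
#' @param path JSON file path.
#' @return `read_config()`: list with elements `poly`
#'   ([calibration_polynomial()]), `layout` ([tactel_layout()]), `thr`
#'   ([sensing_thresholds()]), `imu_thr` ([imu_thresholds()]), `branch`,
#'   and `params` ([gait_profile_params()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("calibration", "layout", "thresholds")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop(sprintf("config is missing section(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  poly <- do.call(calibration_polynomial, as.list(cfg$calibration))
  layout <- tactel_layout(cfg$layout$yi, cfg$layout$region,
                          if (!is.null(cfg$layout$wyi)) cfg$layout$wyi
                          else rep(1, length(cfg$layout$yi)))
  thr <- do.call(sensing_thresholds, as.list(cfg$thresholds))
  imu_thr <- if (!is.null(cfg$imu_thresholds)) {
    do.call(imu_thresholds, as.list(cfg$imu_thresholds))
  } else imu_thresholds()
  branch <- if (!is.null(cfg$branch)) as.numeric(cfg$branch) else c(-2, 0)
  params <- if (!is.null(cfg$simulation)) {
    do.call(gait_profile_params, as.list(cfg$simulation))
  } else gait_profile_params()
  list(poly = poly, layout = layout, thr = thr, imu_thr = imu_thr,
       branch = branch, params = params)
}

#' @rdname read_config
#' @param config A list as returned by [read_config()] (objects allowed).
#' @export
write_config <- function(config, path) {
  out <- list(
    schema_version = 1L,
    calibration = unclass(config$poly),
    layout = list(yi = config$layout$yi, region = config$layout$region,
                  wyi = config$layout$wyi),
    thresholds = unclass(config$thr),
    imu_thresholds = unclass(config$imu_thr),
    branch = config$branch,
    simulation = unclass(config$params)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a trial to a directory of CSV files
#'
#' Emits `pressure.csv` (`time_s,v01..vNN`), `imu.csv`
#' (`time_s,ax,ay,az,wx`), `forceplate.csv` (`time_s,fz`), `truth.csv`
#' (events CSV) when ground truth is present, and `config.json`.
#'
#' @param trial A `synthetic_trial`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vmat <- trial$pressure$voltages
  pdf_ <- data.frame(time_s = trial$pressure$t, vmat)
  names(pdf_) <- c("time_s", sprintf("v%02d", seq_len(ncol(vmat))))
  utils::write.csv(pdf_, file.path(dir, "pressure.csv"), row.names = FALSE)
  idf <- data.frame(time_s = trial$imu$t, ax = trial$imu$ax,
                    ay = trial$imu$ay, az = trial$imu$az, wx = trial$imu$wx)
  utils::write.csv(idf, file.path(dir, "imu.csv"), row.names = FALSE)
  fdf <- data.frame(time_s = trial$fz$t, fz = trial$fz$fz)
  utils::write.csv(fdf, file.path(dir, "forceplate.csv"), row.names = FALSE)
  if (!is.null(trial$truth)) {
    write_events(trial$truth, file.path(dir, "truth.csv"),
                 detector = "TRUTH")
  }
  write_config(list(poly = trial$config$poly, layout = trial$config$layout,
                    thr = trial$config$thr, imu_thr = imu_thresholds(),
                    branch = trial$config$branch, params = trial$params),
               file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a trial from a directory of CSV files
#'
#' Counterpart of [write_trial()]. Validates that every expected column is
#' present, that timestamps are strictly increasing and uniform, that the
#' tactel column count matches the configured layout, and that the sampled
#' rates match the configured rates.
#'
#' @param dir Directory containing `pressure.csv`, `imu.csv`,
#'   `forceplate.csv`, `config.json`, and optionally `truth.csv`.
#' @return A `synthetic_trial` object (without `truth` if no truth file).
#' @export
read_trial <- function(dir) {
  cfg <- read_config(file.path(dir, "config.json"))
  need_file <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("trial file not found: %s", p),
                              call. = FALSE)
    p
  }
  need_cols <- function(df, cols, f) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing column(s): %s", f,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  check_rate <- function(t, fs, what) {
    if (length(t) > 1L) {
      dt <- diff(t)
      if (any(dt <= 0)) stop(sprintf("%s timestamps must be strictly increasing",
                                     what), call. = FALSE)
      if (abs(mean(dt) - 1 / fs) > 1e-6 / fs) {
        stop(sprintf("%s sampling rate %.6g Hz does not match configured %g Hz",
                     what, 1 / mean(dt), fs), call. = FALSE)
      }
    }
  }
  pcols <- sprintf("v%02d", seq_len(cfg$layout$count))
  pdf_ <- utils::read.csv(need_file("pressure.csv"))
  need_cols(pdf_, c("time_s", pcols), "pressure.csv")
  extra <- setdiff(names(pdf_), c("time_s", pcols))
  if (length(extra)) {
    stop(sprintf("pressure.csv has %d tactel columns but the layout has %d tactels",
                 ncol(pdf_) - 1L, cfg$layout$count), call. = FALSE)
  }
  check_rate(pdf_$time_s, cfg$params$fs_sensors, "pressure")
  idf <- utils::read.csv(need_file("imu.csv"))
  need_cols(idf, c("time_s", "ax", "ay", "az", "wx"), "imu.csv")
  check_rate(idf$time_s, cfg$params$fs_sensors, "imu")
  fdf <- utils::read.csv(need_file("forceplate.csv"))
  need_cols(fdf, c("time_s", "fz"), "forceplate.csv")
  check_rate(fdf$time_s, cfg$params$fs_forceplate, "force plate")
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) truth <- read_events(tp)
  structure(list(
    pressure = list(t = pdf_$time_s,
                    voltages = as.matrix(pdf_[, pcols, drop = FALSE])),
    imu = imu_series(t = idf$time_s, ax = idf$ax, ay = idf$ay, az = idf$az,
                     wx = idf$wx),
    fz = list(t = fdf$time_s, fz = fdf$fz),
    truth = truth,
    params = cfg$params,
    config = list(layout = cfg$layout, poly = cfg$poly, thr = cfg$thr,
                  branch = cfg$branch)
  ), class = "synthetic_trial")
}

#' Read and write gait events as CSV
#'
#' Events CSV dialect: columns `event_type` (`HS`|`TO`), `time_s`,
#' `detector` (`PS`|`IMU`|`FP`|`TRUTH`).
#'
#' @param events A [gait_events()] object.
#' @param path CSV file path.
#' @param detector Detector label written to / filtered from the file.
#' @return `read_events()`: a [gait_events()] object.
#' @export
write_events <- function(events, path, detector = NA_character_) {
  utils::write.csv(as.data.frame(events, detector = detector), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, detector = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("event_type", "time_s"), names(df))
  if (length(miss)) {
    stop(sprintf("events file is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(detector) && "detector" %in% names(df)) {
    df <- df[df$detector == detector, , drop = FALSE]
  }
  gait_events(hs = sort(df$time_s[df$event_type == "HS"]),
              to = sort(df$time_s[df$event_type == "TO"]))
}

#' Write and read a benchmark report as JSON
#'
#' The report JSON is schema-versioned and carries the per-trial and
#' grouped tables (event MAE/IQR in s and as % of stride, late-detection
#' fractions, stance-duration stats, Pearson/RMSE tables keyed by
#' variable, and mass-normalized vGRF peaks).
#'
#' @param report A `benchmark_report` from [benchmark_cohort()].
#' @param path JSON file path.
#' @return `read_report()`: the parsed report as a list.
#' @export
write_report <- function(report, path) {
  out <- list(schema_version = 1L, n_trials = report$n_trials,
              per_trial = report$per_trial, grouped = report$grouped)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
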