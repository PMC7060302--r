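# File readers/writers and run configuration. CSV dialect: UTF-8, comma
# separated, mandatory header, dot decimal separator. Reports are JSON;
# configuration is YAML.

#' Read a probe measurement CSV
#'
#' Expected columns: `time_iso` (ISO-8601 datetime), `counts`,
#' `duration_s`, `view`, `is_background`. Times are converted to hours
#' post administration.
#'
#' @param path CSV file path.
#' @param admin_datetime administration end time, anything
#'   `as.POSIXct()` accepts (UTC assumed).
#' @return a readings data.frame as accepted by
#'   [build_retention_curve()], with `time_h` relative to
#'   `admin_datetime` (background rows may be negative).
#' @export
read_probe_csv <- function(path, admin_datetime) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_iso", "counts", "duration_s", "view", "is_background")
  if (!all(req %in% names(df))) {
    stop("probe CSV must have columns: ", paste(req, collapse = ", "))
  }
  t0 <- as.POSIXct(admin_datetime, tz = "UTC")
  tt <- as.POSIXct(df$time_iso, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(tt)) stop("unparseable time_iso values in probe CSV")
  data.frame(time_h = as.numeric(difftime(tt, t0, units = "hours")),
             counts = df$counts, duration_s = df$duration_s,
             view = df$view, is_background = as.logical(df$is_background))
}

#' Read / write a time-activity CSV
#'
#' Columns: `time_h`, `activity_MBq` and optionally `sigma_MBq`.
#'
#' @param path CSV file path.
#' @param tac a data.frame with those columns (for writing).
#' @return `read_tac_csv` returns the data.frame.
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "activity_MBq") %in% names(df))) {
    stop("TAC CSV must have columns time_h, activity_MBq")
  }
  df
}

#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(tac, path) {
  write.csv(tac, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Sections: `patient` (`mass_kg`, optional `sigma_mass_kg`,
#' `admin_activity_MBq`, `admin_datetime`), `protocol`
#' (`target_wb_dose_Gy`, `n_fractions`, `alpha`), and optionally
#' `camera` (`Q_cps_per_MBq`, `tau_low_us`, `tau_high_us`,
#' `mode_switch_cps`).
#'
#' @param path YAML file path.
#' @return a validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$patient$mass_kg) || cfg$patient$mass_kg <= 0) {
    stop("config: patient$mass_kg must be a positive number")
  }
  if (!is.null(cfg$patient$admin_activity_MBq) &&
      cfg$patient$admin_activity_MBq <= 0) {
    stop("config: admin_activity_MBq must be positive")
  }
  if (is.null(cfg$protocol$alpha)) cfg$protocol$alpha <- 0.05
  if (is.null(cfg$patient$sigma_mass_kg)) cfg$patient$sigma_mass_kg <- 0
  cfg
}

#' Write a report as JSON
#'
#' Attaches provenance: package version, creation time and, for any file
#' paths passed, their MD5 hashes.
#'
#' @param report a named list.
#' @param path output JSON path.
#' @param input_paths character vector of input files to hash into the
#'   provenance block.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, input_paths = character()) {
  prov <- list(tool = "mibgdose",
               version = as.character(packageVersion("mibgdose")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (length(input_paths)) {
    prov$input_md5 <- as.list(tools::md5sum(input_paths))
  }
  report$provenance <- prov
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write / read a camera model as JSON
#'
#' Serialises the calibration factor, dead-time modes and (for a fitted
#' power-logistic curve) the recovery parameters; a piecewise-linear
#' fallback curve is stored as its measured points.
#'
#' @param camera a [camera_model()].
#' @param path JSON file path.
#' @return `read_camera_model` reconstructs the [camera_model()].
#' @export
write_camera_model <- function(camera, path) {
  stopifnot(inherits(camera, "camera_model"))
  rec <- NULL
  if (!is.null(camera$recovery)) {
    r <- camera$recovery
    rec <- list(method = r$method, volumes_ml = r$volumes_ml, R = r$R,
                R_max = r$R_max, v50 = r$v50, n = r$n)
  }
  obj <- list(Q_cps_per_MBq = camera$Q, tau_low_s = camera$tau_low_s,
              tau_high_s = camera$tau_high_s,
              mode_switch_cps = camera$mode_switch_cps, recovery = rec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_camera_model
#' @export
read_camera_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- NULL
  if (!is.null(obj$recovery) && length(obj$recovery)) {
    r <- obj$recovery
    if (identical(r$method, "power_logistic")) {
      rec <- structure(list(volumes_ml = r$volumes_ml, R = r$R,
                            R_max = r$R_max, v50 = r$v50, n = r$n,
                            method = "power_logistic", rss = NA_real_),
                       class = "recovery_curve")
    } else {
      Rmono <- cummax(r$R[order(r$volumes_ml)])
      v <- sort(r$volumes_ml)
      rec <- structure(list(volumes_ml = v, R = r$R[order(r$volumes_ml)],
                            R_max = max(Rmono), v50 = NA_real_,
                            n = NA_real_, method = "monotone_linear",
                            interp = approxfun(v, Rmono, rule = 2)),
                       class = "recovery_curve")
    }
  }
  sw <- obj$mode_switch_cps
  if (is.null(sw) || is.na(sw)) sw <- Inf
  camera_model(obj$Q_cps_per_MBq, recovery = rec,
               tau_low_s = obj$tau_low_s, tau_high_s = obj$tau_high_s,
               mode_switch_cps = sw)
}
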