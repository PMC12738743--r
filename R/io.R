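# File formats: IMU recordings as CSV (header row mandatory, metadata in
# leading '#' comment lines), LFP sessions as JSON (extra keys tolerated,
# as real device exports carry many), protocols as JSON segment arrays.
# Units on disk match the device description: acceleration in g, angular
# velocity in degrees/s; SI units appear only after preprocessing.

IMU_COLUMNS <- c("t_s", "acc_x_g", "acc_y_g", "acc_z_g",
                 "gyr_x_dps", "gyr_y_dps", "gyr_z_dps",
                 "q_w", "q_x", "q_y", "q_z")

#' Write an IMU recording to CSV
#'
#' @param rec an [imu_recording]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(rec$t, rec$accel, rec$gyro, rec$quat)
  names(df) <- IMU_COLUMNS
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# task: %s", rec$task), con)
  writeLines(sprintf("# placement: %s", rec$placement), con)
  writeLines(sprintf("# side: %s", rec$side), con)
  writeLines(sprintf("# fs_hz: %.10g", rec$fs), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' @param path input file path
#' @return an [imu_recording]
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 20)
  meta_lines <- grep("^#", header, value = TRUE)
  meta <- list(task = "FS", placement = "ankle", side = "right",
               fs_hz = NA_real_)
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(IMU_COLUMNS, names(df))
  if (length(missing)) {
    stop("IMU CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[IMU_COLUMNS]))
  if (length(bad)) {
    stop("malformed IMU rows (NA values) at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  fs <- as.numeric(meta$fs_hz)
  if (is.na(fs)) fs <- 1 / stats::median(diff(df$t_s))
  imu_recording(df$t_s,
                as.matrix(df[c("acc_x_g", "acc_y_g", "acc_z_g")]),
                as.matrix(df[c("gyr_x_dps", "gyr_y_dps", "gyr_z_dps")]),
                as.matrix(df[c("q_w", "q_x", "q_y", "q_z")]),
                fs, task = meta$task, placement = meta$placement,
                side = meta$side)
}

#' Write an LFP session to JSON
#'
#' @param session an [lfp_session]
#' @param path output file path
#' @param digits numeric precision for the JSON encoding
#' @return `path`, invisibly
#' @export
write_lfp_json <- function(session, path, digits = 10) {
  stopifnot(inherits(session, "lfp_session"))
  obj <- list(beta_peak_hz = session$beta_peak_hz,
              band_low_hz = session$band_low_hz,
              band_high_hz = session$band_high_hz,
              band_power = session$band_power,
              segments = as.data.frame(unclass(session$segments)),
              normalized = session$normalized)
  if (!is.null(session$raw)) {
    obj$raw <- list(fs = session$raw$fs, values = session$raw$values)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = digits)
  invisible(path)
}

#' Read an LFP session from JSON
#'
#' Extra keys are ignored; a missing `raw` channel only disables the
#' spectrum and time-frequency operations.
#'
#' @param path input file path
#' @return an [lfp_session]
#' @export
read_lfp_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("beta_peak_hz", "band_power", "segments")
  missing <- setdiff(req, names(obj))
  if (length(missing)) {
    stop("LFP JSON is missing key(s): ", paste(missing, collapse = ", "))
  }
  raw <- if (!is.null(obj$raw)) {
    list(fs = obj$raw$fs, values = as.numeric(obj$raw$values))
  }
  lfp_session(obj$beta_peak_hz, as.data.frame(obj$band_power),
              as.data.frame(obj$segments), raw = raw,
              normalized = isTRUE(obj$normalized))
}

#' Write a session protocol to JSON
#'
#' @param protocol a `session_protocol`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(as.data.frame(unclass(protocol)), path,
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a session protocol from JSON
#'
#' @param path input file path
#' @return a validated `session_protocol`
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seg <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- as.data.frame(seg)
  seg <- validate_segments(seg)
  class(seg) <- c("session_protocol", "data.frame")
  seg
}
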