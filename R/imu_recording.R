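# Data model and I/O for walk-test IMU recordings.
#
# A recording holds 12 signal channels sampled (possibly irregularly) against
# a strictly increasing timestamp vector: raw acceleration XYZ in the device
# frame, linear acceleration mapped onto body axes (AP, ML, vertical),
# angular velocity XYZ, and pelvis orientation (tilt, obliquity, rotation).

#' Internal channel names of an IMU recording
#'
#' Raw acceleration is kept in device axes; linear acceleration is stored in
#' body axes (anterior-posterior `ap`, medio-lateral `ml`, vertical `vert`)
#' after applying an [axis_convention()].
#'
#' @return character vector of the 12 channel names, in storage order.
#' @export
imu_channels <- function() {
  c("ax_raw", "ay_raw", "az_raw", "ap", "ml", "vert",
    "gx", "gy", "gz", "tilt", "obliquity", "rotation")
}

recording_csv_columns <- function() {
  c("time_s", "ax_raw", "ay_raw", "az_raw", "ax_lin", "ay_lin", "az_lin",
    "gx", "gy", "gz", "tilt", "obliquity", "rotation")
}

#' Device-to-body axis convention
#'
#' The phone is strapped to the posterior pelvis, but device XYZ axes must
#' still be mapped onto body axes. Each body axis is given as a signed device
#' axis, e.g. `"-z"`. The default (`ap = "+z"`, `ml = "+x"`, `vert = "+y"`)
#' corresponds to a portrait-oriented phone with the screen facing backwards:
#' device x points to the wearer's right (medio-lateral), y points up
#' (vertical), z points out of the screen (anterior-posterior).
#'
#' @param ap,ml,vert signed device axis (`"+x"`, `"-x"`, `"+y"`, `"-y"`,
#'   `"+z"`, `"-z"`) carrying each body axis.
#' @return an `axis_convention` object.
#' @export
axis_convention <- function(ap = "+z", ml = "+x", vert = "+y") {
  parse_axis <- function(s, what) {
    if (!is.character(s) || length(s) != 1L ||
        !grepl("^[+-]?[xyz]$", s)) {
      validation_error(sprintf("invalid axis spec for %s: %s", what, s))
    }
    sgn <- if (startsWith(s, "-")) -1 else 1
    list(axis = substr(s, nchar(s), nchar(s)), sign = sgn)
  }
  conv <- list(ap = parse_axis(ap, "ap"), ml = parse_axis(ml, "ml"),
               vert = parse_axis(vert, "vert"))
  axes <- vapply(conv, `[[`, "", "axis")
  if (anyDuplicated(axes)) {
    validation_error("axis convention must be a bijection over x, y, z")
  }
  structure(conv, class = "axis_convention")
}

#' Construct a validated IMU recording
#'
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param channels numeric matrix with one row per sample and the 12 columns
#'   of [imu_channels()] (any column order; names required).
#' @param participant_id opaque identifier string.
#' @param nominal_rate nominal sampling rate in Hz.
#' @return an `imu_recording` object.
#' @export
imu_recording <- function(timestamps, channels, participant_id = "",
                          nominal_rate = 50) {
  if (!is.numeric(timestamps) || length(timestamps) < 2L) {
    validation_error("recording needs at least 2 samples")
  }
  d <- diff(timestamps)
  if (any(d <= 0)) {
    validation_error(sprintf(
      "timestamps must be strictly increasing; first offending index: %d",
      which(d <= 0)[1] + 1L))
  }
  channels <- as.matrix(channels)
  if (is.null(colnames(channels)) ||
      !setequal(colnames(channels), imu_channels())) {
    validation_error("channels must have exactly the 12 named IMU channels")
  }
  channels <- channels[, imu_channels(), drop = FALSE]
  if (nrow(channels) != length(timestamps)) {
    validation_error("all channels must have the same length as timestamps")
  }
  if (!is_pos(nominal_rate)) validation_error("nominal_rate must be positive")
  structure(
    list(timestamps = as.numeric(timestamps), channels = channels,
         participant_id = as.character(participant_id),
         nominal_rate = nominal_rate),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  span <- diff(range(x$timestamps))
  cat(sprintf(
    "<imu_recording> %s: %d samples over %.2f s (nominal %.4g Hz, %s)\n",
    if (nzchar(x$participant_id)) x$participant_id else "(unnamed)",
    n_samples(x), span, x$nominal_rate,
    if (is_uniform(x)) "uniform" else "irregular"))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$timestamps)

#' Is a recording uniformly sampled?
#' @param rec an `imu_recording`.
#' @param tol relative spacing tolerance.
#' @return logical.
#' @export
is_uniform <- function(rec, tol = 1e-6) {
  d <- diff(rec$timestamps)
  h <- mean(d)
  all(abs(d - h) <= tol * h)
}

#' Extract one channel of a recording
#' @param rec an `imu_recording`.
#' @param channel one of [imu_channels()].
#' @return numeric vector.
#' @export
channel <- function(rec, channel) {
  if (!channel %in% imu_channels()) {
    validation_error(sprintf("unknown channel '%s'", channel))
  }
  rec$channels[, channel]
}

# signed device column lookup used by both reader and writer
body_from_device <- function(df, conv, body) {
  ax <- conv[[body]]
  ax$sign * df[[paste0("a", ax$axis, "_lin")]]
}

#' Read a walk-test recording from CSV
#'
#' Expects the 13-column export format with header
#' `time_s,ax_raw,ay_raw,az_raw,ax_lin,ay_lin,az_lin,gx,gy,gz,tilt,obliquity,rotation`.
#' Linear acceleration is mapped onto body axes via `convention`.
#'
#' @param path CSV file path.
#' @param convention an [axis_convention()].
#' @param participant_id identifier to attach; defaults to the file stem.
#' @param nominal_rate nominal rate in Hz.
#' @return an `imu_recording`.
#' @export
read_recording <- function(path, convention = axis_convention(),
                           participant_id = NULL, nominal_rate = 50) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(recording_csv_columns(), names(df))
  if (length(missing)) {
    format_error(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  ch <- cbind(
    ax_raw = df$ax_raw, ay_raw = df$ay_raw, az_raw = df$az_raw,
    ap = body_from_device(df, convention, "ap"),
    ml = body_from_device(df, convention, "ml"),
    vert = body_from_device(df, convention, "vert"),
    gx = df$gx, gy = df$gy, gz = df$gz,
    tilt = df$tilt, obliquity = df$obliquity, rotation = df$rotation)
  if (is.null(participant_id)) {
    participant_id <- tools::file_path_sans_ext(basename(path))
  }
  imu_recording(df$time_s, ch, participant_id, nominal_rate)
}

#' Write a recording to the canonical CSV dialect
#'
#' Inverse of [read_recording()]: body-axis linear acceleration is mapped
#' back to device axes under the same convention. Numbers are printed with 9
#' significant digits, which makes write -> read -> write a fixed point
#' (byte-identical files).
#'
#' @param rec an `imu_recording`.
#' @param path output path.
#' @param convention an [axis_convention()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, convention = axis_convention()) {
  dev <- list(x = NULL, y = NULL, z = NULL)
  for (body in c("ap", "ml", "vert")) {
    ax <- convention[[body]]
    dev[[ax$axis]] <- ax$sign * channel(rec, body)
  }
  df <- data.frame(
    time_s = rec$timestamps,
    ax_raw = channel(rec, "ax_raw"), ay_raw = channel(rec, "ay_raw"),
    az_raw = channel(rec, "az_raw"),
    ax_lin = dev$x, ay_lin = dev$y, az_lin = dev$z,
    gx = channel(rec, "gx"), gy = channel(rec, "gy"), gz = channel(rec, "gz"),
    tilt = channel(rec, "tilt"), obliquity = channel(rec, "obliquity"),
    rotation = channel(rec, "rotation"))
  lines <- c(paste(recording_csv_columns(), collapse = ","),
             do.call(paste, c(lapply(df, function(v) sprintf("%.9g", v)),
                              sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read foot-strike label files
#'
#' One 1-based integer sample index per line, or a two-column `index,time_s`
#' CSV (with or without header).
#'
#' @param path label file path.
#' @return integer vector of sample indices.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(integer(0))
  if (grepl("[A-Za-z]", lines[1])) lines <- lines[-1]  # header
  first <- vapply(strsplit(lines, ","), function(p) trimws(p[[1]]), "")
  idx <- suppressWarnings(as.integer(first))
  if (anyNA(idx)) format_error("label file contains non-integer indices")
  idx
}

#' Write foot-strike labels (one 1-based index per line)
#' @param indices integer sample indices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(indices, path) {
  writeLines(as.character(as.integer(indices)), path)
  invisible(path)
}
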