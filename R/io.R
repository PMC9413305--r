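#' Decode and encode 16-bit two's-complement sensor words
#'
#' IMU acquisition dumps each axis as an unsigned 16-bit decimal word
#' (0..65535); negative readings are stored in two's complement.
#' `decode_counts()` maps words to signed counts in -32768..32767 and
#' `encode_counts()` is its exact inverse. Both are vectorized bijections.
#'
#' @param word Integer vector of unsigned words in `[0, 65535]`.
#' @param count Integer vector of signed counts in `[-32768, 32767]`.
#' @return Signed counts (`decode_counts`) or unsigned words
#'   (`encode_counts`), as doubles holding exact integers.
#' @examples
#' decode_counts(c(0, 65535, 32768))  #  0  -1  -32768
#' encode_counts(decode_counts(0:10))
#' @export
decode_counts <- function(word) {
  word <- as.numeric(word)
  if (any(!is.finite(word)) || any(word < 0 | word > 65535) || any(word != trunc(word))) {
    abort("`word` must contain integers in [0, 65535]", class = "instep_input_error")
  }
  ifelse(word >= 32768, word - 65536, word)
}

#' @rdname decode_counts
#' @export
encode_counts <- function(count) {
  count <- as.numeric(count)
  if (any(!is.finite(count)) || any(count < -32768 | count > 32767) || any(count != trunc(count))) {
    abort("`count` must contain integers in [-32768, 32767]", class = "instep_input_error")
  }
  ifelse(count < 0, count + 65536, count)
}

#' Convert signed sensor counts to physical SI units
#'
#' Applies the full-scale ranges from the configuration: one least significant
#' bit equals `full_scale / 32768` of the physical range, so accelerations map
#' to m/s^2 (via standard gravity 9.80665 m/s^2) and angular rates to rad/s.
#'
#' @param counts A data frame with integer columns `ax, ay, az, gx, gy, gz`
#'   holding signed counts (see [decode_counts()]).
#' @param config An [imu_config()].
#' @return A tibble of IMU records: `t` (s), `ax, ay, az` (m/s^2),
#'   `gx, gy, gz` (rad/s).
#' @export
counts_to_si <- function(counts, config = imu_config()) {
  stopifnot(inherits(config, "imu_config"))
  need <- c("ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(counts))) {
    abort(sprintf("`counts` must have columns %s", paste(need, collapse = ", ")),
          class = "instep_input_error")
  }
  a_lsb <- config$accel_full_scale_g * STANDARD_GRAVITY / 32768
  g_lsb <- config$gyro_full_scale_dps * pi / 180 / 32768
  dt <- 1 / config$sample_rate_hz
  tibble(
    t = (seq_len(nrow(counts)) - 1) * dt,
    ax = counts$ax * a_lsb, ay = counts$ay * a_lsb, az = counts$az * a_lsb,
    gx = counts$gx * g_lsb, gy = counts$gy * g_lsb, gz = counts$gz * g_lsb
  )
}

parse_numeric_table <- function(path, what = "IMU stream") {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: '%s'", what, path), class = "instep_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) abort(sprintf("'%s' contains no data lines", path), class = "instep_parse_error")
  split_fields <- function(s) {
    s <- gsub(",", " ", trimws(s), fixed = TRUE)
    strsplit(s, "\\s+")[[1]]
  }
  fields <- lapply(lines[keep], split_fields)
  first <- suppressWarnings(as.numeric(fields[[1]]))
  header <- NULL
  if (anyNA(first)) {           # header row of column names
    header <- fields[[1]]
    fields <- fields[-1]
    keep <- keep[-1]
    if (!length(fields)) abort(sprintf("'%s' has a header but no data", path), class = "instep_parse_error")
  }
  ncol <- length(fields[[1]])
  nf <- lengths(fields)
  if (any(nf != ncol)) {
    bad <- keep[which(nf != ncol)[1]]
    abort(sprintf("line %d of '%s' has %d fields, expected %d",
                  bad, path, nf[which(nf != ncol)[1]], ncol),
          class = "instep_parse_error")
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(ncol)))
  vals <- if (ncol == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(vals)) {
    bad <- keep[which(rowSums(is.na(vals)) > 0)[1]]
    abort(sprintf("non-numeric field on line %d of '%s'", bad, path),
          class = "instep_parse_error")
  }
  list(values = vals, header = header, lines = keep)
}

#' Read an IMU sample stream from a text/CSV file
#'
#' One sample per line, comma- or whitespace-separated, with six channel
#' columns `ax ay az gx gy gz` and an optional leading integer sample-index
#' column (auto-detected). A header row is skipped if present. Files may hold
#' either raw unsigned 16-bit words (the acquisition dump) or pre-scaled
#' physical values; `values = "auto"` picks raw counts when every field is an
#' integer in `[0, 65535]`.
#'
#' @param path Input file.
#' @param config An [imu_config()]; supplies full-scale ranges, sampling rate,
#'   and the gyro unit used for physical-value files.
#' @param values `"auto"`, `"counts"` (unsigned words) or `"si"`
#'   (already-scaled physical values).
#' @return A tibble of records `t, ax, ay, az, gx, gy, gz` in SI units
#'   (m/s^2, rad/s).
#' @export
read_imu_csv <- function(path, config = imu_config(),
                         values = c("auto", "counts", "si")) {
  values <- match.arg(values)
  stopifnot(inherits(config, "imu_config"))
  parsed <- parse_numeric_table(path, "IMU stream")
  m <- parsed$values
  if (ncol(m) == 7) m <- m[, -1, drop = FALSE]  # leading sample index
  if (ncol(m) != 6) {
    abort(sprintf("'%s' has %d data columns; expected 6 (ax ay az gx gy gz) or 7 (with index)",
                  path, ncol(m)), class = "instep_parse_error")
  }
  if (values == "auto") {
    is_words <- all(m == trunc(m)) && all(m >= 0) && all(m <= 65535)
    values <- if (is_words) "counts" else "si"
  }
  if (values == "counts") {
    counts <- as_tibble(setNames(as.data.frame(m), c("ax", "ay", "az", "gx", "gy", "gz")))
    counts <- dplyr::mutate(counts, across(dplyr::everything(), decode_counts))
    counts_to_si(counts, config)
  } else {
    dt <- 1 / config$sample_rate_hz
    gyro_scale <- if (config$gyro_unit == "dps") pi / 180 else 1
    tibble(
      t = (seq_len(nrow(m)) - 1) * dt,
      ax = m[, 1], ay = m[, 2], az = m[, 3],
      gx = m[, 4] * gyro_scale, gy = m[, 5] * gyro_scale, gz = m[, 6] * gyro_scale
    )
  }
}

#' Write an IMU sample stream to CSV
#'
#' Inverse of [read_imu_csv()]. Raw count tables (columns `ax..gz` of signed
#' counts) are written as unsigned 16-bit words; SI record tables (with a `t`
#' column) are written as physical values with gyro in the configured unit.
#'
#' @param x A counts table or an SI records tibble.
#' @param path Output file.
#' @param config An [imu_config()] (used for the gyro unit of SI files).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(x, path, config = imu_config()) {
  is_si <- "t" %in% names(x)
  if (is_si) {
    gyro_scale <- if (config$gyro_unit == "dps") 180 / pi else 1
    out <- data.frame(
      ax = x$ax, ay = x$ay, az = x$az,
      gx = x$gx * gyro_scale, gy = x$gy * gyro_scale, gz = x$gz * gyro_scale
    )
  } else {
    out <- as.data.frame(lapply(x[c("ax", "ay", "az", "gx", "gy", "gz")], encode_counts))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a reconstructed kinematic track as CSV
#'
#' Columns: `index, t, ax, ay, az, vx, vy, vz, px, py, pz, stationary`
#' (world-frame gravity-free acceleration, velocity, position, and the
#' zero-velocity-update flag as 0/1).
#'
#' @param track A `kick_track` tibble from [reconstruct_track()].
#' @param path File path.
#' @return `write_track_csv()` returns `path` invisibly; `read_track_csv()`
#'   returns the track tibble.
#' @export
write_track_csv <- function(track, path) {
  out <- as.data.frame(track[c("t", "ax", "ay", "az", "vx", "vy", "vz",
                               "px", "py", "pz", "stationary")])
  out$stationary <- as.integer(out$stationary)
  out <- cbind(index = seq_len(nrow(out)), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  parsed <- parse_numeric_table(path, "track")
  cols <- c("index", "t", "ax", "ay", "az", "vx", "vy", "vz", "px", "py", "pz", "stationary")
  if (ncol(parsed$values) != length(cols)) {
    abort(sprintf("'%s' has %d columns; expected %d", path, ncol(parsed$values), length(cols)),
          class = "instep_parse_error")
  }
  out <- as_tibble(setNames(as.data.frame(parsed$values), cols))
  out$stationary <- out$stationary != 0
  out$index <- NULL
  new_kick_track(out)
}

#' Read a reference trajectory (t, x, y, z)
#'
#' Reference trajectories (for example digitized camera tracking) are CSV
#' files with one row per frame: time in seconds and 3D position in metres.
#' Optional `vx, vy, vz` velocity columns are used when present.
#'
#' @param path File path.
#' @return A tibble with columns `t, x, y, z` (and velocities if present).
#' @export
read_reference_csv <- function(path) {
  parsed <- parse_numeric_table(path, "reference trajectory")
  nc <- ncol(parsed$values)
  if (!nc %in% c(4, 7)) {
    abort(sprintf("'%s' has %d columns; expected 4 (t x y z) or 7 (with vx vy vz)", path, nc),
          class = "instep_parse_error")
  }
  cols <- if (nc == 4) c("t", "x", "y", "z") else c("t", "x", "y", "z", "vx", "vy", "vz")
  as_tibble(setNames(as.data.frame(parsed$values), cols))
}

#' Write a metrics or agreement report as JSON
#'
#' @param x A [kick_metrics()] or agreement object (anything `tidy()`-able to
#'   a flat list).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
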