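#' @keywords internal
"_PACKAGE"

# Internal time conventions: timestamps are POSIXct (UTC) in memory and
# ISO-8601 in files; arithmetic is done on numeric seconds. Epoch t covers
# the half-open interval [t, t + epoch_s).

.TIME_FMT <- "%Y-%m-%dT%H:%M:%OS"

.parse_iso <- function(x, path = "<input>") {
  t <- as.POSIXct(x, format = .TIME_FMT, tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad) > 0L) {
    stop(sprintf("%s: malformed timestamp at data row %d: '%s'",
                 path, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  t
}

.format_iso <- function(t) format(t, format = "%Y-%m-%dT%H:%M:%OS4", tz = "UTC")

.as_seconds <- function(t) as.numeric(t)

BRANDS <- c("AG", "GA")
PLACEMENTS <- c("hip", "wrist_dominant", "wrist_nondominant")

#' Construct a raw tri-axial acceleration recording
#'
#' A recording holds timestamped tri-axial samples in g units for one
#' device/placement. Samples are implicitly spaced at `1/sampling_rate` s
#' from `start_time`.
#'
#' @param samples numeric matrix with columns x, y, z, in g.
#' @param start_time POSIXct start of the recording (UTC).
#' @param sampling_rate samples per second (Hz); devices here record at 100 Hz.
#' @param brand `"AG"` (ActiGraph) or `"GA"` (GENEActiv).
#' @param placement one of `"hip"`, `"wrist_dominant"`, `"wrist_nondominant"`.
#' @param device_id free-text identifier.
#' @return object of class `raw_accel`.
#' @export
raw_accel <- function(samples, start_time, sampling_rate = 100,
                      brand = "AG", placement = "wrist_nondominant",
                      device_id = paste(brand, placement, sep = "_")) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns (x, y, z)")
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples))) stop("non-finite acceleration sample")
  if (any(abs(samples) > 8)) {
    stop("acceleration outside the +/-8 g device dynamic range")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  brand <- match.arg(brand, BRANDS)
  placement <- match.arg(placement, PLACEMENTS)
  start_time <- as.POSIXct(start_time, tz = "UTC")
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(device_id = device_id, brand = brand, placement = placement,
         sampling_rate = sampling_rate, start_time = start_time,
         samples = samples),
    class = "raw_accel")
}

#' @export
print.raw_accel <- function(x, ...) {
  cat(sprintf("<raw_accel> %s (%s, %s): %d samples @ %g Hz from %s (%.1f s)\n",
              x$device_id, x$brand, x$placement, nrow(x$samples),
              x$sampling_rate, .format_iso(x$start_time),
              nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Read a raw acceleration CSV
#'
#' Expects a header row and columns `timestamp,x,y,z`; timestamps ISO-8601,
#' acceleration in g. Timestamps must be strictly increasing; a gap larger
#' than one sample period is reported as a warning, a backwards step is an
#' error.
#'
#' @param path file to read.
#' @inheritParams raw_accel
#' @return a [raw_accel] recording.
#' @export
read_raw_accel <- function(path, brand = "AG",
                           placement = "wrist_nondominant",
                           sampling_rate = 100,
                           device_id = paste(brand, placement, sep = "_")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", NA, NA, NA))
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (any(is.na(v))) {
      stop(sprintf("%s: malformed value in column '%s' at data row %d",
                   path, cc,
                   if (length(bad)) bad[1L] else which(is.na(v))[1L]),
           call. = FALSE)
    }
    df[[cc]] <- v
  }
  t <- .parse_iso(df$timestamp, path)
  if (nrow(df) > 1L) {
    dt <- diff(.as_seconds(t))
    if (any(dt <= 0)) {
      stop(sprintf("%s: timestamps not strictly increasing at data row %d",
                   path, which(dt <= 0)[1L] + 1L), call. = FALSE)
    }
    period <- 1 / sampling_rate
    if (any(dt > 1.5 * period)) {
      warning(sprintf("%s: %d gap(s) exceeding one sample period",
                      path, sum(dt > 1.5 * period)), call. = FALSE)
    }
  }
  raw_accel(cbind(x = df$x, y = df$y, z = df$z), start_time = t[1L],
            sampling_rate = sampling_rate, brand = brand,
            placement = placement, device_id = device_id)
}

#' Write a raw acceleration recording to CSV
#'
#' @param rec a [raw_accel] recording.
#' @param path output file.
#' @export
write_raw_accel <- function(rec, path) {
  stopifnot(inherits(rec, "raw_accel"))
  n <- nrow(rec$samples)
  t <- rec$start_time + (seq_len(n) - 1L) / rec$sampling_rate
  df <- data.frame(timestamp = .format_iso(t),
                   x = sprintf("%.6f", rec$samples[, 1L]),
                   y = sprintf("%.6f", rec$samples[, 2L]),
                   z = sprintf("%.6f", rec$samples[, 3L]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a posture event log
#'
#' Event logs mirror thigh-logger "Event" exports: each event has a start
#' time, a positive duration in seconds, and a posture code
#' (0 sit/lie, 1 stand, 2 step). Events must be ordered and non-overlapping
#' (shared boundary instants are allowed).
#'
#' @param start POSIXct (or numeric seconds) event start times.
#' @param duration event durations in seconds, > 0.
#' @param code integer posture codes in \{0, 1, 2\}.
#' @return data.frame of class `posture_events` with columns
#'   `start`, `duration`, `code`.
#' @export
posture_events <- function(start, duration, code) {
  if (inherits(start, "POSIXct")) start <- as.POSIXct(start, tz = "UTC")
  duration <- as.numeric(duration)
  code <- as.integer(code)
  n <- length(duration)
  if (length(start) != n || length(code) != n) {
    stop("start, duration and code must have equal length")
  }
  if (n > 0L) {
    if (any(!code %in% 0:2)) {
      stop(sprintf("unknown posture code %s (must be 0, 1 or 2)",
                   code[!code %in% 0:2][1L]))
    }
    if (any(!is.finite(duration)) || any(duration <= 0)) {
      stop("event durations must be positive")
    }
    s <- .as_seconds(start)
    if (n > 1L) {
      if (any(diff(s) <= 0)) stop("event start times must be strictly increasing")
      # tolerance sized for double precision at absolute-epoch magnitudes
      if (any(s[-1L] < (s[-n] + duration[-n]) - 1e-5)) {
        stop("overlapping posture events")
      }
    }
  }
  structure(data.frame(start = start, duration = duration, code = code),
            class = c("posture_events", "data.frame"))
}

#' Read a posture event CSV
#'
#' Columns `start` (ISO-8601), `duration` (s), `code` (0/1/2).
#'
#' @param path file to read.
#' @return a [posture_events] log.
#' @export
read_posture_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", NA, NA))
  need <- c("start", "duration", "code")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  posture_events(.parse_iso(df$start, path), df$duration, df$code)
}

#' Write a posture event log to CSV
#' @param log a [posture_events] log.
#' @param path output file.
#' @export
write_posture_events <- function(log, path) {
  stopifnot(inherits(log, "posture_events"))
  df <- data.frame(start = .format_iso(log$start),
                   duration = sprintf("%.4f", log$duration),
                   code = log$code)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a 1 Hz (or slower) ENMO epoch series
#'
#' @param time POSIXct epoch start times.
#' @param enmo_mg epoch-mean ENMO in mg (1 mg = 1e-3 g); non-negative.
#' @param brand,placement,device_id device metadata carried through the
#'   pipeline.
#' @param epoch_s epoch length in seconds.
#' @return data.frame of class `epoch_series` with columns `time`, `enmo_mg`.
#' @export
epoch_series <- function(time, enmo_mg, brand = NA_character_,
                         placement = NA_character_,
                         device_id = NA_character_, epoch_s = 1) {
  enmo_mg <- as.numeric(enmo_mg)
  if (length(time) != length(enmo_mg)) stop("time/enmo length mismatch")
  if (any(!is.finite(enmo_mg)) || any(enmo_mg < -1e-12)) {
    stop("ENMO values must be finite and non-negative")
  }
  out <- data.frame(time = as.POSIXct(time, tz = "UTC"),
                    enmo_mg = pmax(enmo_mg, 0))
  structure(out, class = c("epoch_series", "data.frame"),
            brand = brand, placement = placement, device_id = device_id,
            epoch_s = epoch_s)
}

.carry_epoch_attrs <- function(to, from) {
  for (a in c("brand", "placement", "device_id", "epoch_s")) {
    attr(to, a) <- attr(from, a)
  }
  class(to) <- c("epoch_series", "data.frame")
  to
}

#' Write an epoch series to CSV
#'
#' ENMO is written in mg with 4 decimal places, giving a lossless
#' round-trip at that precision.
#'
#' @param series an [epoch_series].
#' @param path output file.
#' @export
write_epochs <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  df <- data.frame(time = .format_iso(series$time),
                   enmo_mg = sprintf("%.4f", series$enmo_mg))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch series CSV written by [write_epochs()]
#' @param path file to read.
#' @inheritParams epoch_series
#' @return an [epoch_series].
#' @export
read_epochs <- function(path, brand = NA_character_,
                        placement = NA_character_,
                        device_id = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", NA))
  if (!all(c("time", "enmo_mg") %in% names(df))) {
    stop(sprintf("%s: expected columns time, enmo_mg", path), call. = FALSE)
  }
  epoch_series(.parse_iso(df$time, path), df$enmo_mg, brand = brand,
               placement = placement, device_id = device_id)
}

#' Construct a wear log
#'
#' Ordered, non-overlapping intervals flagged worn / not worn, mirroring
#' participant log sheets of monitor removal.
#'
#' @param start,end POSIXct interval bounds.
#' @param worn logical.
#' @return data.frame of class `wear_log`.
#' @export
wear_log <- function(start, end, worn) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  worn <- as.logical(worn)
  n <- length(worn)
  if (length(start) != n || length(end) != n) stop("wear log length mismatch")
  if (n > 0L) {
    if (any(.as_seconds(end) <= .as_seconds(start))) {
      stop("wear intervals must have positive length")
    }
    if (n > 1L) {
      s <- .as_seconds(start)
      if (any(diff(s) <= 0)) stop("wear intervals must be ordered")
      if (any(s[-1L] < .as_seconds(end)[-n] - 1e-9)) {
        stop("overlapping wear intervals")
      }
    }
  }
  structure(data.frame(start = start, end = end, worn = worn),
            class = c("wear_log", "data.frame"))
}

#' Read/write wear logs
#' @param path CSV with columns `start`, `end` (ISO-8601), `worn` (TRUE/FALSE).
#' @return a [wear_log].
#' @export
read_wear_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", NA))
  if (!all(c("start", "end", "worn") %in% names(df))) {
    stop(sprintf("%s: expected columns start, end, worn", path), call. = FALSE)
  }
  wear_log(.parse_iso(df$start, path), .parse_iso(df$end, path),
           df$worn)
}

#' @rdname read_wear_log
#' @param log a [wear_log].
#' @export
write_wear_log <- function(log, path) {
  stopifnot(inherits(log, "wear_log"))
  df <- data.frame(start = .format_iso(log$start),
                   end = .format_iso(log$end), worn = log$worn)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable constants of the pipeline with their defaults:
#' 1 s epochs, 30 s transition trimming, central 4 min station window,
#' 07:00-21:00 analysis day, 10% equivalence zone with a 90% CI.
#'
#' @param epoch_s epoch length, s.
#' @param trim_s seconds trimmed from each end of a station bout.
#' @param central_s central analysis window within a station, s.
#' @param day_window_h start/end clock hours of the analysis day.
#' @param zone_fraction half-width of the equivalence zone as a fraction of
#'   the criterion mean.
#' @param equiv_conf confidence level of the equivalence CI.
#' @param seed base random seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(epoch_s = 1, trim_s = 30, central_s = 240,
                       day_window_h = c(7, 21), zone_fraction = 0.10,
                       equiv_conf = 0.90, seed = 1L) {
  stopifnot(epoch_s > 0, trim_s >= 0, central_s > 0,
            length(day_window_h) == 2L, day_window_h[1] < day_window_h[2],
            zone_fraction > 0, zone_fraction < 1,
            equiv_conf > 0, equiv_conf < 1)
  structure(list(epoch_s = epoch_s, trim_s = trim_s, central_s = central_s,
                 day_window_h = as.numeric(day_window_h),
                 zone_fraction = zone_fraction, equiv_conf = equiv_conf,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(y), known)
  if (length(extra) > 0L) {
    stop(sprintf("%s: unknown configuration key(s): %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(run_config, y)
}
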