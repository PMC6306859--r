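# Reduction of raw tri-axial acceleration to 1 Hz ENMO (mg).

#' Per-sample ENMO
#'
#' ENMO (Euclidean norm minus one) is the per-sample vector magnitude of
#' tri-axial acceleration minus 1 g, with negative values rounded up to
#' zero. Clipping is applied per sample, before any epoch averaging.
#'
#' @param rec a [raw_accel] recording, or an n x 3 numeric matrix in g.
#' @return numeric vector of per-sample ENMO in g (same length as input).
#' @export
compute_enmo <- function(rec) {
  m <- if (inherits(rec, "raw_accel")) rec$samples else as.matrix(rec)
  if (ncol(m) != 3L) stop("expected 3 acceleration components")
  if (!all(is.finite(m))) stop("non-finite acceleration sample")
  pmax(sqrt(rowSums(m * m)) - 1, 0)
}

#' Aggregate per-sample ENMO into epochs
#'
#' Each epoch value is the arithmetic mean of its samples' ENMO, converted
#' to mg. A trailing partial epoch is dropped with a warning, never padded.
#'
#' @param sample_enmo per-sample ENMO in g, as from [compute_enmo()].
#' @param sampling_rate samples per second.
#' @param epoch_s epoch length in seconds (default 1 s).
#' @param start_time POSIXct start of the first epoch.
#' @param brand,placement,device_id metadata carried on the result.
#' @return an [epoch_series] (ENMO in mg).
#' @export
aggregate_epochs <- function(sample_enmo, sampling_rate, epoch_s = 1,
                             start_time = as.POSIXct(0, tz = "UTC"),
                             brand = NA_character_,
                             placement = NA_character_,
                             device_id = NA_character_) {
  stopifnot(sampling_rate > 0, epoch_s > 0)
  spe <- sampling_rate * epoch_s
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch length must hold a whole number of samples")
  }
  spe <- as.integer(round(spe))
  n <- length(sample_enmo)
  k <- n %/% spe
  if (n %% spe != 0L) {
    warning(sprintf("dropping trailing partial epoch (%d sample(s))",
                    n %% spe), call. = FALSE)
  }
  if (k == 0L) {
    return(epoch_series(as.POSIXct(numeric(0), tz = "UTC",
                                   origin = "1970-01-01"),
                        numeric(0), brand, placement, device_id, epoch_s))
  }
  x <- sample_enmo[seq_len(k * spe)]
  means_g <- colMeans(matrix(x, nrow = spe, ncol = k))
  epoch_series(start_time + (seq_len(k) - 1L) * epoch_s, means_g * 1000,
               brand, placement, device_id, epoch_s)
}

#' Full reduction of a recording to an ENMO epoch series
#'
#' Convenience wrapper: [compute_enmo()] then [aggregate_epochs()], carrying
#' the recording's device metadata.
#'
#' @inheritParams compute_enmo
#' @inheritParams aggregate_epochs
#' @return an [epoch_series].
#' @export
enmo_epochs <- function(rec, epoch_s = 1) {
  stopifnot(inherits(rec, "raw_accel"))
  aggregate_epochs(compute_enmo(rec), rec$sampling_rate, epoch_s,
                   start_time = rec$start_time, brand = rec$brand,
                   placement = rec$placement, device_id = rec$device_id)
}

#' Extract the analysed window of a station bout
#'
#' The first and last `trim_s` seconds of the bout are discarded to remove
#' transitional movements, then the central `central_s` seconds of what
#' remains are returned. For a 300 s station with the defaults this is
#' exactly the central four minutes, seconds \[30, 270).
#'
#' @param series an [epoch_series] covering the station.
#' @param station_start,station_end POSIXct (or numeric seconds) bounds of
#'   the station bout.
#' @param trim_s seconds trimmed from each end (default 30).
#' @param central_s length of the retained central window (default 240).
#' @param station label used in error messages.
#' @return the windowed [epoch_series].
#' @export
extract_station_window <- function(series, station_start, station_end,
                                   trim_s = 30, central_s = 240,
                                   station = "station") {
  stopifnot(inherits(series, "epoch_series"))
  s0 <- .as_seconds(station_start)
  s1 <- .as_seconds(station_end)
  dur <- s1 - s0
  if (dur < 2 * trim_s + central_s - 1e-9) {
    stop(sprintf(
      "station '%s' too short (%.1f s) for %g s trimming + %g s window",
      station, dur, trim_s, central_s), call. = FALSE)
  }
  lo <- s0 + trim_s
  hi <- s1 - trim_s
  mid <- (lo + hi) / 2
  w0 <- mid - central_s / 2
  w1 <- mid + central_s / 2
  t <- .as_seconds(series$time)
  keep <- t >= w0 - 1e-9 & t < w1 - 1e-9
  .carry_epoch_attrs(series[keep, , drop = FALSE], series)
}
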