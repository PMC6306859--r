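# Small programmatic fixtures shared across test files.

T0 <- as.POSIXct("2018-03-01 09:00:00", tz = "UTC")

# A recording whose every sample has the given (x, y, z).
constant_recording <- function(xyz, n = 300, rate = 100, start = T0, ...) {
  raw_accel(matrix(rep(xyz, each = n), ncol = 3), start_time = start,
            sampling_rate = rate, ...)
}

# Epoch series on the integer-second grid.
make_epochs <- function(enmo_mg, start = T0, ...) {
  epoch_series(start + seq_along(enmo_mg) - 1, enmo_mg, ...)
}

# Posture seconds frame from bare codes.
make_seconds <- function(codes, start = T0) {
  structure(data.frame(second = start + seq_along(codes) - 1,
                       code = as.integer(codes)),
            class = c("posture_seconds", "data.frame"),
            duplicate_seconds = 0L)
}

# Well-separated station profiles: seated ENMO far below standing, which
# in turn sits far below walking, for all placements.
separated_profiles <- function() {
  p <- station_profiles()
  seated <- p$posture_code == 0
  stand <- p$station == "standing_phone"
  walk <- p$station == "walking"
  p$mean_mg[seated] <- 10; p$sd_mg[seated] <- 8
  p$mean_mg[stand] <- 150; p$sd_mg[stand] <- 25
  p$mean_mg[walk] <- 500; p$sd_mg[walk] <- 60
  p
}
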