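# Synthetic cohorts: a seven-station calibration protocol plus recess, and
# semi-Markov free-living days, with planted per-second ENMO so every
# downstream stage has a known truth.

STATIONS <- c("tv_viewing", "resting", "seated_tablet", "seated_lego",
              "seated_homework", "standing_phone", "walking")

#' Station ENMO target profiles
#'
#' Per-placement (mean, SD) targets in mg for the seven protocol stations,
#' with posture codes (seated stations and resting 0, standing with phone
#' 1, walking 2). The defaults are the ActiGraph calibration-study pooled
#' per-second outputs per station; GENEActiv devices receive an additive
#' latent-mean brand offset at simulation time (see [cohort_params()]).
#'
#' @return data.frame with columns `station`, `posture_code`, `placement`,
#'   `mean_mg`, `sd_mg`, `duration_s`.
#' @export
station_profiles <- function() {
  tbl <- rbind(
    # station, code, hip mean/sd, wrist_dom mean/sd, wrist_ndom mean/sd
    c("resting",         0,   8.9, 12.4,  23.5,  34.1,  18.7,  36.1),
    c("tv_viewing",      0,   5.5,  7.7,  15.2,  27.7,  15.8,  27.8),
    c("seated_tablet",   0,   8.4,  8.6,  21.5,  28.7,  18.6,  29.3),
    c("standing_phone",  1,   3.9,  8.1,  16.7,  19.2,  12.0,  23.5),
    c("seated_lego",     0,   6.5,  8.0,  32.8,  25.7,  21.8,  27.6),
    c("seated_homework", 0,   5.3,  8.5,  13.5,  19.8,   9.3,  19.1),
    c("walking",         2, 148.2, 51.5, 178.0, 139.3, 199.3, 131.0))
  station <- tbl[, 1L]
  code <- as.integer(tbl[, 2L])
  num <- apply(tbl[, 3:8], 2, as.numeric)
  out <- data.frame(
    station = rep(station, times = 3L),
    posture_code = rep(code, times = 3L),
    placement = rep(PLACEMENTS, each = length(station)),
    mean_mg = c(num[, 1L], num[, 3L], num[, 5L]),
    sd_mg = c(num[, 2L], num[, 4L], num[, 6L]),
    duration_s = 300,
    stringsAsFactors = FALSE)
  stopifnot(all(out$mean_mg >= 0), all(out$sd_mg >= 0))
  out
}

#' Cohort simulation parameters
#'
#' @param n_participants calibration cohort size (27 in the study design).
#' @param brand_offset additive latent-mean offset in mg for GENEActiv
#'   devices (the brands' global mean output difference, default 1.44 mg).
#' @param duplicate_second_prob probability that a posture transition is
#'   logged at a non-integer second, creating a duplicate second downstream.
#' @param posture_misclass_prob probability that a sit/lie bout is logged
#'   as standing by the posture logger.
#' @param sedentary_fraction expected sit/lie share of free-living worn
#'   time (default 0.666).
#' @param nonsed_stand_share expected stand share of non-sedentary
#'   free-living time (default 0.549).
#' @param sit_bout_mean_s mean free-living sit/lie bout length, s.
#' @param nonwear_rate expected number of non-wear bouts per free-living
#'   day (Poisson).
#' @param nonwear_min_range min/max length of a non-wear bout, minutes.
#' @param seed base seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 27L, brand_offset = 1.44,
                          duplicate_second_prob = 0.05,
                          posture_misclass_prob = 0.02,
                          sedentary_fraction = 0.666,
                          nonsed_stand_share = 0.549,
                          sit_bout_mean_s = 300,
                          nonwear_rate = 1,
                          nonwear_min_range = c(45, 120),
                          seed = 1L) {
  stopifnot(n_participants >= 1,
            duplicate_second_prob >= 0, duplicate_second_prob <= 1,
            posture_misclass_prob >= 0, posture_misclass_prob <= 1,
            sedentary_fraction > 0, sedentary_fraction <= 1,
            nonsed_stand_share >= 0, nonsed_stand_share <= 1,
            sit_bout_mean_s > 0, nonwear_rate >= 0)
  structure(list(n_participants = as.integer(n_participants),
                 brand_offset = brand_offset,
                 duplicate_second_prob = duplicate_second_prob,
                 posture_misclass_prob = posture_misclass_prob,
                 sedentary_fraction = sedentary_fraction,
                 nonsed_stand_share = nonsed_stand_share,
                 sit_bout_mean_s = sit_bout_mean_s,
                 nonwear_rate = nonwear_rate,
                 nonwear_min_range = nonwear_min_range,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

.schedule_df <- function(behaviour, posture_code, start, duration,
                         is_station) {
  structure(data.frame(behaviour = behaviour,
                       posture_code = as.integer(posture_code),
                       start = start, duration = as.numeric(duration),
                       is_station = is_station, stringsAsFactors = FALSE),
            class = c("activity_schedule", "data.frame"))
}

#' Protocol activity schedule
#'
#' Seven 300 s stations -- TV viewing always first, the remaining six in
#' seeded random order -- followed by at least 600 s of recess made of
#' alternating stand/step bouts of 5-60 s.
#'
#' @param params a [cohort_params] list.
#' @param seed RNG seed for the station order and recess bouts.
#' @param start_time POSIXct protocol start.
#' @param station_s station length in seconds (default 300).
#' @param recess_s minimum recess length in seconds (default 600).
#' @return data.frame of class `activity_schedule` with columns
#'   `behaviour`, `posture_code`, `start`, `duration`, `is_station`.
#' @export
make_protocol_schedule <- function(params = cohort_params(), seed = 1L,
                                   start_time = as.POSIXct(
                                     "2018-03-01 09:00:00", tz = "UTC"),
                                   station_s = 300, recess_s = 600) {
  set.seed(seed)
  prof <- station_profiles()
  codes <- prof$posture_code[match(STATIONS, prof$station)]
  names(codes) <- STATIONS
  rest <- sample(setdiff(STATIONS, "tv_viewing"))
  order_ <- c("tv_viewing", rest)
  dur <- rep(station_s, length(order_))
  # recess: alternating stand/step play bouts until the minimum is reached
  rb_beh <- character(0)
  rb_dur <- numeric(0)
  state <- sample(c("standing_phone", "walking"), 1L)
  while (sum(rb_dur) < recess_s) {
    rb_beh <- c(rb_beh, state)
    rb_dur <- c(rb_dur, round(stats::runif(1L, 5, 60)))
    state <- if (state == "walking") "standing_phone" else "walking"
  }
  beh <- c(order_, rb_beh)
  dur <- c(dur, rb_dur)
  st <- .as_seconds(start_time) + cumsum(c(0, dur[-length(dur)]))
  .schedule_df(beh, codes[beh],
               as.POSIXct(st, tz = "UTC", origin = "1970-01-01"), dur,
               c(rep(TRUE, length(order_)), rep(FALSE, length(rb_beh))))
}

.gamma_draw <- function(n, mean_mg, sd_mg) {
  if (mean_mg <= 0) return(rep(0, n))
  if (sd_mg <= 0) return(rep(mean_mg, n))
  shape <- (mean_mg / sd_mg)^2
  stats::rgamma(n, shape = shape, scale = sd_mg^2 / mean_mg)
}

.random_unit_vector <- function(n = 1L) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m * m))
}

# Expand planted per-second ENMO (mg) into raw samples: every second emits
# `rate` identical samples with vector magnitude 1 + e/1000 along the
# second's gravity direction, so per-second mean ENMO recovers e exactly.
# With sub_unit = TRUE the magnitude is 1 - e/1000 (floored at 0), which
# exercises the negative-clipping branch downstream (ENMO = 0).
.expand_to_samples <- function(e_mg, dir_per_sec, rate, sub_unit = FALSE) {
  mag <- if (sub_unit) pmax(1 - e_mg / 1000, 0) else 1 + e_mg / 1000
  idx <- rep(seq_along(e_mg), each = rate)
  dir_per_sec[idx, , drop = FALSE] * mag[idx]
}

#' Simulate a raw acceleration recording for a schedule
#'
#' Per second a latent epoch ENMO is drawn from a gamma distribution with
#' the scheduled behaviour's per-placement (mean, SD) in mg (GENEActiv
#' devices add the brand offset to the mean); the second's `sampling_rate`
#' samples all have vector magnitude 1 + e/1000 g along a per-bout random
#' gravity direction, so downstream 1 s epoch ENMO equals the planted
#' value to float tolerance.
#'
#' @param schedule an `activity_schedule`.
#' @param brand,placement device to simulate.
#' @param params a [cohort_params] (brand offset).
#' @param profiles per-placement targets, see [station_profiles()].
#' @param seed RNG seed.
#' @param sampling_rate Hz (default 100).
#' @param sub_unit emit sub-1 g magnitudes instead (downstream ENMO is 0).
#' @param device_id identifier for the recording.
#' @return a [raw_accel] with attribute `planted_e_mg` (the latent
#'   per-second ENMO).
#' @export
simulate_raw_signal <- function(schedule, brand = "AG",
                                placement = "wrist_nondominant",
                                params = cohort_params(),
                                profiles = station_profiles(), seed = 1L,
                                sampling_rate = 100, sub_unit = FALSE,
                                device_id = paste(brand, placement,
                                                  sep = "_")) {
  set.seed(seed)
  stopifnot(inherits(schedule, "activity_schedule"))
  brand <- match.arg(brand, BRANDS)
  placement <- match.arg(placement, PLACEMENTS)
  if (any(profiles$mean_mg < 0)) stop("negative target mean in profiles")
  prof <- profiles[profiles$placement == placement, ]
  miss <- setdiff(unique(schedule$behaviour), prof$station)
  if (length(miss) > 0L) {
    stop(sprintf("no %s profile for behaviour(s): %s", placement,
                 paste(miss, collapse = ", ")))
  }
  off <- if (brand == "GA") params$brand_offset else 0
  durs <- round(schedule$duration)
  n_sec <- sum(durs)
  e <- numeric(n_sec)
  dir <- matrix(0, n_sec, 3L)
  pos <- 0L
  for (b in seq_len(nrow(schedule))) {
    d <- durs[b]
    if (d == 0L) next
    p <- prof[prof$station == schedule$behaviour[b], ]
    e[pos + seq_len(d)] <- .gamma_draw(d, p$mean_mg + off, p$sd_mg)
    dir[pos + seq_len(d), ] <- matrix(.random_unit_vector(1L), d, 3L,
                                      byrow = TRUE)
    pos <- pos + d
  }
  samples <- .expand_to_samples(e, dir, sampling_rate, sub_unit)
  rec <- raw_accel(samples, start_time = schedule$start[1L],
                   sampling_rate = sampling_rate, brand = brand,
                   placement = placement, device_id = device_id)
  attr(rec, "planted_e_mg") <- e
  rec
}

#' Simulate the posture-logger event log for a schedule
#'
#' One event per scheduled bout. With probability
#' `posture_misclass_prob` a sit/lie bout is logged as standing (the
#' logger's sit-as-stand failure mode); with probability
#' `duplicate_second_prob` an interior transition is shifted to a
#' non-integer second (creating a duplicate second on expansion). Total
#' event time always equals the schedule duration.
#'
#' @param schedule an `activity_schedule`.
#' @param params a [cohort_params].
#' @param seed RNG seed.
#' @return a [posture_events] log.
#' @export
simulate_posture_log <- function(schedule, params = cohort_params(),
                                 seed = 1L) {
  set.seed(seed)
  stopifnot(inherits(schedule, "activity_schedule"))
  start <- .as_seconds(schedule$start)
  dur <- schedule$duration
  code <- schedule$posture_code
  sit <- which(code == 0L)
  if (length(sit) > 0L && params$posture_misclass_prob > 0) {
    flip <- stats::runif(length(sit)) < params$posture_misclass_prob
    code[sit[flip]] <- 1L
  }
  n <- length(dur)
  if (n > 1L && params$duplicate_second_prob > 0) {
    for (i in seq_len(n - 1L)) {
      if (stats::runif(1L) < params$duplicate_second_prob) {
        u <- stats::runif(1L, 0.15, 0.85)
        if (dur[i + 1L] > u + 0.2) {
          dur[i] <- dur[i] + u
          start[i + 1L] <- start[i + 1L] + u
          dur[i + 1L] <- dur[i + 1L] - u
        }
      }
    }
  }
  posture_events(as.POSIXct(start, tz = "UTC", origin = "1970-01-01"),
                 dur, code)
}

#' Simulate one free-living day
#'
#' Behaviour alternates between sit/lie and non-sedentary bouts over the
#' 07:00-21:00 day (semi-Markov with exponential bout lengths): sit bouts
#' have mean `sit_bout_mean_s` and draw their ENMO profile from a random
#' seated station; non-sedentary bouts are standing or stepping (stand
#' chosen with probability `nonsed_stand_share`) with mean length
#' `sit_bout_mean_s * (1 - f) / f` so the expected sit share of the day is
#' `f = sedentary_fraction`. Non-wear bouts (Poisson count, uniform
#' length) zero the wrist signal and are recorded in the wear log; the
#' posture logger keeps running.
#'
#' @param params a [cohort_params].
#' @param profiles per-placement targets, see [station_profiles()].
#' @param seed RNG seed.
#' @param date day being simulated (POSIXct midnight or "YYYY-MM-DD").
#' @param brands devices to emit (all on the non-dominant wrist).
#' @param placement wrist placement of the free-living devices.
#' @param sampling_rate Hz.
#' @param window_h clock-hour day window.
#' @param emit_recordings when `FALSE`, skip raw-signal synthesis and
#'   return only the schedule, posture log and wear log.
#' @return list with `recordings` (named by brand), `posture_log`,
#'   `wear_log`, `schedule`.
#' @export
simulate_freeliving_day <- function(params = cohort_params(),
                                    profiles = station_profiles(),
                                    seed = 1L, date = "2018-05-15",
                                    brands = c("AG", "GA"),
                                    placement = "wrist_nondominant",
                                    sampling_rate = 100,
                                    window_h = c(7, 21),
                                    emit_recordings = TRUE) {
  set.seed(seed)
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  t0 <- .as_seconds(day0) + window_h[1L] * 3600
  t1 <- .as_seconds(day0) + window_h[2L] * 3600
  total <- t1 - t0
  f <- params$sedentary_fraction
  m_sit <- params$sit_bout_mean_s
  m_non <- m_sit * (1 - f) / f
  seated <- c("resting", "tv_viewing", "seated_tablet", "seated_lego",
              "seated_homework")

  beh <- character(0); code <- integer(0); dur <- numeric(0)
  state_sit <- f >= 1 || stats::runif(1L) < f
  elapsed <- 0
  if (f >= 1) {
    # boundary: the whole day is one sit/lie bout
    beh <- sample(seated, 1L); code <- 0L; dur <- total; elapsed <- total
  }
  while (elapsed < total) {
    if (state_sit) {
      b <- sample(seated, 1L)
      d <- max(1, round(stats::rexp(1L, rate = 1 / m_sit)))
      cd <- 0L
    } else {
      stand <- stats::runif(1L) < params$nonsed_stand_share
      b <- if (stand) "standing_phone" else "walking"
      d <- max(1, round(stats::rexp(1L, rate = 1 / m_non)))
      cd <- if (stand) 1L else 2L
    }
    d <- min(d, total - elapsed)
    beh <- c(beh, b); code <- c(code, cd); dur <- c(dur, d)
    elapsed <- elapsed + d
    state_sit <- !state_sit
  }
  sched <- .schedule_df(beh, code,
                        as.POSIXct(t0 + cumsum(c(0, dur[-length(dur)])),
                                   tz = "UTC", origin = "1970-01-01"),
                        dur, FALSE)

  # non-wear bouts (wrist monitors only; the thigh logger keeps running)
  n_nw <- stats::rpois(1L, params$nonwear_rate)
  nw <- NULL
  if (n_nw > 0L) {
    len <- stats::runif(n_nw, params$nonwear_min_range[1L] * 60,
                        params$nonwear_min_range[2L] * 60)
    st <- sort(stats::runif(n_nw, t0, t1 - len))
    en <- pmin(st + len, t1)
    # merge overlapping bouts
    ks <- st[1L]; ke <- en[1L]
    if (n_nw > 1L) {
      for (i in 2L:n_nw) {
        if (st[i] <= ke[length(ke)]) {
          ke[length(ke)] <- max(ke[length(ke)], en[i])
        } else {
          ks <- c(ks, st[i]); ke <- c(ke, en[i])
        }
      }
    }
    nw <- cbind(ks, ke)
  }
  # wear log: alternate worn / not-worn intervals covering the day
  bounds <- c(t0, if (!is.null(nw)) as.vector(t(nw)), t1)
  ws <- bounds[-length(bounds)]
  we <- bounds[-1L]
  worn <- rep(c(TRUE, FALSE), length.out = length(ws))
  keep <- we > ws + 1e-9
  wl <- wear_log(as.POSIXct(ws[keep], tz = "UTC", origin = "1970-01-01"),
                 as.POSIXct(we[keep], tz = "UTC", origin = "1970-01-01"),
                 worn[keep])

  log <- simulate_posture_log(sched, params,
                              seed = (seed * 7L + 1L) %% .Machine$integer.max)

  sec_t <- t0 + seq_len(total) - 1
  nonwear_sec <- rep(FALSE, total)
  if (!is.null(nw)) {
    for (i in seq_len(nrow(nw))) {
      nonwear_sec <- nonwear_sec | (sec_t >= nw[i, 1L] & sec_t < nw[i, 2L])
    }
  }
  recs <- list()
  if (!emit_recordings) {
    return(list(recordings = recs, posture_log = log, wear_log = wl,
                schedule = sched))
  }
  for (br in brands) {
    rec <- simulate_raw_signal(
      sched, brand = br, placement = placement, params = params,
      profiles = profiles,
      seed = (seed * 131L + match(br, BRANDS)) %% .Machine$integer.max,
      sampling_rate = sampling_rate,
      device_id = paste(br, placement, "fl", sep = "_"))
    if (any(nonwear_sec)) {
      e <- attr(rec, "planted_e_mg")
      e[nonwear_sec] <- 0
      # monitor off-wrist: unit-gravity stillness
      idx <- which(rep(nonwear_sec, each = sampling_rate))
      rec$samples[idx, ] <- matrix(rep(c(0, 0, 1), each = length(idx)),
                                   ncol = 3L)
      attr(rec, "planted_e_mg") <- e
    }
    recs[[br]] <- rec
  }
  list(recordings = recs, posture_log = log, wear_log = wl,
       schedule = sched)
}
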