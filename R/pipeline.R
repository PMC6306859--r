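# End-to-end drivers: simulate the calibration protocol, derive the
# threshold table, and validate thresholds on simulated free-living days.

CALIBRATION_DEVICES <- data.frame(
  brand = c("AG", "AG", "AG", "GA", "GA"),
  placement = c("hip", "wrist_dominant", "wrist_nondominant",
                "wrist_dominant", "wrist_nondominant"),
  stringsAsFactors = FALSE)

.sub_seed <- function(seed, i, salt = 0L) {
  (as.integer(seed) * 1009L + i * 101L + salt) %% 2147483629L
}

#' Simulate a calibration cohort and pool labelled seconds
#'
#' For each participant: a protocol schedule (TV first, shuffled stations,
#' recess), a posture event log, and one recording per device of the
#' five-monitor roster (AG hip, AG/GA dominant and non-dominant wrists).
#' Recordings are reduced to 1 s ENMO; stations contribute their trimmed
#' central window, recess contributes in full; labels come from the
#' expanded posture log under both coding schemes; seconds are pooled
#' across participants.
#'
#' @param params a [cohort_params]; `params$n_participants` sets the
#'   cohort size.
#' @param profiles per-placement targets, see [station_profiles()].
#' @param seed base seed (participant-level seeds are derived from it).
#' @param devices device roster data.frame with columns `brand`,
#'   `placement`.
#' @param sampling_rate Hz of the simulated recordings.
#' @return data.frame with columns `participant`, `brand`, `placement`,
#'   `scheme`, `enmo_mg`, `label` ready for [calibrate_cohort()].
#' @export
simulate_calibration_cohort <- function(params = cohort_params(),
                                        profiles = station_profiles(),
                                        seed = 1L,
                                        devices = CALIBRATION_DEVICES,
                                        sampling_rate = 100) {
  trim_s <- 30
  central_s <- 240
  acc <- vector("list", params$n_participants * nrow(devices) * 2L)
  k <- 0L
  for (p in seq_len(params$n_participants)) {
    sched <- make_protocol_schedule(params, seed = .sub_seed(seed, p, 1L))
    plog <- simulate_posture_log(sched, params,
                                 seed = .sub_seed(seed, p, 2L))
    secs <- expand_to_seconds(plog)
    for (d in seq_len(nrow(devices))) {
      rec <- simulate_raw_signal(
        sched, brand = devices$brand[d], placement = devices$placement[d],
        params = params, profiles = profiles,
        seed = .sub_seed(seed, p, 2L + d), sampling_rate = sampling_rate)
      ep <- enmo_epochs(rec)
      st <- sched[sched$is_station, ]
      parts <- lapply(seq_len(nrow(st)), function(i) {
        extract_station_window(ep, st$start[i],
                               .as_seconds(st$start[i]) + st$duration[i],
                               trim_s = trim_s, central_s = central_s,
                               station = st$behaviour[i])
      })
      rec_ep <- ep[.as_seconds(ep$time) >=
                     min(.as_seconds(sched$start[!sched$is_station])), ,
                   drop = FALSE]
      used <- rbind(do.call(rbind, parts), rec_ep)
      used <- .carry_epoch_attrs(used, ep)
      for (sc in c("sedentary", "stationary")) {
        lab <- code_scheme(secs, sc)
        ds <- synchronize(used, lab, seconds = secs, scheme = sc)
        k <- k + 1L
        acc[[k]] <- data.frame(participant = p,
                               brand = devices$brand[d],
                               placement = devices$placement[d],
                               scheme = sc, enmo_mg = ds$enmo_mg,
                               label = ds$label,
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, acc[seq_len(k)])
}

#' Run the full calibration study on synthetic data
#'
#' [simulate_calibration_cohort()] followed by [calibrate_cohort()]:
#' 5 devices x 2 schemes = 10 threshold rows for the study roster.
#'
#' @inheritParams simulate_calibration_cohort
#' @return list with `data` (pooled labelled seconds) and `thresholds`
#'   (a `threshold_table`).
#' @export
run_calibration_study <- function(params = cohort_params(),
                                  profiles = station_profiles(),
                                  seed = 1L,
                                  devices = CALIBRATION_DEVICES,
                                  sampling_rate = 100) {
  dat <- simulate_calibration_cohort(params, profiles, seed, devices,
                                     sampling_rate)
  list(data = dat, thresholds = calibrate_cohort(dat))
}

#' Validate thresholds on simulated free-living days
#'
#' Simulates `n_days` free-living days (one participant-day each, AG and
#' GA on the non-dominant wrist), reduces each recording to valid-hour 1 s
#' ENMO, applies the brand's non-dominant-wrist thresholds with the strict
#' less-than rule, and assembles the agreement battery per brand x scheme.
#'
#' @param thresholds a `threshold_table` from [calibrate_cohort()] (must
#'   contain non-dominant-wrist rows for both schemes and brands).
#' @param n_days number of simulated participant-days.
#' @param params a [cohort_params].
#' @param profiles per-placement targets.
#' @param seed base seed.
#' @param sampling_rate Hz of the simulated recordings.
#' @param window_h clock-hour analysis window.
#' @return list with `minutes` (per participant-day x brand x scheme) and
#'   `reports` (one [agreement_report()] row per brand x scheme).
#' @export
run_freeliving_validation <- function(thresholds, n_days = 20L,
                                      params = cohort_params(),
                                      profiles = station_profiles(),
                                      seed = 1L, sampling_rate = 100,
                                      window_h = c(7, 21)) {
  th_of <- function(brand, scheme) {
    r <- thresholds[thresholds$brand == brand &
                      thresholds$placement == "wrist_nondominant" &
                      thresholds$scheme == scheme, ]
    if (nrow(r) != 1L || is.na(r$threshold_mg)) {
      stop(sprintf("missing %s %s non-dominant-wrist threshold",
                   brand, scheme))
    }
    r$threshold_mg
  }
  ths <- list(
    AG = c(sedentary = th_of("AG", "sedentary"),
           stationary = th_of("AG", "stationary")),
    GA = c(sedentary = th_of("GA", "sedentary"),
           stationary = th_of("GA", "stationary")))
  rows <- list()
  for (i in seq_len(n_days)) {
    day <- simulate_freeliving_day(params, profiles,
                                   seed = .sub_seed(seed, i, 17L),
                                   sampling_rate = sampling_rate,
                                   window_h = window_h)
    secs <- expand_to_seconds(day$posture_log)
    for (br in names(day$recordings)) {
      ep <- enmo_epochs(day$recordings[[br]])
      ep <- filter_valid_hours(ep, day$wear_log, window_h)
      if (nrow(ep) == 0L) next
      pm <- classify_and_summarize(ep, secs, ths[[br]],
                                   participant = sprintf("d%02d", i))
      pm$brand <- br
      rows[[length(rows) + 1L]] <- pm
    }
  }
  minutes <- do.call(rbind, rows)
  reports <- list()
  for (br in unique(minutes$brand)) {
    for (sc in c("sedentary", "stationary")) {
      m <- minutes[minutes$brand == br & minutes$scheme == sc, ]
      if (nrow(m) < 3L) next
      reports[[paste(br, sc, sep = "_")]] <-
        agreement_report(m$criterion_min, m$estimate_min,
                         label = paste(br, sc))
    }
  }
  list(minutes = minutes,
       reports = do.call(rbind, reports))
}
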