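test_that("protocol schedules start with TV, cover the protocol, and are seeded", {
  for (s in c(1, 9, 33)) {
    sch <- make_protocol_schedule(seed = s)
    expect_equal(sch$behaviour[1], "tv_viewing")
    expect_gte(sum(sch$duration), 7 * 300 + 600)
    expect_equal(sum(sch$is_station), 7L)
    # contiguous bouts
    st <- as.numeric(sch$start)
    expect_equal(st[-1], (st + sch$duration)[-nrow(sch)])
    # recess alternates stand/step
    rec <- sch$behaviour[!sch$is_station]
    expect_true(all(rec %in% c("standing_phone", "walking")))
    expect_true(all(rec[-1] != rec[-length(rec)]))
  }
  expect_identical(make_protocol_schedule(seed = 5),
                   make_protocol_schedule(seed = 5))
  expect_false(identical(make_protocol_schedule(seed = 5)$behaviour,
                         make_protocol_schedule(seed = 6)$behaviour))
})

test_that("station posture codes follow the protocol design", {
  p <- station_profiles()
  seated <- c("resting", "tv_viewing", "seated_tablet", "seated_lego",
              "seated_homework")
  expect_true(all(p$posture_code[p$station %in% seated] == 0))
  expect_true(all(p$posture_code[p$station == "standing_phone"] == 1))
  expect_true(all(p$posture_code[p$station == "walking"] == 2))
  expect_true(all(p$mean_mg >= 0 & p$sd_mg >= 0))
})

test_that("a zero-mean profile gives unit-magnitude samples and zero ENMO", {
  p <- station_profiles()
  p$mean_mg <- 0
  p$sd_mg <- 0
  sch <- make_protocol_schedule(seed = 1)[1:2, ]
  rec <- simulate_raw_signal(sch, profiles = p, seed = 2,
                             sampling_rate = 10)
  mags <- sqrt(rowSums(rec$samples^2))
  expect_equal(mags, rep(1, length(mags)), tolerance = 1e-12)
  expect_equal(enmo_epochs(rec)$enmo_mg, rep(0, 600), tolerance = 1e-12)
})

test_that("a planted constant 50 mg survives the full reduction", {
  p <- station_profiles()
  p$mean_mg <- 50
  p$sd_mg <- 0
  sch <- make_protocol_schedule(seed = 3)[1:2, ]
  rec <- simulate_raw_signal(sch, profiles = p, seed = 2,
                             sampling_rate = 20)
  expect_equal(enmo_epochs(rec)$enmo_mg, rep(50, 600), tolerance = 1e-9)
})

test_that("planted per-second ENMO is recovered exactly by the pipeline", {
  sch <- make_protocol_schedule(seed = 4)
  rec <- simulate_raw_signal(sch, seed = 5, sampling_rate = 25)
  ep <- enmo_epochs(rec)
  expect_lt(max(abs(ep$enmo_mg - attr(rec, "planted_e_mg"))), 1e-6) # 1e-9 g
})

test_that("the GA brand offset shifts the latent mean additively", {
  p <- station_profiles()
  p$mean_mg <- 30
  p$sd_mg <- 0
  sch <- make_protocol_schedule(seed = 6)[1:2, ]
  ag <- simulate_raw_signal(sch, brand = "AG", profiles = p, seed = 7,
                            sampling_rate = 5)
  ga <- simulate_raw_signal(sch, brand = "GA", profiles = p, seed = 7,
                            sampling_rate = 5)
  expect_equal(attr(ga, "planted_e_mg") - attr(ag, "planted_e_mg"),
               rep(1.44, 600), tolerance = 1e-12)
})

test_that("sub-unit magnitudes exercise negative clipping downstream", {
  sch <- make_protocol_schedule(seed = 8)[1:2, ]
  rec <- simulate_raw_signal(sch, seed = 9, sampling_rate = 10,
                             sub_unit = TRUE)
  expect_true(all(sqrt(rowSums(rec$samples^2)) <= 1 + 1e-12))
  expect_equal(enmo_epochs(rec)$enmo_mg, rep(0, 600))
})

test_that("a missing placement profile is a configuration error", {
  p <- station_profiles()
  p <- p[p$station != "walking", ]
  sch <- make_protocol_schedule(seed = 10)
  expect_error(simulate_raw_signal(sch, profiles = p, seed = 1,
                                   sampling_rate = 5), "walking")
  p2 <- station_profiles()
  p2$mean_mg[1] <- -5
  expect_error(simulate_raw_signal(sch, profiles = p2, seed = 1,
                                   sampling_rate = 5), "negative")
})

test_that("pooled station epochs converge to the planted target", {
  # 27 simulated participants' central resting windows, hip placement
  set.seed(84)
  vals <- unlist(lapply(1:27, function(i) {
    sch <- enmocut:::.schedule_df("resting", 0L, T0, 300, TRUE)
    rec <- simulate_raw_signal(sch, brand = "AG", placement = "hip",
                               seed = 8400 + i, sampling_rate = 5)
    ep <- enmo_epochs(rec)
    extract_station_window(ep, T0, T0 + 300)$enmo_mg
  }))
  expect_equal(length(vals), 27 * 240)
  # gamma standard error ~ 12.4 / sqrt(6480) ~ 0.15 mg; 2 mg >> 3 SE
  expect_lt(abs(mean(vals) - 8.9), 2)
  expect_lt(abs(sd(vals) - 12.4), 1.5)
})

test_that("posture logs mirror the schedule when jitter is off", {
  sch <- make_protocol_schedule(seed = 11)
  p0 <- cohort_params(duplicate_second_prob = 0, posture_misclass_prob = 0)
  log <- simulate_posture_log(sch, p0, seed = 12)
  expect_equal(as.numeric(log$start), as.numeric(sch$start))
  expect_equal(log$duration, sch$duration)
  expect_equal(log$code, sch$posture_code)
})

test_that("posture-log jitter conserves total time; misclass flips codes", {
  sch <- make_protocol_schedule(seed = 13)
  p1 <- cohort_params(duplicate_second_prob = 1, posture_misclass_prob = 1)
  log <- simulate_posture_log(sch, p1, seed = 14)
  expect_equal(sum(log$duration), sum(sch$duration))
  expect_equal(as.numeric(log$start[1]) + sum(log$duration),
               as.numeric(sch$start[1]) + sum(sch$duration))
  expect_true(all(log$code[sch$posture_code == 0] == 1))
  expect_gt(attr(expand_to_seconds(log), "duplicate_seconds"), 0)
})

test_that("free-living days are deterministic under a fixed seed", {
  d1 <- simulate_freeliving_day(seed = 15, sampling_rate = 2)
  d2 <- simulate_freeliving_day(seed = 15, sampling_rate = 2)
  expect_identical(d1$schedule, d2$schedule)
  expect_identical(d1$posture_log, d2$posture_log)
  expect_identical(d1$wear_log, d2$wear_log)
  expect_identical(d1$recordings$AG$samples, d2$recordings$AG$samples)
})

test_that("wear log and recordings cover the identical day span", {
  d <- simulate_freeliving_day(seed = 16, sampling_rate = 2)
  wl <- d$wear_log
  span <- sum(as.numeric(wl$end) - as.numeric(wl$start))
  expect_equal(span, 14 * 3600)
  for (rec in d$recordings) {
    expect_equal(nrow(rec$samples) / rec$sampling_rate, 14 * 3600)
    expect_equal(as.numeric(rec$start_time), as.numeric(wl$start[1]))
  }
  # schedule is contiguous over the day
  st <- as.numeric(d$schedule$start)
  expect_equal(st[-1], (st + d$schedule$duration)[-nrow(d$schedule)])
})

test_that("full sedentary fraction collapses the day to one sit/lie event", {
  pfull <- cohort_params(sedentary_fraction = 1, nonwear_rate = 0,
                         duplicate_second_prob = 0,
                         posture_misclass_prob = 0)
  d <- simulate_freeliving_day(pfull, seed = 17, emit_recordings = FALSE)
  expect_equal(nrow(d$posture_log), 1L)
  expect_equal(d$posture_log$code, 0L)
  expect_equal(d$posture_log$duration, 14 * 3600)
})

test_that("expected sit share of the day tracks the sedentary fraction", {
  p0 <- cohort_params(posture_misclass_prob = 0, nonwear_rate = 0)
  shares <- vapply(1:20, function(i) {
    d <- simulate_freeliving_day(p0, seed = 1700 + i,
                                 emit_recordings = FALSE)
    s <- d$schedule
    sum(s$duration[s$posture_code == 0]) / sum(s$duration)
  }, numeric(1))
  # delta-method SE of a renewal time-share with exponential bouts:
  # Var(day share) ~ f^2 (1-f)^2 (CV_sit^2 + CV_non^2) / n_cycles
  f <- 0.666
  n_cycles <- 14 * 3600 / (300 + 300 * (1 - f) / f)
  se <- sqrt(f^2 * (1 - f)^2 * 2 / n_cycles) / sqrt(20)
  expect_lt(abs(mean(shares) - f), 3 * se)
})
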