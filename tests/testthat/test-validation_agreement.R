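day_start <- as.POSIXct("2018-05-15 07:00:00", tz = "UTC")

full_day_epochs <- function(enmo = 0) {
  make_epochs(rep(enmo, length.out = 14 * 3600), start = day_start)
}

full_wear <- function() {
  wear_log(day_start, day_start + 14 * 3600, TRUE)
}

test_that("a fully worn day yields 14 valid hours", {
  ep <- filter_valid_hours(full_day_epochs(), full_wear())
  expect_equal(attr(ep, "valid_hours"), 14L)
  expect_equal(nrow(ep), 14 * 3600)
})

test_that("one non-wear minute invalidates its whole clock hour", {
  t1030 <- day_start + 3.5 * 3600
  wl <- wear_log(c(day_start, t1030, t1030 + 60),
                 c(t1030, t1030 + 60, day_start + 14 * 3600),
                 c(TRUE, FALSE, TRUE))
  ep <- filter_valid_hours(full_day_epochs(), wl)
  expect_equal(attr(ep, "valid_hours"), 13L)
  expect_equal(attr(ep, "excluded_hours"), 1L)
  expect_equal(nrow(ep), 13 * 3600)
  # the excluded hour is 10:00-11:00
  hrs <- unique(format(ep$time, "%H"))
  expect_false("10" %in% hrs)
})

test_that("non-wear spanning an hour boundary invalidates both hours", {
  a <- day_start + 2 * 3600 + 58 * 60   # 09:58
  b <- a + 4 * 60                       # 10:02
  wl <- wear_log(c(day_start, a, b),
                 c(a, b, day_start + 14 * 3600),
                 c(TRUE, FALSE, TRUE))
  ep <- filter_valid_hours(full_day_epochs(), wl)
  expect_equal(attr(ep, "valid_hours"), 12L)
  hrs <- unique(format(ep$time, "%H"))
  expect_false(any(c("09", "10") %in% hrs))
})

test_that("an empty filter result warns rather than errors", {
  wl <- wear_log(day_start, day_start + 14 * 3600, FALSE)
  expect_warning(ep <- filter_valid_hours(full_day_epochs(), wl),
                 "valid hours")
  expect_equal(nrow(ep), 0L)
})

test_that("classification counts strict below-threshold seconds", {
  n <- 600
  labs <- make_seconds(rep(0, n), start = day_start)
  ep0 <- make_epochs(rep(0, n), start = day_start)
  pm <- classify_and_summarize(ep0, labs, c(sedentary = 48), "p1")
  expect_equal(pm$estimate_min, n / 60)
  expect_equal(pm$criterion_min, n / 60)
  # ENMO exactly at the threshold is NOT below it
  ep48 <- make_epochs(rep(48, n), start = day_start)
  pm48 <- classify_and_summarize(ep48, labs, c(sedentary = 48), "p1")
  expect_equal(pm48$estimate_min, 0)
  expect_error(classify_and_summarize(ep0, labs, c(48), "p1"), "scheme")
})

test_that("classification equals a per-second recount on random input", {
  set.seed(85)
  n <- 2000
  enmo <- rgamma(n, 0.8, rate = 0.02)
  codes <- sample(0:2, n, replace = TRUE)
  ep <- make_epochs(enmo, start = day_start)
  labs <- make_seconds(codes, start = day_start)
  th <- c(sedentary = 45, stationary = 60)
  pm <- classify_and_summarize(ep, labs, th, "p1")
  sed <- pm[pm$scheme == "sedentary", ]
  expect_equal(sed$estimate_min, sum(enmo < 45) / 60)
  expect_equal(sed$criterion_min, sum(codes == 0) / 60)
  sta <- pm[pm$scheme == "stationary", ]
  expect_equal(sta$estimate_min, sum(enmo < 60) / 60)
  expect_equal(sta$criterion_min, sum(codes <= 1) / 60)
  expect_equal(sed$estimate_pct, 100 * sed$estimate_min / sed$wear_min)
})

test_that("higher stationary threshold implies more stationary minutes", {
  set.seed(86)
  for (i in 1:10) {
    enmo <- rgamma(500, 1, rate = 0.03)
    ep <- make_epochs(enmo, start = day_start)
    labs <- make_seconds(sample(0:2, 500, TRUE), start = day_start)
    th <- sort(runif(2, 10, 120))
    pm <- classify_and_summarize(ep, labs,
                                 c(sedentary = th[1], stationary = th[2]),
                                 "p")
    expect_gte(pm$estimate_min[pm$scheme == "stationary"],
               pm$estimate_min[pm$scheme == "sedentary"])
  }
})

test_that("Bland-Altman matches its closed form", {
  ba <- bland_altman(c(1, 2, 3), c(0, 2, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1.96, 1.96))
  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$bias, 0)
  expect_equal(same$loa, c(0, 0))
  set.seed(87)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    crit <- runif(n, 300, 700)
    est <- crit + rnorm(n, 20, 40)
    ba <- bland_altman(crit, est)
    d <- est - crit
    expect_equal(ba$bias, mean(d))
    expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d))
    expect_equal(ba$bias_ci,
                 mean(d) + c(-1, 1) * qt(0.975, n - 1) * sd(d) / sqrt(n))
    expect_true(ba$loa[1] <= ba$bias && ba$bias <= ba$loa[2])
  }
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman limits cover ~95% of large normal samples", {
  set.seed(88)
  crit <- rnorm(10000, 500, 50)
  est <- crit + rnorm(10000, 30, 25)
  ba <- bland_altman(crit, est)
  d <- est - crit
  cover <- mean(d >= ba$loa[1] & d <= ba$loa[2])
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("MPE/MAPE follow the criterion-minus-estimate sign convention", {
  r <- mpe_mape(c(100, 100), c(110, 90))
  expect_equal(r$mpe, 0)
  expect_equal(r$mape, 10)
  # one-directional error: |MPE| = MAPE
  r2 <- mpe_mape(c(100, 100), c(110, 120))
  expect_equal(r2$mpe, -15)
  expect_equal(r2$mape, 15)
  r3 <- mpe_mape(c(7, 9, 11), c(7, 9, 11))
  expect_equal(c(r3$mpe, r3$mape), c(0, 0))
  expect_warning(r4 <- mpe_mape(c(100, 0), c(90, 10)), "zero criterion")
  expect_equal(r4$n, 1)
})

test_that("|MPE| <= MAPE always; equality iff single-signed errors", {
  set.seed(89)
  for (i in 1:30) {
    n <- sample(3:30, 1)
    crit <- runif(n, 200, 800)
    est <- crit * runif(n, 0.7, 1.3)
    r <- mpe_mape(crit, est)
    expect_lte(abs(r$mpe), r$mape + 1e-12)
    pe <- (crit - est) / crit
    one_sided <- all(pe >= 0) || all(pe <= 0)
    expect_equal(abs(abs(r$mpe) - r$mape) < 1e-9, one_sided)
  }
})

test_that("paired comparison matches the textbook formulas", {
  same <- paired_comparison(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$cohen_d, 0)
  # constant shift: d = shift / SD under equal group SDs
  crit <- c(400, 500, 600, 700)
  est <- crit + 50
  pc <- paired_comparison(crit, est)
  expect_equal(pc$cohen_d, 50 / sd(crit))
  set.seed(90)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    crit <- runif(n, 300, 700)
    est <- crit + rnorm(n, 10, 30)
    pc <- paired_comparison(crit, est)
    d <- est - crit
    expect_equal(pc$t, mean(d) / (sd(d) / sqrt(n)))
    expect_equal(pc$p, 2 * pt(-abs(pc$t), n - 1))
    expect_equal(pc$cohen_d,
                 mean(d) / sqrt((var(est) + var(crit)) / 2))
  }
})

test_that("the equivalence zone and CI rule behave as documented", {
  expect_equal(equivalence_zone(594.6), c(535.14, 654.06))
  crit <- c(560, 590, 620, 610, 580)
  eq <- equivalence_test(crit, crit)
  expect_true(eq$equivalent)
  far <- crit + 200
  eq2 <- equivalence_test(crit, far)
  expect_false(eq2$equivalent)
  # CI outside the zone on one side only is still not equivalent
  set.seed(91)
  est <- crit * 1.1 + rnorm(5, 0, 2)
  eq3 <- equivalence_test(crit, est)
  expect_equal(eq3$zone, mean(crit) * c(0.9, 1.1))
  expect_equal(eq3$ci,
               mean(est) + c(-1, 1) * qt(0.95, 4) * sd(est) / sqrt(5))
})

test_that("Pearson correlation wraps the product-moment formula", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  set.seed(92)
  crit <- runif(20, 100, 900)
  est <- crit + rnorm(20, 0, 80)
  r <- pearson_r(crit, est)
  expect_equal(r$r, cor(crit, est))
  expect_error(pearson_r(rep(5, 4), 1:4), "variance")
})

test_that("the agreement report bundles consistent statistics", {
  set.seed(93)
  crit <- runif(15, 350, 650)
  est <- crit + rnorm(15, 25, 35)
  rep_ <- agreement_report(crit, est, label = "AG sedentary")
  expect_equal(rep_$mean_diff, mean(est - crit))
  expect_lte(abs(rep_$mpe), rep_$mape)
  expect_true(rep_$loa_lo <= rep_$mean_diff &&
                rep_$mean_diff <= rep_$loa_hi)
  expect_equal(rep_$zone_lo, 0.9 * mean(crit))
})

test_that("plots run without error on a toy cohort", {
  set.seed(94)
  crit <- runif(10, 400, 600)
  est <- crit + rnorm(10, 10, 20)
  f <- withr::local_tempfile(fileext = ".pdf")
  pdf(f)
  expect_no_error(plot_bland_altman(crit, est))
  expect_no_error(plot_equivalence(crit, list(AG = est, GA = est + 5)))
  dev.off()
})

test_that("end-to-end equivalence holds for well-separated planted classes", {
  # zero misclassification, zero brand offset, seated/standing/walking
  # ENMO distributions far apart: calibrated thresholds applied to
  # held-out free-living days must be equivalent under the 10% zone
  prof <- separated_profiles()
  pars <- cohort_params(n_participants = 6, brand_offset = 0,
                        duplicate_second_prob = 0,
                        posture_misclass_prob = 0, nonwear_rate = 0)
  cal <- run_calibration_study(params = pars, profiles = prof, seed = 95,
                               sampling_rate = 5)
  expect_equal(nrow(cal$thresholds), 10L)
  expect_true(all(cal$thresholds$status == "ok"))
  val <- run_freeliving_validation(cal$thresholds, n_days = 8,
                                   params = pars, profiles = prof,
                                   seed = 96, sampling_rate = 5)
  for (k in seq_len(nrow(val$reports))) {
    expect_true(val$reports$equivalent[k],
                info = val$reports$label[k])
    expect_lte(abs(val$reports$mpe[k]), val$reports$mape[k])
  }
})
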