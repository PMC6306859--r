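# Free-living validation: valid-hour filtering, threshold classification,
# and the method-agreement battery (paired t / Cohen's d, Bland-Altman,
# Pearson r, MPE/MAPE, 10%-zone equivalence testing).

#' Keep only valid clock hours of a free-living day
#'
#' A clock hour is valid when it lies wholly inside the analysis window
#' (07:00-21:00 by default) and the wear log shows zero non-wear during it
#' -- removal for any number of minutes invalidates the whole hour. Epochs
#' outside valid hours are dropped; the count of excluded in-window hours
#' is reported as attribute `excluded_hours`.
#'
#' @param epochs an [epoch_series].
#' @param wear a [wear_log] on the same clock.
#' @param window_h start/end clock hours of the analysis day.
#' @return the filtered [epoch_series]; attributes `valid_hours`,
#'   `excluded_hours`.
#' @export
filter_valid_hours <- function(epochs, wear, window_h = c(7, 21)) {
  stopifnot(inherits(epochs, "epoch_series"), inherits(wear, "wear_log"))
  t <- .as_seconds(epochs$time)
  if (nrow(epochs) == 0L) {
    warning("empty epoch series; no valid hours", call. = FALSE)
    return(structure(epochs, valid_hours = 0L, excluded_hours = 0L))
  }
  day0 <- floor(min(t) / 86400) * 86400 # midnight of the epoch's day (UTC)
  hours <- day0 + seq(window_h[1L], window_h[2L] - 1L) * 3600
  nw <- wear[!wear$worn, , drop = FALSE]
  nws <- .as_seconds(nw$start)
  nwe <- .as_seconds(nw$end)
  hour_ok <- vapply(hours, function(h0) {
    !any(nws < h0 + 3600 - 1e-9 & nwe > h0 + 1e-9)
  }, logical(1L))
  valid <- hours[hour_ok]
  keep <- t >= day0 + window_h[1L] * 3600 &
    t < day0 + window_h[2L] * 3600 &
    (floor(t / 3600) * 3600) %in% valid
  out <- .carry_epoch_attrs(epochs[keep, , drop = FALSE], epochs)
  if (!any(keep)) warning("no valid hours remain", call. = FALSE)
  structure(out, valid_hours = sum(hour_ok),
            excluded_hours = sum(!hour_ok))
}

#' Classify free-living seconds and summarize participant minutes
#'
#' Applies the strict less-than rule -- a second is sedentary/stationary
#' iff its ENMO lies below the scheme's threshold -- and accumulates
#' estimate and criterion minutes over the synchronized valid seconds.
#'
#' @param epochs a (valid-hour filtered) [epoch_series].
#' @param labels a `posture_seconds` frame from [expand_to_seconds()].
#' @param thresholds named numeric: threshold in mg per scheme, e.g.
#'   `c(sedentary = 48.1, stationary = 57.5)`.
#' @param participant participant identifier carried to the output.
#' @return data.frame of class `participant_minutes`, one row per scheme:
#'   `participant`, `scheme`, `wear_min`, `criterion_min`, `estimate_min`,
#'   `criterion_pct`, `estimate_pct`.
#' @export
classify_and_summarize <- function(epochs, labels, thresholds,
                                   participant = "p1") {
  stopifnot(inherits(epochs, "epoch_series"))
  schemes <- names(thresholds)
  if (is.null(schemes) || !all(schemes %in% c("sedentary", "stationary"))) {
    stop("thresholds must be named with schemes 'sedentary'/'stationary'")
  }
  rows <- lapply(schemes, function(sc) {
    lab <- code_scheme(labels, sc)
    ds <- synchronize(epochs, lab, seconds = labels, scheme = sc)
    wear_min <- nrow(ds) / 60
    est_min <- sum(ds$enmo_mg < thresholds[[sc]]) / 60
    crit_min <- sum(ds$label == 1L) / 60
    data.frame(participant = participant, scheme = sc,
               wear_min = wear_min, criterion_min = crit_min,
               estimate_min = est_min,
               criterion_pct = 100 * crit_min / wear_min,
               estimate_pct = 100 * est_min / wear_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("participant_minutes", "data.frame"))
}

.check_pairs <- function(criterion, estimate, min_n = 3L) {
  if (length(criterion) != length(estimate)) {
    stop("criterion/estimate length mismatch")
  }
  if (length(criterion) < min_n) {
    stop(sprintf("insufficient data: need at least %d pairs", min_n))
  }
  invisible(NULL)
}

#' Bland-Altman agreement
#'
#' Bias is the mean of (estimate - criterion); the 95% limits of agreement
#' are bias +/- 1.96 SD of the differences; the CI of the bias uses the
#' t-distribution.
#'
#' @param criterion,estimate per-participant minutes (paired).
#' @param conf confidence level of the bias CI.
#' @return list with `bias`, `sd_diff`, `loa` (lo, hi), `bias_ci` (lo, hi),
#'   `n`.
#' @export
bland_altman <- function(criterion, estimate, conf = 0.95) {
  .check_pairs(criterion, estimate)
  d <- estimate - criterion
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  list(bias = bias, sd_diff = s,
       loa = c(bias - 1.96 * s, bias + 1.96 * s),
       bias_ci = c(bias - tq * s / sqrt(n), bias + tq * s / sqrt(n)),
       n = n)
}

#' Mean (signed) and mean absolute percentage error
#'
#' Per-participant percentage error is (criterion - estimate) / criterion
#' x 100, so overestimation yields a *negative* MPE. Participants with a
#' zero criterion are excluded with a warning.
#'
#' @param criterion,estimate per-participant minutes (paired).
#' @return list with `mpe`, `mpe_sd`, `mape`, `mape_sd`, `n`.
#' @export
mpe_mape <- function(criterion, estimate) {
  if (length(criterion) != length(estimate)) {
    stop("criterion/estimate length mismatch")
  }
  keep <- criterion != 0
  if (!all(keep)) {
    warning(sprintf("excluding %d participant(s) with zero criterion",
                    sum(!keep)), call. = FALSE)
  }
  pe <- (criterion[keep] - estimate[keep]) / criterion[keep] * 100
  list(mpe = mean(pe), mpe_sd = stats::sd(pe),
       mape = mean(abs(pe)), mape_sd = stats::sd(abs(pe)),
       n = sum(keep))
}

#' Paired t-test and Cohen's d
#'
#' Two-sided paired t-test of estimate vs criterion. Cohen's d is the mean
#' difference divided by the pooled SD of the two measurements,
#' sqrt((sd_est^2 + sd_crit^2) / 2) -- an effect size on the
#' between-participant scale, not the SD of differences.
#'
#' @param criterion,estimate per-participant minutes (paired).
#' @return list with `t`, `df`, `p`, `mean_diff`, `cohen_d`, `n`.
#' @export
paired_comparison <- function(criterion, estimate) {
  .check_pairs(criterion, estimate)
  d0 <- estimate - criterion
  if (stats::sd(d0) == 0) {
    # degenerate paired test: identical differences everywhere
    tstat <- if (mean(d0) == 0) 0 else sign(mean(d0)) * Inf
    pooled <- sqrt((stats::var(estimate) + stats::var(criterion)) / 2)
    return(list(t = tstat, df = length(d0) - 1,
                p = if (mean(d0) == 0) 1 else 0,
                mean_diff = mean(d0),
                cohen_d = if (pooled > 0) mean(d0) / pooled else 0,
                n = length(d0)))
  }
  ht <- stats::t.test(estimate, criterion, paired = TRUE)
  pooled <- sqrt((stats::var(estimate) + stats::var(criterion)) / 2)
  d <- if (pooled > 0) mean(estimate - criterion) / pooled else 0
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(estimate - criterion),
       cohen_d = d, n = length(criterion))
}

#' Equivalence zone around a criterion mean
#'
#' @param criterion_mean mean criterion minutes.
#' @param zone_fraction half-width as a fraction of the mean (default 0.10).
#' @return numeric length-2: zone (lo, hi).
#' @export
equivalence_zone <- function(criterion_mean, zone_fraction = 0.10) {
  stopifnot(zone_fraction > 0, zone_fraction < 1)
  criterion_mean * c(1 - zone_fraction, 1 + zone_fraction)
}

#' Equivalence test against a proportional zone
#'
#' Two-one-sided-tests style presentation: the comparison measure is
#' declared equivalent to the criterion when the `conf`-level t-CI of its
#' mean lies entirely inside criterion mean x (1 +/- `zone_fraction`).
#'
#' @param criterion,estimate per-participant minutes (paired).
#' @param zone_fraction fraction of the criterion mean (default 0.10).
#' @param conf CI level of the estimate mean (default 0.90).
#' @return list with `zone` (lo, hi), `estimate_mean`, `ci` (lo, hi),
#'   `equivalent` (logical), `n`.
#' @export
equivalence_test <- function(criterion, estimate, zone_fraction = 0.10,
                             conf = 0.90) {
  .check_pairs(criterion, estimate)
  zone <- equivalence_zone(mean(criterion), zone_fraction)
  n <- length(estimate)
  m <- mean(estimate)
  se <- stats::sd(estimate) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  ci <- c(m - tq * se, m + tq * se)
  list(zone = zone, estimate_mean = m, ci = ci,
       equivalent = ci[1L] >= zone[1L] && ci[2L] <= zone[2L], n = n)
}

#' Pearson correlation between criterion and estimate
#'
#' @param criterion,estimate per-participant minutes (paired).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(criterion, estimate) {
  .check_pairs(criterion, estimate)
  if (stats::sd(criterion) == 0 || stats::sd(estimate) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(criterion, estimate)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(criterion))
}

#' Full agreement report for one device x scheme
#'
#' Bundles the whole battery -- means, paired t and Cohen's d,
#' Bland-Altman, MPE/MAPE, Pearson r, equivalence -- into one row of a
#' published-style agreement table.
#'
#' @param criterion,estimate per-participant minutes (paired).
#' @param label comparison label (e.g. `"AG sedentary"`).
#' @param zone_fraction,equiv_conf equivalence-test settings.
#' @return one-row data.frame of class `agreement_report`.
#' @export
agreement_report <- function(criterion, estimate, label = "comparison",
                             zone_fraction = 0.10, equiv_conf = 0.90) {
  ba <- bland_altman(criterion, estimate)
  pe <- mpe_mape(criterion, estimate)
  tt <- paired_comparison(criterion, estimate)
  rr <- pearson_r(criterion, estimate)
  eq <- equivalence_test(criterion, estimate, zone_fraction, equiv_conf)
  out <- data.frame(
    label = label, n = ba$n,
    criterion_mean = mean(criterion), criterion_sd = stats::sd(criterion),
    estimate_mean = mean(estimate), estimate_sd = stats::sd(estimate),
    mean_diff = ba$bias, t = tt$t, p = tt$p, cohen_d = tt$cohen_d,
    loa_lo = ba$loa[1L], loa_hi = ba$loa[2L],
    bias_ci_lo = ba$bias_ci[1L], bias_ci_hi = ba$bias_ci[2L],
    mpe = pe$mpe, mpe_sd = pe$mpe_sd, mape = pe$mape, mape_sd = pe$mape_sd,
    r = rr$r, r_p = rr$p,
    zone_lo = eq$zone[1L], zone_hi = eq$zone[2L],
    equiv_ci_lo = eq$ci[1L], equiv_ci_hi = eq$ci[2L],
    equivalent = eq$equivalent,
    stringsAsFactors = FALSE)
  structure(out, class = c("agreement_report", "data.frame"))
}

#' Bland-Altman plot
#'
#' Scatter of differences against pair means with the bias (solid), its CI
#' (dotted) and the 95% limits of agreement (dashed).
#'
#' @inheritParams bland_altman
#' @param main plot title.
#' @export
plot_bland_altman <- function(criterion, estimate, main = "Bland-Altman") {
  ba <- bland_altman(criterion, estimate)
  avg <- (criterion + estimate) / 2
  d <- estimate - criterion
  graphics::plot(avg, d, xlab = "Mean of methods (min)",
                 ylab = "Estimate - criterion (min)", main = main,
                 pch = 19)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = ba$bias_ci, lty = 3)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}

#' Equivalence-zone plot
#'
#' Shows the proportional equivalence zone around the criterion mean and
#' the CI of each comparison mean.
#'
#' @param criterion per-participant criterion minutes.
#' @param estimates named list of per-participant estimate minutes.
#' @inheritParams equivalence_test
#' @param main plot title.
#' @export
plot_equivalence <- function(criterion, estimates, zone_fraction = 0.10,
                             conf = 0.90, main = "Equivalence") {
  zone <- equivalence_zone(mean(criterion), zone_fraction)
  k <- length(estimates)
  res <- lapply(estimates, function(e)
    equivalence_test(criterion, e, zone_fraction, conf))
  lo <- min(zone[1L], vapply(res, function(r) r$ci[1L], 0))
  hi <- max(zone[2L], vapply(res, function(r) r$ci[2L], 0))
  graphics::plot(NA, xlim = c(lo, hi), ylim = c(0.5, k + 0.5),
                 yaxt = "n", xlab = "Minutes", ylab = "", main = main)
  graphics::axis(2, at = seq_len(k), labels = names(estimates), las = 1)
  graphics::abline(v = zone, lty = 3)
  graphics::abline(v = mean(criterion), lty = 1)
  for (i in seq_len(k)) {
    graphics::segments(res[[i]]$ci[1L], i, res[[i]]$ci[2L], i, lwd = 2)
    graphics::points(res[[i]]$estimate_mean, i, pch = 19)
  }
  invisible(res)
}
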