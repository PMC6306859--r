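# Independent brute-force oracles used to pin down expected values.

# Epoch means by direct re-summation.
oracle_epoch_means <- function(sample_enmo, spe) {
  k <- length(sample_enmo) %/% spe
  vapply(seq_len(k), function(i) {
    mean(sample_enmo[((i - 1) * spe + 1):(i * spe)])
  }, numeric(1)) * 1000
}

# Per-code second totals of an event log, accumulated at 1 ms resolution.
oracle_code_totals_ms <- function(start, duration, code, res = 0.001) {
  t0 <- min(start)
  t1 <- max(start + duration)
  grid <- seq(t0 + res / 2, t1 - res / 2, by = res)
  idx <- findInterval(grid, start)
  cc <- code[idx]
  in_ev <- grid < (start + duration)[idx]
  tab <- vapply(0:2, function(k) sum(in_ev & cc == k) * res, numeric(1))
  names(tab) <- as.character(0:2)
  tab
}

# Exhaustive confusion-matrix ROC scan; positive iff enmo < threshold.
oracle_roc_scan <- function(enmo, label) {
  pos <- enmo[label == 1]
  neg <- enmo[label == 0]
  th <- c(sort(unique(enmo)), Inf)
  sens <- vapply(th, function(t) mean(pos < t), numeric(1))
  spec <- vapply(th, function(t) mean(neg >= t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec,
             youden_j = sens + spec - 1)
}

# Best Youden point by exhaustive scan, smallest threshold on ties.
oracle_youden <- function(enmo, label) {
  sc <- oracle_roc_scan(enmo, label)
  sc[which.max(sc$youden_j), ]
}

# AUC as the O(n^2) pairwise Mann-Whitney statistic (positives low).
oracle_auc_pairwise <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# Uniform random 3-D rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random posture event log with non-integer boundaries and occasional gaps.
random_event_log <- function(n_events = NULL, integer_bounds = FALSE) {
  if (is.null(n_events)) n_events <- sample(2:12, 1)
  dur <- if (integer_bounds) sample(1:8, n_events, replace = TRUE)
         else round(runif(n_events, 0.4, 8), 3)
  start0 <- round(runif(1, 0, 3), 3)
  start <- start0 + cumsum(c(0, dur[-n_events]))
  code <- sample(0:2, n_events, replace = TRUE)
  posture_events(as.POSIXct(start, tz = "UTC", origin = "1970-01-01"),
                 dur, code)
}
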