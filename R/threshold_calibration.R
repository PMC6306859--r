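# ROC-curve cut-point calibration: candidate thresholds, Youden-optimal
# operating points, trapezoidal/rank AUC with DeLong confidence intervals.
#
# Decision rule throughout: a second is classified positive (sedentary or
# stationary) iff its ENMO is strictly BELOW the threshold.

.split_classes <- function(data, enmo, label) {
  if (!missing(data) && !is.null(data)) {
    enmo <- data$enmo_mg
    label <- data$label
  }
  if (length(enmo) != length(label)) stop("enmo/label length mismatch")
  if (any(!label %in% c(0L, 1L))) stop("labels must be 0/1")
  pos <- enmo[label == 1L]
  neg <- enmo[label == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("degenerate input: both classes must be present")
  }
  list(pos = pos, neg = neg)
}

#' ROC curve over observed ENMO thresholds
#'
#' Candidate thresholds are every unique observed ENMO value plus +Inf.
#' At threshold t the rule "positive iff enmo < t" gives sensitivity
#' (TPR) non-decreasing and specificity (TNR) non-increasing in t.
#'
#' @param data a `labelled_dataset` (columns `enmo_mg`, `label`), or `NULL`
#'   when `enmo`/`label` are given directly.
#' @param enmo,label numeric ENMO values (mg) and 0/1 labels, used when
#'   `data` is `NULL`; label 1 is the behaviour being detected.
#' @return data.frame of class `roc_points` with columns `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`, ordered by threshold.
#' @export
roc_curve <- function(data = NULL, enmo = NULL, label = NULL) {
  cl <- .split_classes(data, enmo, label)
  uv <- sort(unique(c(cl$pos, cl$neg)))
  # counts strictly below each candidate threshold, computed exactly
  # (no floating-point epsilon): value uv[k] contributes to thresholds > uv[k]
  cnt <- function(x) {
    tab <- tabulate(findInterval(x, uv), nbins = length(uv))
    c(0, cumsum(tab)) # below uv[1], uv[2], ..., below +Inf
  }
  th <- c(uv, Inf)
  npos_lt <- cnt(cl$pos)
  nneg_lt <- cnt(cl$neg)
  sens <- npos_lt / length(cl$pos)
  spec <- (length(cl$neg) - nneg_lt) / length(cl$neg)
  structure(data.frame(threshold = th, sensitivity = sens,
                       specificity = spec,
                       youden_j = sens + spec - 1),
            class = c("roc_points", "data.frame"),
            n_positive = length(cl$pos), n_negative = length(cl$neg))
}

# DeLong midrank machinery, oriented so that a HIGHER score argues for the
# positive class. Returns AUC = P(X > Y) + 0.5 P(X = Y) and its asymptotic
# variance from the structural components.
.delong <- function(x_pos, y_neg) {
  m <- length(x_pos)
  n <- length(y_neg)
  tz <- rank(c(x_pos, y_neg), ties.method = "average")
  tx <- rank(x_pos, ties.method = "average")
  ty <- rank(y_neg, ties.method = "average")
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  list(auc = auc, var = s10 / m + s01 / n)
}

#' AUC with DeLong 95% confidence interval
#'
#' The area under the ROC of [roc_curve()] by trapezoidal integration is
#' numerically identical to the Mann-Whitney rank statistic
#' P(enmo_pos < enmo_neg) + 0.5 P(tie); it is computed in that rank form,
#' with the asymptotic DeLong variance for the confidence interval.
#'
#' @inheritParams roc_curve
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (length-2), `n_positive`,
#'   `n_negative`.
#' @export
roc_auc <- function(data = NULL, enmo = NULL, label = NULL, conf = 0.95) {
  cl <- .split_classes(data, enmo, label)
  # positives are LOW-ENMO: score orientation flips sign
  d <- .delong(-cl$pos, -cl$neg)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(max(d$var, 0))
  list(auc = d$auc, se = sqrt(max(d$var, 0)),
       ci = c(max(0, d$auc - half), min(1, d$auc + half)),
       conf = conf,
       n_positive = length(cl$pos), n_negative = length(cl$neg))
}

#' Youden-optimal operating point
#'
#' Returns the ROC point maximizing J = sensitivity + specificity - 1;
#' ties are broken by the smallest threshold (the least behaviour-time
#' claimed).
#'
#' @param points a `roc_points` frame from [roc_curve()].
#' @return one-row data.frame with `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
select_youden <- function(points) {
  stopifnot(inherits(points, "roc_points"), nrow(points) >= 1L)
  o <- order(points$threshold)
  points <- points[o, , drop = FALSE]
  points[which.max(points$youden_j), , drop = FALSE]
}

#' Calibrate cut points for a cohort
#'
#' Pools labelled seconds across participants and derives one Youden
#' threshold per device (brand x placement) x coding scheme. Groups in
#' which only one class is present are recorded as failed rows and the run
#' continues.
#'
#' @param data data.frame with columns `brand`, `placement`, `scheme`,
#'   `enmo_mg`, `label` (pooled seconds across participants).
#' @return data.frame of class `threshold_table`, one row per group:
#'   device metadata, `threshold_mg`, `sensitivity`, `specificity`, `auc`,
#'   `auc_lo`, `auc_hi`, `n_positive`, `n_negative`, `status`.
#' @export
calibrate_cohort <- function(data) {
  need <- c("brand", "placement", "scheme", "enmo_mg", "label")
  if (!all(need %in% names(data))) {
    stop(sprintf("expected columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(data) == 0L) {
    out <- data.frame(brand = character(0), placement = character(0),
                      scheme = character(0), threshold_mg = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      auc = numeric(0), auc_lo = numeric(0),
                      auc_hi = numeric(0), n_positive = integer(0),
                      n_negative = integer(0), status = character(0))
    return(structure(out, class = c("threshold_table", "data.frame")))
  }
  key <- interaction(data$brand, data$placement, data$scheme, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(data)), key), function(ix) {
    g <- data[ix, ]
    base <- data.frame(brand = g$brand[1L], placement = g$placement[1L],
                       scheme = g$scheme[1L], stringsAsFactors = FALSE)
    res <- try({
      roc <- roc_curve(enmo = g$enmo_mg, label = g$label)
      best <- select_youden(roc)
      a <- roc_auc(enmo = g$enmo_mg, label = g$label)
      cbind(base,
            data.frame(threshold_mg = best$threshold,
                       sensitivity = best$sensitivity,
                       specificity = best$specificity,
                       auc = a$auc, auc_lo = a$ci[1L], auc_hi = a$ci[2L],
                       n_positive = a$n_positive,
                       n_negative = a$n_negative, status = "ok"))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      cbind(base,
            data.frame(threshold_mg = NA_real_, sensitivity = NA_real_,
                       specificity = NA_real_, auc = NA_real_,
                       auc_lo = NA_real_, auc_hi = NA_real_,
                       n_positive = sum(g$label == 1L),
                       n_negative = sum(g$label == 0L),
                       status = "degenerate"))
    } else res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("threshold_table", "data.frame"))
}

#' Write a threshold table shaped like a published cut-point table
#'
#' Thresholds are reported to 0.1 mg; sensitivity/specificity as
#' percentages.
#'
#' @param tbl a `threshold_table` from [calibrate_cohort()].
#' @param path output CSV (or `.json`).
#' @export
write_thresholds <- function(tbl, path) {
  stopifnot(inherits(tbl, "threshold_table"))
  out <- data.frame(
    brand = tbl$brand, placement = tbl$placement, scheme = tbl$scheme,
    sensitivity_pct = round(100 * tbl$sensitivity),
    specificity_pct = round(100 * tbl$specificity),
    auc = round(tbl$auc, 3),
    auc_ci = sprintf("%.3f-%.3f", tbl$auc_lo, tbl$auc_hi),
    threshold_mg = round(tbl$threshold_mg, 1))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
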