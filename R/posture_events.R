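# Posture event expansion, binary coding schemes, and synchronization with
# epoch ENMO.

#' Expand a posture event log to second-by-second codes
#'
#' Every whole wall-clock second fully covered by the log receives exactly
#' one posture code. When a posture transition falls inside a second (a
#' "duplicate second", two or more postures sharing one second), the second
#' receives the posture transitioned *into*; with three or more postures in
#' one second the last-entered posture wins. The number of duplicate
#' seconds is reported as attribute `duplicate_seconds`.
#'
#' Seconds inside a gap between events (if any) are dropped with a warning.
#'
#' @param log a [posture_events] log.
#' @return data.frame of class `posture_seconds` with columns `second`
#'   (POSIXct, integer-second grid) and `code`; attribute
#'   `duplicate_seconds` counts transition seconds.
#' @export
expand_to_seconds <- function(log) {
  stopifnot(inherits(log, "posture_events"))
  if (any(log$duration <= 0)) stop("event durations must be positive")
  if (nrow(log) == 0L) {
    out <- data.frame(second = as.POSIXct(numeric(0), tz = "UTC",
                                          origin = "1970-01-01"),
                      code = integer(0))
    return(structure(out, class = c("posture_seconds", "data.frame"),
                     duplicate_seconds = 0L))
  }
  eps <- 1e-6
  s <- .as_seconds(log$start)
  e <- s + log$duration
  first <- floor(s[1L] + eps)
  last_full <- floor(e[length(e)] + eps) # exclusive end of last whole second
  if (last_full <= first) {
    stop("event log spans less than one whole second")
  }
  sec <- seq(first, last_full - 1)
  # event active at the end of each second = the posture transitioned into
  idx_last <- findInterval(sec + 1 - eps, s)        # last event starting before sec+1
  # first event with positive overlap: first i with e_i > sec
  idx_first <- findInterval(sec + eps, e) + 1L
  in_gap <- idx_first > idx_last
  if (any(in_gap)) {
    warning(sprintf("dropping %d second(s) not covered by any event",
                    sum(in_gap)), call. = FALSE)
  }
  dup <- !in_gap & (idx_last - idx_first >= 1L)
  out <- data.frame(
    second = as.POSIXct(sec[!in_gap], tz = "UTC", origin = "1970-01-01"),
    code = log$code[idx_last[!in_gap]])
  structure(out, class = c("posture_seconds", "data.frame"),
            duplicate_seconds = sum(dup))
}

#' Binary label coding schemes
#'
#' Maps second-level posture codes to binary labels where 1 marks the
#' behaviour being detected: under the `"sedentary"` scheme sit/lie (code 0)
#' is positive; under the `"stationary"` scheme sit/lie and stand
#' (codes 0 and 1) are positive.
#'
#' @param series a `posture_seconds` data.frame (or integer codes).
#' @param scheme `"sedentary"` or `"stationary"`.
#' @return integer vector of 0/1 labels.
#' @export
code_scheme <- function(series, scheme = c("sedentary", "stationary")) {
  scheme <- match.arg(scheme)
  code <- if (is.data.frame(series)) series$code else as.integer(series)
  if (any(!code %in% 0:2)) stop("unknown posture code")
  if (scheme == "sedentary") as.integer(code == 0L)
  else as.integer(code <= 1L)
}

#' Synchronize epoch ENMO with second-level labels
#'
#' Inner join on the integer second. Records present on one side only are
#' dropped and counted in attributes `dropped_epochs` / `dropped_labels`.
#'
#' @param epochs an [epoch_series] at 1 s epochs.
#' @param labels a `posture_seconds` data.frame with an added `label`
#'   column, or the result of [code_scheme()] aligned with a
#'   `posture_seconds` frame passed via `seconds`.
#' @param seconds optional `posture_seconds` frame when `labels` is a bare
#'   0/1 vector.
#' @param scheme coding scheme tag carried on the result.
#' @return data.frame of class `labelled_dataset` with columns `time`,
#'   `enmo_mg`, `label`.
#' @export
synchronize <- function(epochs, labels, seconds = NULL,
                        scheme = NA_character_) {
  stopifnot(inherits(epochs, "epoch_series"))
  if (is.data.frame(labels)) {
    if (!"label" %in% names(labels)) stop("labels frame needs a 'label' column")
    lab_sec <- floor(.as_seconds(labels$second) + 1e-6)
    lab <- as.integer(labels$label)
  } else {
    if (is.null(seconds)) stop("bare labels need the matching 'seconds' frame")
    lab_sec <- floor(.as_seconds(seconds$second) + 1e-6)
    lab <- as.integer(labels)
    if (length(lab) != length(lab_sec)) stop("labels/seconds length mismatch")
  }
  if (any(duplicated(lab_sec))) stop("duplicate seconds in labels")
  ep_sec <- floor(.as_seconds(epochs$time) + 1e-6)
  if (any(duplicated(ep_sec))) stop("duplicate seconds in epochs")
  m <- match(ep_sec, lab_sec)
  keep <- !is.na(m)
  if (!any(keep)) stop("no overlapping seconds between epochs and labels")
  out <- data.frame(time = epochs$time[keep],
                    enmo_mg = epochs$enmo_mg[keep],
                    label = lab[m[keep]])
  structure(out, class = c("labelled_dataset", "data.frame"),
            scheme = scheme,
            brand = attr(epochs, "brand"),
            placement = attr(epochs, "placement"),
            device_id = attr(epochs, "device_id"),
            dropped_epochs = sum(!keep),
            dropped_labels = length(lab_sec) - sum(keep))
}
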