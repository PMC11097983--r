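#' Derive an extraction threshold from a baseline window
#'
#' The multi-unit extraction threshold is set from the spontaneous baseline
#' of each recording: mean minus (negative polarity) or plus (positive) `k`
#' baseline standard deviations; for absolute polarity the threshold is
#' `mean(|x|) + k sd(|x|)` applied to the rectified trace.
#'
#' @param trace a [simulate_raw_trace()] object.
#' @param baseline_window `c(start_s, end_s)` within the trace used to
#'   estimate the noise statistics.
#' @param k SD multiplier (conventional extracellular practice uses 3-5; the
#'   default is 4).
#' @param polarity `"negative"` (default for extracellular spikes, whose
#'   dominant deflection is negative), `"positive"`, or `"absolute"`.
#' @return Scalar threshold in trace units (signed for the signed
#'   polarities).
#' @export
derive_threshold <- function(trace, baseline_window, k = 4,
                             polarity = c("negative", "positive", "absolute")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(trace, "voltage_trace"))
  sr <- trace$sampling_rate_hz
  i0 <- max(1L, floor(baseline_window[1] * sr) + 1L)
  i1 <- min(length(trace$samples), ceiling(baseline_window[2] * sr))
  if (i1 < i0) stop("invalid window: empty baseline window")
  x <- trace$samples[i0:i1]
  if (polarity == "absolute") x <- abs(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (is.na(s)) s <- 0
  switch(polarity,
         negative = m - k * s,
         positive = m + k * s,
         absolute = m + k * s)
}

#' Extract multi-unit spike times by threshold crossing
#'
#' Emits one spike at each threshold-crossing sample (the first sample beyond
#' the threshold in the configured polarity); subsequent crossings within
#' `dead_time_s` of an accepted spike are suppressed.
#'
#' @param trace a [simulate_raw_trace()] object.
#' @param threshold signed threshold (a.u.), e.g. from [derive_threshold()].
#' @param polarity crossing direction: `"negative"` accepts samples below
#'   the threshold, `"positive"` above, `"absolute"` `|x|` above
#'   `|threshold|`.
#' @param dead_time_s refractory suppression after each accepted spike
#'   (>= 0; default 0.5 ms).
#' @param diff_filter apply a first-order difference before thresholding, as
#'   a crude stand-in for high-pass filtering (off by default; recordings
#'   are assumed already high-pass filtered).
#' @return Sorted numeric vector of spike times (s).
#' @export
detect_spikes <- function(trace, threshold,
                          polarity = c("negative", "positive", "absolute"),
                          dead_time_s = 0.0005, diff_filter = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(trace, "voltage_trace"), dead_time_s >= 0)
  x <- trace$samples
  if (diff_filter) x <- c(0, diff(x))
  beyond <- switch(polarity,
                   negative = x < threshold,
                   positive = x > threshold,
                   absolute = abs(x) > abs(threshold))
  ## crossing = first sample of each run beyond threshold
  cross <- which(beyond & !c(FALSE, beyond[-length(beyond)]))
  if (!length(cross)) return(numeric(0))
  times <- (cross - 1) / trace$sampling_rate_hz
  if (dead_time_s > 0 && length(times) > 1) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      if (times[i] - last < dead_time_s) keep[i] <- FALSE else last <- times[i]
    }
    times <- times[keep]
  }
  times
}
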