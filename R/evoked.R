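## Indices of pre-stimulus baseline bins and of response-window bins.
baseline_bin_idx <- function(psth, baseline_ms = c(-500, 0)) {
  idx <- which(psth$bin_starts_ms >= baseline_ms[1] - 1e-9 &
               psth$bin_starts_ms < baseline_ms[2] - 1e-9)
  if (!length(idx))
    stop("configuration error: PSTH window does not cover the baseline window")
  idx
}

response_bin_idx <- function(psth, response_ms = c(0, 50)) {
  which(psth$bin_starts_ms >= response_ms[1] - 1e-9 &
        psth$bin_starts_ms < response_ms[2] - 1e-9)
}

## Population SD (divisor n): the threshold is a property of the observed
## baseline bins, not an estimate for unseen ones.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Baseline firing threshold for evoked-response detection
#'
#' Computes, over the 500 ms of pre-stimulus spontaneous activity of a block
#' PSTH, the mean and (population) standard deviation of the per-bin counts,
#' and the detection threshold mean + `k` SD.  With 1 ms bins the baseline
#' comprises 500 bins.
#'
#' @param psth a block [build_psth()] whose window covers the baseline.
#' @param k SD multiplier (3 is the standard used throughout).
#' @param baseline_ms baseline window `c(start_ms, end_ms)`, default
#'   \[-500, 0).
#' @return List `baseline_mean`, `baseline_sd`, `threshold` (all in
#'   counts/bin).
#' @examples
#' p <- build_psth(numeric(0), 0)          # empty train
#' baseline_threshold(p)$threshold         # 0
#' @export
baseline_threshold <- function(psth, k = 3, baseline_ms = c(-500, 0)) {
  stopifnot(inherits(psth, "psth"))
  x <- psth$counts[baseline_bin_idx(psth, baseline_ms)]
  m <- mean(x)
  s <- pop_sd(x)
  list(baseline_mean = m, baseline_sd = s, threshold = m + k * s)
}

#' Detect the cortically-evoked response in a block PSTH
#'
#' The response peak is the maximum-count bin within the 50 ms following
#' stimulation (ties broken toward the earliest bin).  If no bin in that
#' window strictly exceeds the threshold, no response is returned.
#' Otherwise the onset is the earliest bin of the contiguous suprathreshold
#' run containing the peak, and the offset the last bin of that run (the
#' first bins to exceed, respectively fall back below, threshold around the
#' peak).  The run is confined to the response window.
#'
#' @param psth a block [build_psth()].
#' @param thr result of [baseline_threshold()] (or a compatible list).
#' @param response_ms response window, default \[0, 50) ms.
#' @return `NULL` when no bin exceeds threshold; otherwise an
#'   `"evoked_response"` object with `peak_latency_ms`, `onset_ms`,
#'   `offset_ms`, `magnitude` (see [response_magnitude()]), `baseline_mean`,
#'   `baseline_sd`, `threshold`.
#' @export
detect_response <- function(psth, thr = baseline_threshold(psth),
                            response_ms = c(0, 50)) {
  stopifnot(inherits(psth, "psth"))
  ridx <- response_bin_idx(psth, response_ms)
  if (!length(ridx)) stop("configuration error: PSTH window misses the response window")
  cts <- psth$counts[ridx]
  if (!any(cts > thr$threshold)) return(NULL)
  peak <- which.max(cts)           # earliest max by which.max contract
  above <- cts > thr$threshold
  on <- peak
  while (on > 1 && above[on - 1]) on <- on - 1
  off <- peak
  while (off < length(cts) && above[off + 1]) off <- off + 1
  res <- structure(list(
    peak_latency_ms = psth$bin_starts_ms[ridx[peak]],
    onset_ms = psth$bin_starts_ms[ridx[on]],
    offset_ms = psth$bin_starts_ms[ridx[off]],
    magnitude = NA_real_,
    baseline_mean = thr$baseline_mean,
    baseline_sd = thr$baseline_sd,
    threshold = thr$threshold), class = "evoked_response")
  res$magnitude <- response_magnitude(psth, res)
  res
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("Evoked response: peak %g ms, onset %g ms, offset %g ms\n",
              x$peak_latency_ms, x$onset_ms, x$offset_ms))
  cat(sprintf("  magnitude %.2f counts above baseline (threshold %.2f/bin)\n",
              x$magnitude, x$threshold))
  invisible(x)
}

#' Evoked-response magnitude
#'
#' Number of spike counts during the evoked response (onset through offset
#' bins) minus the mean baseline count expected over the same number of
#' bins.
#'
#' @param psth the block [build_psth()] the response was detected in.
#' @param response an [detect_response()] result (not `NULL`).
#' @return Magnitude in spike counts above baseline.
#' @export
response_magnitude <- function(psth, response) {
  if (is.null(response)) stop("response is NULL")
  idx <- which(psth$bin_starts_ms >= response$onset_ms - 1e-9 &
               psth$bin_starts_ms <= response$offset_ms + 1e-9)
  sum(psth$counts[idx]) - response$baseline_mean * length(idx)
}

#' Normalize a per-block magnitude series to its pre-disinhibition baseline
#'
#' Each subject's block magnitudes are expressed relative to the mean
#' magnitude of the blocks recorded before the bicuculline injection.  The
#' default convention is percent-of-baseline (100 = no change); percent
#' change (0 = no change) is also available.
#'
#' @param magnitudes numeric vector of per-block magnitudes.
#' @param baseline_blocks indices of the pre-disinhibition blocks.
#' @param convention `"percent_of_baseline"` (default) or
#'   `"percent_change"`.
#' @return Numeric vector of normalized values, one per block, with
#'   attribute `baseline_blocks`.
#' @examples
#' normalize_series(c(10, 10, 10, 15), 1:3)   # 100 100 100 150
#' @export
normalize_series <- function(magnitudes, baseline_blocks,
                             convention = c("percent_of_baseline", "percent_change")) {
  convention <- match.arg(convention)
  stopifnot(all(baseline_blocks >= 1), all(baseline_blocks <= length(magnitudes)))
  base <- mean(magnitudes[baseline_blocks])
  if (!is.finite(base) || base == 0)
    stop("undefined normalization: baseline mean is zero")
  out <- 100 * magnitudes / base
  if (convention == "percent_change") out <- out - 100
  attr(out, "baseline_blocks") <- baseline_blocks
  out
}

#' Block-wise evoked-response analysis (single-electrode designs)
#'
#' Runs the Experiment-1/2 analysis over every channel and block: a
#' mean + `k` SD threshold from the 500 ms pre-stimulus baseline of each
#' block PSTH, peak/onset/offset detection within 50 ms of stimulation,
#' response magnitude, and per-channel normalization to the
#' pre-disinhibition blocks.  Blocks with no detectable response contribute
#' magnitude 0 to the normalized series.
#'
#' @param dataset a [simulate_experiment()] dataset or named list of spike
#'   trains.
#' @param schedule event schedule (taken from the dataset when omitted).
#' @param baseline_blocks block indices before the bicuculline injection;
#'   defaults to all blocks before the gated epoch of the schedule.
#' @param window,bin_width_ms PSTH parameters (see [build_psth()]).
#' @param sd_mult detection-threshold SD multiplier.
#' @param response_ms response window (ms).
#' @param convention normalization convention (see [normalize_series()]).
#' @return Object of class `"evoked_series"`: `table` (data frame: channel,
#'   block, onset_ms, offset_ms, peak_ms, magnitude, normalized_pct),
#'   `baseline_blocks`, `params`.
#' @export
analyze_evoked <- function(dataset, schedule = NULL, baseline_blocks = NULL,
                           window = c(-500, 100), bin_width_ms = 1,
                           sd_mult = 3, response_ms = c(0, 50),
                           convention = "percent_of_baseline") {
  if (inherits(dataset, "striatpot_dataset") && is.null(schedule))
    schedule <- dataset$schedule
  set <- block_psths(dataset, schedule, window, bin_width_ms)
  if (is.null(baseline_blocks)) {
    ob <- gated_onset_block(schedule)
    baseline_blocks <- if (is.na(ob)) seq_len(set$n_blocks) else seq_len(ob - 1)
  }
  rows <- list()
  for (ch in seq_along(set$channels)) {
    mags <- numeric(set$n_blocks)
    det <- vector("list", set$n_blocks)
    for (b in seq_len(set$n_blocks)) {
      p <- get_psth(set, ch, b)
      thr <- baseline_threshold(p, k = sd_mult)
      r <- detect_response(p, thr, response_ms)
      det[b] <- list(r)
      mags[b] <- if (is.null(r)) 0 else r$magnitude
    }
    ## channels with no measurable baseline response cannot be normalized
    norm <- if (mean(mags[baseline_blocks]) == 0) rep(NA_real_, set$n_blocks)
            else normalize_series(mags, baseline_blocks, convention)
    rows[[ch]] <- data.frame(
      channel = set$channels[ch],
      block = seq_len(set$n_blocks),
      onset_ms = vapply(det, function(r) if (is.null(r)) NA_real_ else r$onset_ms, 0),
      offset_ms = vapply(det, function(r) if (is.null(r)) NA_real_ else r$offset_ms, 0),
      peak_ms = vapply(det, function(r) if (is.null(r)) NA_real_ else r$peak_latency_ms, 0),
      magnitude = mags,
      normalized_pct = as.numeric(norm),
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows),
                 baseline_blocks = baseline_blocks,
                 params = list(window = window, bin_width_ms = bin_width_ms,
                               sd_mult = sd_mult, response_ms = response_ms,
                               convention = convention)),
            class = "evoked_series")
}

#' @export
print.evoked_series <- function(x, ...) {
  if (is.null(x$table)) {
    cat("Evoked-response series: no channels\n")
    return(invisible(x))
  }
  nch <- length(unique(x$table$channel))
  cat(sprintf("Evoked-response series: %d channel(s) x %d blocks\n",
              nch, max(x$table$block)))
  cat(sprintf("  baseline blocks: %s\n",
              paste(range(x$baseline_blocks), collapse = "-")))
  post <- x$table$block > max(x$baseline_blocks)
  if (any(post))
    cat(sprintf("  mean normalized level after baseline: %.1f%%\n",
                mean(x$table$normalized_pct[post])))
  invisible(x)
}

#' @export
summary.evoked_series <- function(object, ...) {
  agg <- stats::aggregate(normalized_pct ~ block, object$table, mean)
  names(agg)[2] <- "mean_normalized_pct"
  agg
}

#' @export
plot.evoked_series <- function(x, ...) {
  agg <- summary(x)
  graphics::plot(agg$block, agg$mean_normalized_pct, type = "b",
                 xlab = "block", ylab = "response (% of baseline)", ...)
  graphics::abline(h = 100, lty = 2)
  graphics::abline(v = max(x$baseline_blocks) + 0.5, col = "blue", lty = 3)
  invisible(x)
}
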