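#' Peri-stimulus time histogram
#'
#' Bins spike times relative to each stimulation onset into half-open
#' `[lo, hi)` bins and sums counts over all stimulations.  `counts[b]` is
#' the number of (spike, stimulation) pairs whose latency falls in bin `b`;
#' bins are 0-based in time, with `bin_starts_ms` giving each bin's left
#' edge.
#'
#' @param spikes sorted numeric vector of spike times (s).
#' @param stim_times sorted numeric vector of stimulation times (s).
#' @param window `c(start_ms, end_ms)` relative to stimulation onset;
#'   `bin_width_ms` must divide its length.  The default \[-500, 100) keeps
#'   500 ms of pre-stimulus spontaneous activity for baseline estimation and
#'   headroom past the 50 ms response window.
#' @param bin_width_ms bin width in ms (1 ms is the analysis standard here).
#' @param channel_id,block_index optional labels carried on the object.
#' @return Object of class `"psth"`: list with `counts`, `bin_starts_ms`,
#'   `bin_width_ms`, `window_ms`, `n_stims`, `channel_id`, `block_index`.
#' @examples
#' p <- build_psth(c(0.010, 1.012), c(0, 1), window = c(0, 50))
#' which(p$counts > 0)   # bins 10 and 12 (1-based: 11, 13)
#' @export
build_psth <- function(spikes, stim_times, window = c(-500, 100),
                       bin_width_ms = 1, channel_id = NA, block_index = NA) {
  n_bins <- (window[2] - window[1]) / bin_width_ms
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("configuration error: 'bin_width_ms' must divide the window length")
  n_bins <- as.integer(round(n_bins))
  if (is.unsorted(stim_times)) stop("'stim_times' must be sorted")
  spikes <- sort(spikes)
  counts <- psth_counts(spikes, stim_times, rep(1L, length(stim_times)),
                        1L, window, bin_width_ms, n_bins)[, 1]
  structure(list(counts = as.integer(counts),
                 bin_starts_ms = window[1] + bin_width_ms * (seq_len(n_bins) - 1),
                 bin_width_ms = bin_width_ms,
                 window_ms = window,
                 n_stims = length(stim_times),
                 channel_id = channel_id,
                 block_index = block_index),
            class = "psth")
}

## Vectorised alignment core: counts matrix (n_bins x n_groups) of spike
## latencies relative to each stimulation, stimulations grouped by `group`
## (e.g. block index).  Half-open bins [lo, hi); a small latency guard
## (1e-6 ms) absorbs floating-point error at bin edges.
psth_counts <- function(spikes, stim_times, group, n_groups, window,
                        bin_width_ms, n_bins) {
  out <- matrix(0L, nrow = n_bins, ncol = n_groups)
  if (!length(spikes) || !length(stim_times)) return(out)
  lo_s <- window[1] / 1000
  hi_s <- window[2] / 1000
  i_lo <- findInterval(stim_times + lo_s, spikes, left.open = TRUE)
  i_hi <- findInterval(stim_times + hi_s, spikes, left.open = TRUE)
  counts_per_stim <- i_hi - i_lo
  tot <- sum(counts_per_stim)
  if (!tot) return(out)
  spike_idx <- sequence(counts_per_stim, from = i_lo + 1L)
  stim_rep <- rep(seq_along(stim_times), counts_per_stim)
  offset_ms <- (spikes[spike_idx] - stim_times[stim_rep]) * 1000
  bin <- floor((offset_ms - window[1]) / bin_width_ms + 1e-6)
  ok <- bin >= 0 & bin < n_bins
  idx <- bin[ok] + n_bins * (group[stim_rep[ok]] - 1L) + 1L
  tab <- tabulate(idx, nbins = n_bins * n_groups)
  out[] <- tab
  out
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms on [%g, %g) ms, %d stimulations\n",
              length(x$counts), x$bin_width_ms, x$window_ms[1], x$window_ms[2],
              x$n_stims))
  if (!is.na(x$channel_id) || !is.na(x$block_index))
    cat(sprintf("  channel %s, block %s\n", x$channel_id, x$block_index))
  cat(sprintf("  total count %d, max %d\n", sum(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  graphics::plot(x$bin_starts_ms, x$counts, type = "h",
                 xlab = "time from stimulation (ms)",
                 ylab = sprintf("spikes / %g ms bin", x$bin_width_ms), ...)
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(x)
}

#' Per-block, per-channel PSTHs
#'
#' Builds one PSTH per channel and block of the schedule, the unit of all
#' downstream analysis (each block covers 120 stimulations under the default
#' protocols).
#'
#' @param dataset a [simulate_experiment()] dataset, or a named list of
#'   spike-time vectors.
#' @param schedule an [generate_stim_times()] event schedule (taken from the
#'   dataset when omitted).
#' @inheritParams build_psth
#' @return Object of class `"psth_set"`: `counts` array of dimension
#'   (bins, blocks, channels), `bin_starts_ms`, `bin_width_ms`, `window_ms`,
#'   `n_stims` per block, `channels`, `n_blocks`.
#' @export
block_psths <- function(dataset, schedule = NULL, window = c(-500, 100),
                        bin_width_ms = 1) {
  if (inherits(dataset, "striatpot_dataset")) {
    if (is.null(schedule)) schedule <- dataset$schedule
    spikes <- dataset$spikes
  } else spikes <- dataset
  stopifnot(inherits(schedule, "event_schedule"))
  n_bins <- (window[2] - window[1]) / bin_width_ms
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("configuration error: 'bin_width_ms' must divide the window length")
  n_bins <- as.integer(round(n_bins))
  ids <- names(spikes)
  if (is.null(ids)) ids <- sprintf("ch%02d", seq_along(spikes))
  arr <- array(0L, dim = c(n_bins, schedule$n_blocks, length(spikes)),
               dimnames = list(NULL, NULL, ids))
  for (i in seq_along(spikes)) {
    sp <- spikes[[i]]
    if (any(sp < 0 | sp > schedule$duration_s)) {
      warning("spikes outside the recording ignored (channel ", ids[i], ")")
      sp <- sp[sp >= 0 & sp <= schedule$duration_s]
    }
    arr[, , i] <- psth_counts(sort(sp), schedule$stim_times, schedule$block,
                              schedule$n_blocks, window, bin_width_ms, n_bins)
  }
  structure(list(counts = arr,
                 bin_starts_ms = window[1] + bin_width_ms * (seq_len(n_bins) - 1),
                 bin_width_ms = bin_width_ms,
                 window_ms = window,
                 n_stims = schedule$block_size,
                 channels = ids,
                 n_blocks = schedule$n_blocks),
            class = "psth_set")
}

#' @export
print.psth_set <- function(x, ...) {
  cat(sprintf("PSTH set: %d channels x %d blocks, %d bins of %g ms on [%g, %g) ms\n",
              length(x$channels), x$n_blocks, length(x$bin_starts_ms),
              x$bin_width_ms, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Extract a single block PSTH from a set
#'
#' @param set a [block_psths()] result.
#' @param channel channel id (name) or index.
#' @param block 1-based block index.
#' @return A `"psth"` object.
#' @export
get_psth <- function(set, channel, block) {
  stopifnot(inherits(set, "psth_set"))
  ch <- if (is.character(channel)) match(channel, set$channels) else channel
  if (is.na(ch) || ch < 1 || ch > length(set$channels)) stop("unknown channel")
  if (block < 1 || block > set$n_blocks) stop("unknown block")
  structure(list(counts = set$counts[, block, ch],
                 bin_starts_ms = set$bin_starts_ms,
                 bin_width_ms = set$bin_width_ms,
                 window_ms = set$window_ms,
                 n_stims = set$n_stims,
                 channel_id = set$channels[ch],
                 block_index = block),
            class = "psth")
}
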