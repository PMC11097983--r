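#' Subtract a PSTH's own spontaneous firing
#'
#' Subtracts from every bin the mean per-bin count of the 500 ms of
#' spontaneous activity preceding the stimulation, yielding the block's
#' baseline-corrected response profile (values may be negative).
#'
#' @param psth a block [build_psth()] whose window covers the baseline.
#' @param baseline_ms baseline window, default \[-500, 0) ms.
#' @return Numeric vector of adjusted per-bin values, with attributes
#'   `bin_starts_ms` and `spontaneous_mean`.
#' @export
subtract_spontaneous <- function(psth, baseline_ms = c(-500, 0)) {
  stopifnot(inherits(psth, "psth"))
  m <- mean(psth$counts[baseline_bin_idx(psth, baseline_ms)])
  out <- psth$counts - m
  attr(out, "bin_starts_ms") <- psth$bin_starts_ms
  attr(out, "spontaneous_mean") <- m
  out
}

#' Average baseline response profile
#'
#' Per-bin mean and (population) SD of the baseline-corrected responses over
#' the blocks preceding the bicuculline injection — in the multichannel
#' design, the 8 blocks comprising 4 post-drug blocks and 4 post-drug blocks
#' with light pairing.
#'
#' Because the per-bin SD is estimated from few blocks it occasionally comes
#' out near zero, which would turn ordinary counting noise into spurious
#' "peaks" at that bin in every subsequent block.  The profile therefore
#' also carries a Poisson counting-noise floor per bin — the square root of
#' the bin's mean raw count (baseline-corrected mean plus the mean
#' spontaneous level), the smallest dispersion a Poisson spike count can
#' have — which [detect_peaks()] applies by default.
#'
#' @param adjusted list of [subtract_spontaneous()] vectors, one per
#'   baseline block, sharing binning.
#' @param expected_blocks expected number of baseline blocks (checked;
#'   set `NULL` to override).
#' @return Object of class `"baseline_profile"`: `mean`, `sd` and
#'   `sd_floor` per bin, `spontaneous_mean`, `bin_starts_ms`, `n_blocks`.
#' @export
baseline_profile <- function(adjusted, expected_blocks = 8) {
  if (!is.null(expected_blocks) && length(adjusted) != expected_blocks)
    stop(sprintf("configuration error: expected %d baseline blocks, got %d (pass expected_blocks = NULL to override)",
                 expected_blocks, length(adjusted)))
  m <- do.call(cbind, adjusted)
  spont <- mean(vapply(adjusted, function(a) {
    s <- attr(a, "spontaneous_mean")
    if (is.null(s)) 0 else s
  }, 0))
  mu <- rowMeans(m)
  structure(list(mean = mu,
                 sd = apply(m, 1, pop_sd),
                 sd_floor = sqrt(pmax(0, mu + spont)),
                 spontaneous_mean = spont,
                 bin_starts_ms = attr(adjusted[[1]], "bin_starts_ms"),
                 n_blocks = length(adjusted)),
            class = "baseline_profile")
}

#' Detect potentiation peaks in one block
#'
#' A potentiation peak occurs at every post-stimulus bin whose
#' baseline-corrected value strictly exceeds the average baseline response
#' at that bin plus `k` times its per-bin SD; the peak's excess is the
#' difference between the block value and the baseline mean at that bin.
#'
#' The per-bin SD is floored at the profile's Poisson counting-noise level
#' by default (see [baseline_profile()]); set `sd_floor = FALSE` for the
#' raw across-block SD.
#'
#' @param adjusted a [subtract_spontaneous()] vector for the block.
#' @param profile a [baseline_profile()] sharing the binning.
#' @param k per-bin SD multiplier (2 is the standard here).
#' @param response_ms detection window, default \[0, 50) ms.
#' @param sd_floor apply the profile's Poisson dispersion floor.
#' @return Data frame with one row per peak: `latency_ms`, `excess`.
#' @export
detect_peaks <- function(adjusted, profile, k = 2, response_ms = c(0, 50),
                         sd_floor = TRUE) {
  stopifnot(inherits(profile, "baseline_profile"))
  bins <- attr(adjusted, "bin_starts_ms")
  if (length(bins) != length(profile$bin_starts_ms) ||
      any(abs(bins - profile$bin_starts_ms) > 1e-9))
    stop("block and profile binning differ")
  s <- if (sd_floor) pmax(profile$sd, profile$sd_floor) else profile$sd
  in_win <- bins >= response_ms[1] - 1e-9 & bins < response_ms[2] - 1e-9
  hit <- in_win & (as.numeric(adjusted) > profile$mean + k * s)
  data.frame(latency_ms = bins[hit],
             excess = as.numeric(adjusted)[hit] - profile$mean[hit])
}

#' Classify one channel as potentiated or not
#'
#' A channel is potentiated if some latency shows potentiation peaks (within
#' `latency_tolerance_ms`) in at least `run_length` strictly consecutive
#' post-disinhibition blocks, with such peaks absent at a similar latency
#' during the pre-drug veto period.  The recorded criterion distinguishes
#' runs of 5-6 blocks (`run5`) from runs of 7 or more (`run7`).  The
#' potentiated response's latency is its earliest bin, its duration the
#' number of distinct bins showing peaks across the supporting blocks, and
#' its total magnitude the summed excess of all supporting peaks.
#'
#' "Absent during the pre-drug period" is interpreted through the method's
#' own persistence logic: isolated single-block exceedances of the 2-SD
#' rule are expected noise, so the veto fires only when similar-latency
#' peaks recur in at least `veto_min_blocks` distinct pre-drug blocks
#' (default 2).  Set `veto_min_blocks = 1` for the literal any-peak veto.
#'
#' When several latencies qualify, the call is made at the one with the
#' longest supporting run, ties broken by the largest total excess.
#'
#' @param peaks_by_block list indexed by block of [detect_peaks()] frames
#'   (every block, pre- and post-disinhibition).
#' @param bicuculline_block first post-disinhibition block.
#' @param pre_drug_blocks veto blocks (default 1-4; extend to all
#'   pre-disinhibition blocks for a stricter veto).
#' @param latency_tolerance_ms peaks within this tolerance of a candidate
#'   latency count as "similar" (default 2 ms).
#' @param run_length minimum number of consecutive supporting blocks
#'   (default 5).
#' @param max_gap_blocks number of missing blocks tolerated inside a run
#'   (default 0 = strictly consecutive).
#' @param veto_min_blocks distinct pre-drug blocks with similar-latency
#'   peaks required for the veto to fire (default 2).
#' @return Object of class `"potentiation_call"`: `potentiated`, `criterion`
#'   (`"run5"`, `"run7"` or `"none"`), `supporting_blocks`, `latency_ms`,
#'   `duration_bins`, `total_magnitude`, `average_magnitude`, and
#'   `supporting_peaks` (data frame block/latency_ms/excess).
#' @export
classify_channel <- function(peaks_by_block, bicuculline_block,
                             pre_drug_blocks = 1:4,
                             latency_tolerance_ms = 2, run_length = 5,
                             max_gap_blocks = 0, veto_min_blocks = 2) {
  n_blocks <- length(peaks_by_block)
  if (bicuculline_block > n_blocks)
    stop("configuration error: no post-disinhibition blocks")
  post_blocks <- bicuculline_block:n_blocks
  all_peaks <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    p <- peaks_by_block[[b]]
    if (is.null(p) || !nrow(p)) return(NULL)
    cbind(block = b, p)
  }))
  none <- structure(list(potentiated = FALSE, criterion = "none",
                         supporting_blocks = integer(0), latency_ms = NA_real_,
                         duration_bins = 0L, total_magnitude = 0,
                         average_magnitude = NA_real_,
                         supporting_peaks = data.frame(block = integer(0),
                                                       latency_ms = numeric(0),
                                                       excess = numeric(0))),
                    class = "potentiation_call")
  if (is.null(all_peaks)) return(none)
  post_peaks <- all_peaks[all_peaks$block %in% post_blocks, , drop = FALSE]
  if (!nrow(post_peaks)) return(none)
  pre_peaks <- all_peaks[all_peaks$block %in% pre_drug_blocks, , drop = FALSE]

  best <- NULL
  for (lam in sort(unique(post_peaks$latency_ms))) {
    pre_near <- abs(pre_peaks$latency_ms - lam) <= latency_tolerance_ms + 1e-9
    if (length(unique(pre_peaks$block[pre_near])) >= veto_min_blocks) next
    near <- abs(post_peaks$latency_ms - lam) <= latency_tolerance_ms + 1e-9
    blocks_with <- sort(unique(post_peaks$block[near]))
    run <- longest_run(blocks_with, max_gap_blocks)
    if (length(run) < run_length) next
    excess <- sum(post_peaks$excess[near & post_peaks$block %in% run])
    if (is.null(best) || length(run) > length(best$run) ||
        (length(run) == length(best$run) && excess > best$excess))
      best <- list(lambda = lam, run = run, excess = excess)
  }
  if (is.null(best)) return(none)
  sel <- post_peaks$block %in% best$run &
    abs(post_peaks$latency_ms - best$lambda) <= latency_tolerance_ms + 1e-9
  sp <- post_peaks[sel, c("block", "latency_ms", "excess")]
  dur <- length(unique(sp$latency_ms))
  tot <- sum(sp$excess)
  structure(list(potentiated = TRUE,
                 criterion = if (length(best$run) >= 7) "run7" else "run5",
                 supporting_blocks = best$run,
                 latency_ms = min(sp$latency_ms),
                 duration_bins = as.integer(dur),
                 total_magnitude = tot,
                 average_magnitude = tot / dur,
                 supporting_peaks = sp),
            class = "potentiation_call")
}

## Longest run of consecutive integers in sorted x, allowing up to
## `max_gap` missing values between members; returns the members of the run.
longest_run <- function(x, max_gap = 0) {
  if (!length(x)) return(integer(0))
  breaks <- c(0, which(diff(x) > max_gap + 1), length(x))
  lens <- diff(breaks)
  ## run length measured in supporting blocks present
  i <- which.max(lens)
  x[(breaks[i] + 1):breaks[i + 1]]
}

#' @export
print.potentiation_call <- function(x, ...) {
  if (!x$potentiated) {
    cat("Channel not potentiated\n")
  } else {
    cat(sprintf("Channel potentiated (%s): latency %g ms, duration %d bins\n",
                x$criterion, x$latency_ms, x$duration_bins))
    cat(sprintf("  blocks %s; total magnitude %.1f, average %.2f/bin\n",
                paste(range(x$supporting_blocks), collapse = "-"),
                x$total_magnitude, x$average_magnitude))
  }
  invisible(x)
}

#' Quantify a potentiated response
#'
#' Recomputes latency (first bin of the potentiated response), duration
#' (distinct bins with peaks across the supporting blocks), total magnitude
#' (summed excess of all supporting peaks) and average magnitude
#' (total/duration) from a potentiated call.
#'
#' @param call a [classify_channel()] result with `potentiated = TRUE`.
#' @return List `latency_ms`, `duration_bins`, `total_magnitude`,
#'   `average_magnitude`.
#' @export
quantify <- function(call) {
  stopifnot(inherits(call, "potentiation_call"))
  if (!call$potentiated) stop("contract error: channel is not potentiated")
  sp <- call$supporting_peaks
  dur <- length(unique(sp$latency_ms))
  tot <- sum(sp$excess)
  list(latency_ms = min(sp$latency_ms), duration_bins = as.integer(dur),
       total_magnitude = tot, average_magnitude = tot / dur)
}

#' Multichannel potentiation analysis
#'
#' Runs the Experiment-3 pipeline over every channel: baseline-corrected
#' block PSTHs, the 8-block average baseline response with per-bin
#' dispersion, per-block potentiation-peak detection (mean + 2 SD per bin),
#' and the consecutive-block channel classification.
#'
#' @param dataset a [simulate_experiment()] dataset or named list of spike
#'   trains.
#' @param schedule event schedule (taken from the dataset when omitted);
#'   its epochs determine the default block roles.
#' @param baseline_blocks blocks of the average baseline response (default:
#'   the 8 blocks preceding the gated epoch, i.e. 5-12 in the standard
#'   design).
#' @param pre_drug_blocks veto blocks (default 1-4).
#' @param bicuculline_block first post-disinhibition block (default: onset
#'   of the gated epoch).
#' @param window,bin_width_ms PSTH parameters.
#' @param peak_sd_mult per-bin SD multiplier for peak detection.
#' @param latency_tolerance_ms,run_length,max_gap_blocks see
#'   [classify_channel()].
#' @param veto_scope `"pre_drug"` (veto restricted to the pre-drug blocks)
#'   or `"all_pre_bicuculline"` (veto over every pre-disinhibition block).
#' @param veto_min_blocks see [classify_channel()].
#' @param sd_floor see [detect_peaks()].
#' @param response_ms peak-detection window (ms).
#' @return Object of class `"potentiation_calls"`: `table` (one row per
#'   channel: channel, potentiated, criterion, latency_ms, duration_bins,
#'   total_magnitude, average_magnitude, supporting_blocks), `calls` (per
#'   channel [classify_channel()] objects), `params`.
#' @export
analyze_potentiation <- function(dataset, schedule = NULL,
                                 baseline_blocks = NULL, pre_drug_blocks = 1:4,
                                 bicuculline_block = NULL,
                                 window = c(-500, 100), bin_width_ms = 1,
                                 peak_sd_mult = 2, latency_tolerance_ms = 2,
                                 run_length = 5, max_gap_blocks = 0,
                                 veto_scope = c("pre_drug", "all_pre_bicuculline"),
                                 veto_min_blocks = 2, sd_floor = TRUE,
                                 response_ms = c(0, 50)) {
  veto_scope <- match.arg(veto_scope)
  if (inherits(dataset, "striatpot_dataset") && is.null(schedule))
    schedule <- dataset$schedule
  set <- block_psths(dataset, schedule, window, bin_width_ms)
  if (is.null(bicuculline_block)) {
    bicuculline_block <- gated_onset_block(schedule)
    if (is.na(bicuculline_block))
      stop("configuration error: schedule has no gated epoch; pass 'bicuculline_block'")
  }
  if (is.null(baseline_blocks))
    baseline_blocks <- max(1, bicuculline_block - 8):(bicuculline_block - 1)
  veto <- if (veto_scope == "pre_drug") pre_drug_blocks else seq_len(bicuculline_block - 1)

  calls <- vector("list", length(set$channels))
  names(calls) <- set$channels
  for (ch in seq_along(set$channels)) {
    adj <- lapply(seq_len(set$n_blocks),
                  function(b) subtract_spontaneous(get_psth(set, ch, b)))
    prof <- baseline_profile(adj[baseline_blocks],
                             expected_blocks = length(baseline_blocks))
    peaks <- lapply(adj, detect_peaks, profile = prof, k = peak_sd_mult,
                    response_ms = response_ms, sd_floor = sd_floor)
    calls[[ch]] <- classify_channel(peaks, bicuculline_block, veto,
                                    latency_tolerance_ms, run_length,
                                    max_gap_blocks, veto_min_blocks)
  }
  tab <- do.call(rbind, lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    data.frame(channel = set$channels[i], potentiated = cl$potentiated,
               criterion = cl$criterion, latency_ms = cl$latency_ms,
               duration_bins = cl$duration_bins,
               total_magnitude = cl$total_magnitude,
               average_magnitude = cl$average_magnitude,
               supporting_blocks = paste(cl$supporting_blocks, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, calls = calls,
                 params = list(baseline_blocks = baseline_blocks,
                               pre_drug_blocks = pre_drug_blocks,
                               bicuculline_block = bicuculline_block,
                               window = window, bin_width_ms = bin_width_ms,
                               peak_sd_mult = peak_sd_mult,
                               latency_tolerance_ms = latency_tolerance_ms,
                               run_length = run_length,
                               veto_scope = veto_scope,
                               veto_min_blocks = veto_min_blocks,
                               sd_floor = sd_floor)),
            class = "potentiation_calls")
}

#' @export
print.potentiation_calls <- function(x, ...) {
  if (is.null(x$table)) {
    cat("Potentiation calls: no channels\n")
    return(invisible(x))
  }
  n <- nrow(x$table)
  np <- sum(x$table$potentiated)
  cat(sprintf("Potentiation calls: %d/%d channels potentiated (%.1f%%)\n",
              np, n, 100 * np / n))
  if (np) {
    p <- x$table[x$table$potentiated, ]
    cat(sprintf("  latencies %s ms; mean duration %.1f bins; mean total magnitude %.1f\n",
                paste(p$latency_ms, collapse = ", "),
                mean(p$duration_bins), mean(p$total_magnitude)))
  }
  invisible(x)
}

#' @export
summary.potentiation_calls <- function(object, ...) object$table
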