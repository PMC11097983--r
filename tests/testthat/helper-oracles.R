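## Independent brute-force oracles and small fixture builders.  The oracles
## deliberately use naive double loops / explicit formulas so they share no
## code path with the implementation they check.

## PSTH by explicit double loop over (spike, stim) pairs.
oracle_psth <- function(spikes, stim_times, window, bin_width_ms) {
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width_ms))
  counts <- integer(n_bins)
  for (sp in spikes) {
    for (st in stim_times) {
      off <- (sp - st) * 1000
      if (off >= window[1] && off < window[2]) {
        b <- floor((off - window[1]) / bin_width_ms + 1e-6) + 1
        if (b >= 1 && b <= n_bins) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

## Mean / population SD by explicit loops.
oracle_mean_sd <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  list(mean = m, sd = sqrt(s / length(x)))
}

## Peak detection by explicit per-bin scan.
oracle_peaks <- function(adjusted, prof_mean, prof_sd, bins, k = 2,
                         response = c(0, 50)) {
  out <- data.frame(latency_ms = numeric(0), excess = numeric(0))
  for (i in seq_along(bins)) {
    if (bins[i] < response[1] || bins[i] >= response[2]) next
    if (adjusted[i] > prof_mean[i] + k * prof_sd[i])
      out <- rbind(out, data.frame(latency_ms = bins[i],
                                   excess = adjusted[i] - prof_mean[i]))
  }
  out
}

## Pearson chi-square on a 2x2 by the textbook expected-count formula.
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  rs <- rowSums(obs); cs <- colSums(obs); N <- sum(obs)
  exp_ <- outer(rs, cs) / N
  sum((obs - exp_)^2 / exp_)
}

## Construct a bare psth object with given counts (window in ms).
make_psth <- function(counts, window = c(-500, 100), bin_width_ms = 1,
                      n_stims = 120) {
  structure(list(counts = as.integer(counts),
                 bin_starts_ms = window[1] + bin_width_ms * (seq_along(counts) - 1),
                 bin_width_ms = bin_width_ms, window_ms = window,
                 n_stims = n_stims, channel_id = NA, block_index = NA),
            class = "psth")
}

## A psth with given counts at specific post-stimulus bins (ms), rest 0.
make_response_psth <- function(at_ms, values, baseline_value = 0,
                               window = c(-500, 100)) {
  n <- window[2] - window[1]
  counts <- rep(baseline_value, n)
  bins <- window[1]:(window[2] - 1)
  counts[match(at_ms, bins)] <- values
  make_psth(counts, window)
}

## Peak lists for classify_channel tests: peaks at `latency` in `blocks`.
make_peaks <- function(n_blocks, latency_blocks, latency_ms = 10, excess = 3) {
  lapply(seq_len(n_blocks), function(b) {
    if (b %in% latency_blocks)
      data.frame(latency_ms = latency_ms, excess = excess)
    else data.frame(latency_ms = numeric(0), excess = numeric(0))
  })
}

## Small standard protocols/schedules for simulation tests.
quick_protocol <- function(rate = 1, blocks = 4, block_size = 30, jitter = 0.2)
  stim_protocol(rate, jitter, block_size, blocks)

exp3_protocol <- function(n_blocks = 20)
  stim_protocol(0.33, 0.3, 120, n_blocks, flash_delay_s = 0.25)

exp1_protocol <- function(n_blocks = 24)
  stim_protocol(0.5, 0.3, 120, n_blocks, flash_delay_s = 0.25)

## Channel whose mono- and multisynaptic components overlap into a single
## contiguous evoked response (the unimodal multi-unit regime of the
## duration measure).
merged_response_model <- function(gain = 2, onset = 13, baseline = 30)
  channel_model(baseline, list(
    response_component(8.5, 0.5, 1.2, potentiable = TRUE),
    response_component(12.5, 2.5, 1.0, potentiable = TRUE)),
    potentiation_onset_block = if (gain > 1) onset else NA,
    potentiation_gain = gain)
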