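#' Evoked-response component
#'
#' One latency-structured component of a channel's cortically-evoked
#' response.  Per stimulation the component emits a Poisson-distributed
#' number of spikes (mean `probability` times any active gain), each placed
#' at `latency_ms` plus Gaussian jitter, truncated at the stimulation time.
#' Components below 12 ms model monosynaptic cortical drive; longer
#' latencies model multisynaptic routes.
#'
#' @param latency_ms mean spike latency after the stimulation, in
#'   milliseconds; must lie in the 0-50 ms detection window.
#' @param latency_jitter_ms Gaussian SD of the emitted latency (ms).
#' @param probability expected spikes per stimulation (>= 0; may exceed 1
#'   for multi-unit channels).
#' @param potentiable logical; does the reinforcement gain apply to this
#'   component?
#' @return An object of class `"response_component"`.
#' @export
response_component <- function(latency_ms, latency_jitter_ms = 1,
                               probability = 1, potentiable = FALSE) {
  if (latency_ms < 0 || latency_ms >= 50)
    stop("invalid component: 'latency_ms' must lie in [0, 50)")
  if (probability < 0) stop("invalid component: 'probability' must be >= 0")
  if (latency_jitter_ms < 0) stop("invalid component: negative jitter")
  structure(list(latency_ms = latency_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 probability = probability,
                 potentiable = isTRUE(potentiable)),
            class = "response_component")
}

#' Generative model for one recording channel
#'
#' A channel is a homogeneous Poisson background at `baseline_rate_hz`
#' superposed with stimulus-locked evoked components.  From
#' `potentiation_onset_block` onward, `potentiation_gain` multiplies the
#' probability of every potentiable component, ramping up linearly over
#' `ramp_blocks` blocks (potentiation in vivo grows gradually rather than
#' stepping); an optional `new_component` switches on at the same block,
#' modelling spiking at a novel latency after reinforcement.  `drug_scale`
#' multiplies all component probabilities from the first systemic-drug block
#' of the schedule onward.
#'
#' @param baseline_rate_hz spontaneous multi-unit firing rate (Hz), >= 0.
#' @param components list of [response_component()]s (may be empty for an
#'   unresponsive channel).
#' @param potentiation_onset_block 1-based block at which potentiation
#'   begins, or `NA` for a non-potentiating channel.
#' @param potentiation_gain multiplicative gain on potentiable components
#'   (>= 1 when an onset block is set).
#' @param ramp_blocks blocks over which the gain ramps from 1 to its full
#'   value (>= 1; 1 = step change).
#' @param new_component optional [response_component()] appearing at
#'   potentiation onset (its probability ramps with the gain).
#' @param drug_scale multiplicative factor on all components from the drug
#'   epoch onward (1 = no drug effect).
#' @return An object of class `"channel_model"`.
#' @export
channel_model <- function(baseline_rate_hz = 30, components = list(),
                          potentiation_onset_block = NA_integer_,
                          potentiation_gain = 1, ramp_blocks = 4,
                          new_component = NULL, drug_scale = 1) {
  if (baseline_rate_hz < 0) stop("invalid model: negative 'baseline_rate_hz'")
  if (!all(vapply(components, inherits, TRUE, "response_component")))
    stop("invalid model: 'components' must be response_component objects")
  if (!is.na(potentiation_onset_block) && potentiation_gain < 1)
    stop("invalid model: 'potentiation_gain' must be >= 1 when an onset block is set")
  if (ramp_blocks < 1) stop("invalid model: 'ramp_blocks' must be >= 1")
  if (drug_scale < 0) stop("invalid model: negative 'drug_scale'")
  structure(list(baseline_rate_hz = baseline_rate_hz,
                 components = components,
                 potentiation_onset_block = as.integer(potentiation_onset_block),
                 potentiation_gain = potentiation_gain,
                 ramp_blocks = as.integer(ramp_blocks),
                 new_component = new_component,
                 drug_scale = drug_scale),
            class = "channel_model")
}

## Potentiation gain factor per block (linear ramp from onset).
potentiation_factor <- function(model, blocks) {
  g <- rep(1, length(blocks))
  ob <- model$potentiation_onset_block
  if (!is.na(ob)) {
    frac <- pmin(1, pmax(0, (blocks - ob + 1) / model$ramp_blocks))
    g <- 1 + (model$potentiation_gain - 1) * frac
  }
  g
}

## Ramp fraction for the new component (0 before onset, 1 when full).
new_component_fraction <- function(model, blocks) {
  ob <- model$potentiation_onset_block
  if (is.na(ob)) return(rep(0, length(blocks)))
  pmin(1, pmax(0, (blocks - ob + 1) / model$ramp_blocks))
}

#' Simulate one channel's spike train
#'
#' Superposes a homogeneous Poisson background over the recording with, for
#' each stimulation and each component, a Poisson count of evoked spikes
#' (mean = probability x potentiation gain x drug scale for that
#' stimulation's block) at Gaussian-jittered latencies truncated at zero.
#' Background and evoked processes are independent; no refractoriness is
#' modelled (multi-unit activity).
#'
#' @param model a [channel_model()].
#' @param schedule an [generate_stim_times()] event schedule.
#' @param seed integer RNG seed.
#' @return Sorted numeric vector of spike times in seconds, within
#'   \[0, `schedule$duration_s`\].
#' @export
simulate_channel <- function(model, schedule, seed) {
  stopifnot(inherits(model, "channel_model"), inherits(schedule, "event_schedule"))
  if (!length(schedule$stim_times)) stop("empty schedule")
  set.seed(seed)
  dur <- schedule$duration_s
  ## background: Poisson process on [0, dur]
  n_bg <- stats::rpois(1, model$baseline_rate_hz * dur)
  spikes <- stats::runif(n_bg, 0, dur)

  blocks <- schedule$block
  drug_blocks <- epoch_blocks(schedule, "drug_any")
  drug_on <- if (length(drug_blocks)) blocks >= drug_blocks[1] else rep(FALSE, length(blocks))
  dscale <- ifelse(drug_on, model$drug_scale, 1)
  pot <- potentiation_factor(model, blocks)

  emit <- function(comp, lambda) {
    counts <- stats::rpois(length(lambda), lambda)
    tot <- sum(counts)
    if (!tot) return(numeric(0))
    stim <- rep(schedule$stim_times, counts)
    lat <- pmax(0, stats::rnorm(tot, comp$latency_ms, comp$latency_jitter_ms)) / 1000
    stim + lat
  }
  for (comp in model$components) {
    gain <- if (comp$potentiable) pot else rep(1, length(blocks))
    spikes <- c(spikes, emit(comp, comp$probability * gain * dscale))
  }
  if (!is.null(model$new_component)) {
    frac <- new_component_fraction(model, blocks)
    spikes <- c(spikes, emit(model$new_component,
                             model$new_component$probability * frac * dscale))
  }
  sort(spikes[spikes >= 0 & spikes <= dur])
}

#' Default 16-channel array models
#'
#' Builds the channel models for a simulated 16-channel experiment: a
#' responsive subset carries the canonical two-component evoked response
#' (monosynaptic 8 ms, multisynaptic 18 ms, either side of the 12 ms split),
#' and a sub-subset of those potentiates from `potentiation_onset_block`.
#'
#' @param n_channels array size.
#' @param n_responsive channels with an evoked response (the first
#'   `n_responsive`).
#' @param n_potentiating responsive channels that potentiate (the first
#'   `n_potentiating`).
#' @param baseline_rate_hz background rate for every channel.
#' @param potentiation_gain gain applied to the potentiable 8 ms component.
#' @param potentiation_onset_block onset block for potentiating channels
#'   (`NA` allowed only when `n_potentiating` is 0).
#' @param drug_scale drug scaling applied to all responsive channels.
#' @param mono_probability,multi_probability expected spikes/stimulus of the
#'   8 ms and 18 ms components.
#' @return List of `n_channels` [channel_model()]s.
#' @export
default_channel_models <- function(n_channels = 16, n_responsive = 6,
                                   n_potentiating = 4, baseline_rate_hz = 30,
                                   potentiation_gain = 2,
                                   potentiation_onset_block = NA,
                                   drug_scale = 1,
                                   mono_probability = 1,
                                   multi_probability = 0.5) {
  stopifnot(n_responsive <= n_channels, n_potentiating <= n_responsive)
  if (n_potentiating > 0 && is.na(potentiation_onset_block))
    stop("potentiating channels need 'potentiation_onset_block'")
  lapply(seq_len(n_channels), function(i) {
    if (i > n_responsive)
      return(channel_model(baseline_rate_hz, list()))
    comps <- list(
      response_component(8, 0.5, mono_probability, potentiable = TRUE),
      response_component(18, 1.5, multi_probability, potentiable = FALSE))
    channel_model(baseline_rate_hz, comps,
                  potentiation_onset_block =
                    if (i <= n_potentiating) potentiation_onset_block else NA,
                  potentiation_gain = potentiation_gain,
                  drug_scale = drug_scale)
  })
}

#' Simulate a full multichannel experiment
#'
#' One spike train per channel, each from an independent sub-seed derived
#' from `seed`, together with the ground truth needed for recovery testing.
#'
#' @param protocol a [stim_protocol()].
#' @param channel_models list of [channel_model()]s (one per channel).
#' @param seed integer master seed.
#' @param epochs optional condition-epoch table attached to the schedule.
#' @return A list of class `"striatpot_dataset"` with elements `spikes`
#'   (named list of per-channel spike-time vectors, names `ch01`, ...),
#'   `schedule`, and `ground_truth` (data frame: `channel`, `potentiated`,
#'   `onset_block`, `latencies_ms` as a comma-joined string).
#' @export
simulate_experiment <- function(protocol, channel_models, seed, epochs = NULL) {
  stopifnot(length(channel_models) >= 1)
  schedule <- generate_stim_times(protocol, seed = seed, epochs = epochs)
  set.seed(seed + 1L)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(channel_models))
  ids <- sprintf("ch%02d", seq_along(channel_models))
  spikes <- stats::setNames(
    mapply(function(m, s) simulate_channel(m, schedule, seed = s),
           channel_models, sub_seeds, SIMPLIFY = FALSE), ids)
  gt <- do.call(rbind, lapply(seq_along(channel_models), function(i) {
    m <- channel_models[[i]]
    pot <- !is.na(m$potentiation_onset_block)
    lats <- numeric(0)
    if (pot) {
      lats <- vapply(Filter(function(cc) cc$potentiable, m$components),
                     function(cc) cc$latency_ms, numeric(1))
      if (!is.null(m$new_component))
        lats <- c(lats, m$new_component$latency_ms)
    }
    data.frame(channel = ids[i], potentiated = pot,
               onset_block = m$potentiation_onset_block,
               latencies_ms = paste(lats, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(spikes = spikes, schedule = schedule, ground_truth = gt),
            class = "striatpot_dataset")
}

#' @export
print.striatpot_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d channels, %d stimulations, %.0f s\n",
              length(x$spikes), length(x$schedule$stim_times),
              x$schedule$duration_s))
  cat(sprintf("  potentiated channels (ground truth): %d\n",
              sum(x$ground_truth$potentiated)))
  invisible(x)
}

## Biphasic extracellular spike template (dominant negative deflection),
## ~1.2 ms long at the given sampling rate, negative peak = -1.
spike_template <- function(sampling_rate_hz) {
  t <- seq(0, 0.0012, by = 1 / sampling_rate_hz)
  w <- -exp(-((t - 0.0001) / 0.00015)^2) + 0.35 * exp(-((t - 0.0005) / 0.00025)^2)
  w / max(abs(w))
}

#' Simulate a raw voltage trace from a spike train
#'
#' Adds a biphasic spike template (dominant negative deflection, amplitude
#' `waveform_amplitude`) at each spike time to a Gaussian noise trace.  The
#' trace exists solely to exercise threshold-based spike extraction; no
#' waveform-shape realism beyond the single template is attempted.
#'
#' @param spikes numeric vector of spike times (s).
#' @param duration_s trace length (s); defaults to covering the last spike.
#' @param waveform_amplitude negative-peak amplitude (a.u.).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param sampling_rate_hz sampling rate, > 0 (extracellular multi-unit
#'   recordings are typically sampled at 15-25 kHz).
#' @param seed integer RNG seed.
#' @return A list of class `"voltage_trace"`: `samples`, `sampling_rate_hz`,
#'   `duration_s`.
#' @export
simulate_raw_trace <- function(spikes, duration_s = NULL,
                               waveform_amplitude = 1, noise_sd = 0.1,
                               sampling_rate_hz = 15000, seed = 1) {
  if (sampling_rate_hz <= 0) stop("'sampling_rate_hz' must be positive")
  if (is.null(duration_s))
    duration_s <- if (length(spikes)) max(spikes) + 0.005 else 1
  n <- ceiling(duration_s * sampling_rate_hz)
  set.seed(seed)
  v <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  if (length(spikes) && waveform_amplitude != 0) {
    w <- spike_template(sampling_rate_hz) * waveform_amplitude
    for (s in spikes) {
      i0 <- floor(s * sampling_rate_hz) + 1
      idx <- i0:min(n, i0 + length(w) - 1)
      if (idx[1] <= n)
        v[idx] <- v[idx] + w[seq_along(idx)]
    }
  }
  structure(list(samples = v, sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s), class = "voltage_trace")
}

#' Block-level evoked-response magnitudes from the generative model
#'
#' Draws per-channel per-block response values directly from the generator's
#' block-level marginal distribution, bypassing spike-level simulation.  The
#' pipeline's block response value (baseline-subtracted spike count summed
#' over the 0-50 ms window) decomposes as: Poisson evoked count with mean
#' `block_size x sum(probability x gains)`, plus the background count in the
#' response window, minus the scaled background count of the 500 ms baseline
#' window used for subtraction.  This is the distribution the spike-level
#' pipeline produces (up to latency truncation at the window edge) and is
#' used for statistical calibration runs where thousands of replicates are
#' needed.
#'
#' @param models list of [channel_model()]s.
#' @param n_blocks number of blocks to draw.
#' @param block_size stimulations per block.
#' @param drug_onset_block block from which `drug_scale` applies (`NA` =
#'   never).
#' @param response_window_ms,baseline_window_ms window lengths (ms) of the
#'   response sum and of the spontaneous-rate estimate.
#' @param seed integer RNG seed.
#' @return Matrix `length(models)` x `n_blocks` of response values.
#' @export
simulate_block_magnitudes <- function(models, n_blocks, block_size = 120,
                                      drug_onset_block = NA,
                                      response_window_ms = 50,
                                      baseline_window_ms = 500, seed = 1) {
  set.seed(seed)
  blocks <- seq_len(n_blocks)
  drug_on <- if (is.na(drug_onset_block)) rep(FALSE, n_blocks) else blocks >= drug_onset_block
  out <- matrix(0, nrow = length(models), ncol = n_blocks)
  wr <- response_window_ms / 1000
  wb <- baseline_window_ms / 1000
  for (i in seq_along(models)) {
    m <- models[[i]]
    dscale <- ifelse(drug_on, m$drug_scale, 1)
    pot <- potentiation_factor(m, blocks)
    lam <- rep(0, n_blocks)
    for (comp in m$components) {
      gain <- if (comp$potentiable) pot else 1
      lam <- lam + comp$probability * gain * dscale
    }
    evoked <- stats::rpois(n_blocks, block_size * lam)
    bg_resp <- stats::rpois(n_blocks, block_size * m$baseline_rate_hz * wr)
    bg_base <- stats::rpois(n_blocks, block_size * m$baseline_rate_hz * wb)
    out[i, ] <- evoked + bg_resp - (wr / wb) * bg_base
  }
  out
}
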