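#' Stimulation protocol
#'
#' Describes a train of single-pulse cortical stimulations delivered at a
#' nominal rate with uniformly jittered inter-stimulus intervals (ISIs),
#' grouped into fixed-size blocks, optionally paired with a light flash at a
#' fixed delay.
#'
#' With nominal rate \eqn{r} and jitter fraction \eqn{j}, every ISI is drawn
#' independently and uniformly from \eqn{[(1-j)/r, (1+j)/r]}; at 0.5 Hz with
#' 30\% jitter this is the 1.4--2.6 s range.
#'
#' @param nominal_rate_hz average stimulation rate (events/s), > 0.
#' @param jitter_fraction fraction of the nominal ISI by which intervals are
#'   jittered, in \[0, 1).
#' @param block_size stimulations per block (the unit over which one PSTH is
#'   accumulated).
#' @param n_blocks number of blocks; total stimulations =
#'   `block_size * n_blocks`.
#' @param flash_delay_s delay of the reinforcing light flash relative to each
#'   stimulation, in seconds (may be negative), or `NA` for no flash.
#' @param flash_duration_s flash duration in seconds.
#' @return An object of class `"stim_protocol"`.
#' @examples
#' stim_protocol(0.5, 0.3, block_size = 120, n_blocks = 6)
#' @export
stim_protocol <- function(nominal_rate_hz = 0.5, jitter_fraction = 0.3,
                          block_size = 120, n_blocks = 6,
                          flash_delay_s = NA_real_, flash_duration_s = 0.010) {
  if (!is.numeric(nominal_rate_hz) || nominal_rate_hz <= 0)
    stop("invalid protocol: 'nominal_rate_hz' must be positive")
  if (jitter_fraction < 0 || jitter_fraction >= 1)
    stop("invalid protocol: 'jitter_fraction' must lie in [0, 1)")
  if (block_size < 1 || block_size != round(block_size))
    stop("invalid protocol: 'block_size' must be a positive integer")
  if (n_blocks < 1 || n_blocks != round(n_blocks))
    stop("invalid protocol: 'n_blocks' must be a positive integer")
  structure(list(
    nominal_rate_hz = nominal_rate_hz,
    jitter_fraction = jitter_fraction,
    block_size = as.integer(block_size),
    n_blocks = as.integer(n_blocks),
    flash_delay_s = flash_delay_s,
    flash_duration_s = flash_duration_s
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  T <- 1 / x$nominal_rate_hz
  cat(sprintf("Stimulation protocol: %.3g Hz, %.0f%% jitter (ISI %.3g-%.3g s)\n",
              x$nominal_rate_hz, 100 * x$jitter_fraction,
              T * (1 - x$jitter_fraction), T * (1 + x$jitter_fraction)))
  cat(sprintf("  %d blocks x %d stimulations\n", x$n_blocks, x$block_size))
  if (!is.na(x$flash_delay_s))
    cat(sprintf("  light flash at %+.3g ms, %.3g ms duration\n",
                1000 * x$flash_delay_s, 1000 * x$flash_duration_s))
  invisible(x)
}

#' Condition epochs for the three experimental designs
#'
#' Blocks are annotated with the condition in force: a pre-pairing or pre-drug
#' baseline, a systemic drug epoch, light pairing, and the collicular
#' disinhibition (gated reinforcement) window during which potentiation can be
#' induced.
#'
#' `epochs_exp1()` models the first design: 6 baseline blocks, 6 light-paired
#' blocks, then collicular disinhibition with continued pairing.
#' `epochs_exp3()` models the multichannel drug design: blocks 1-4 pre-drug,
#' 5-8 post-drug, 9-12 post-drug with light pairing (together the 8-block
#' baseline used by the potentiation analysis), then disinhibition from block
#' 13 on.
#'
#' @param n_blocks total number of blocks in the recording.
#' @param drug_name drug label for the systemic injection epoch (`exp3`), or
#'   `NA` for saline handling by the caller.
#' @return A data frame with columns `label`, `first_block`, `last_block`,
#'   `drug_name`, `light_paired`, `colliculus_gated`.
#' @export
epochs_exp1 <- function(n_blocks = 24) {
  stopifnot(n_blocks >= 13)
  data.frame(
    label = c("baseline", "light_pairing", "gated_pairing"),
    first_block = c(1L, 7L, 13L),
    last_block = c(6L, 12L, as.integer(n_blocks)),
    drug_name = NA_character_,
    light_paired = c(FALSE, TRUE, TRUE),
    colliculus_gated = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname epochs_exp1
#' @export
epochs_exp3 <- function(n_blocks = 20, drug_name = "saline") {
  stopifnot(n_blocks >= 13)
  data.frame(
    label = c("pre_drug", "post_drug", "post_drug_light", "gated_pairing"),
    first_block = c(1L, 5L, 9L, 13L),
    last_block = c(4L, 8L, 12L, as.integer(n_blocks)),
    drug_name = c(NA_character_, drug_name, drug_name, drug_name),
    light_paired = c(FALSE, FALSE, TRUE, TRUE),
    colliculus_gated = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate jittered stimulation times
#'
#' Draws the stimulation train defined by a [stim_protocol()]: consecutive
#' ISIs are independent uniform draws on
#' \eqn{[(1-j)/r, (1+j)/r]}, flash times (when configured) follow each
#' stimulation at the protocol's delay, and stimulations are assigned to
#' blocks of `block_size` in order.
#'
#' @param protocol a [stim_protocol()].
#' @param seed integer RNG seed.
#' @param epochs optional condition-epoch table (see [epochs_exp1()]);
#'   carried on the schedule for downstream analyses.
#' @return An object of class `"event_schedule"`: a list with `stim_times`
#'   (sorted, seconds), `flash_times` (or `NULL`), `block` (1-based block
#'   index per stimulation), `block_size`, `n_blocks`, `protocol`, `epochs`,
#'   and `duration_s` (end of recording, one nominal ISI after the last
#'   stimulation).
#' @examples
#' sched <- generate_stim_times(stim_protocol(0.5, 0.3, 120, 6), seed = 1)
#' range(diff(sched$stim_times))   # within [1.4, 2.6]
#' @export
generate_stim_times <- function(protocol, seed, epochs = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  n <- protocol$block_size * protocol$n_blocks
  T <- 1 / protocol$nominal_rate_hz
  j <- protocol$jitter_fraction
  set.seed(seed)
  isi <- stats::runif(n, T * (1 - j), T * (1 + j))
  stim <- cumsum(isi)
  flash <- if (!is.na(protocol$flash_delay_s)) stim + protocol$flash_delay_s else NULL
  structure(list(
    stim_times = stim,
    flash_times = flash,
    block = rep(seq_len(protocol$n_blocks), each = protocol$block_size),
    block_size = protocol$block_size,
    n_blocks = protocol$n_blocks,
    protocol = protocol,
    epochs = epochs,
    duration_s = stim[n] + T
  ), class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("Event schedule: %d stimulations in %d blocks of %d (%.1f s)\n",
              length(x$stim_times), x$n_blocks, x$block_size, x$duration_s))
  if (!is.null(x$flash_times)) cat("  flash paired with every stimulation\n")
  if (!is.null(x$epochs)) {
    cat("  epochs:\n")
    for (i in seq_len(nrow(x$epochs)))
      cat(sprintf("    blocks %2d-%2d  %s\n", x$epochs$first_block[i],
                  x$epochs$last_block[i], x$epochs$label[i]))
  }
  invisible(x)
}

## Blocks (1-based indices) lying inside epochs with a given flag set.
epoch_blocks <- function(schedule, flag) {
  ep <- schedule$epochs
  if (is.null(ep)) return(integer(0))
  sel <- switch(flag,
    gated = ep$colliculus_gated,
    drug = !is.na(ep$drug_name) & ep$drug_name != "saline",
    drug_any = !is.na(ep$drug_name),
    light = ep$light_paired,
    stop("unknown epoch flag: ", flag))
  out <- integer(0)
  for (i in which(sel)) out <- c(out, seq(ep$first_block[i], ep$last_block[i]))
  sort(unique(out))
}

## First block of the collicular-disinhibition (gated) epoch, or NA.
gated_onset_block <- function(schedule) {
  b <- epoch_blocks(schedule, "gated")
  if (length(b)) b[1] else NA_integer_
}
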