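## On-disk conventions: tab-delimited tables with a mandatory header,
## comment lines prefixed "#", times in seconds as decimal text with 9
## fractional digits, latencies in ms.

fmt_time <- function(x) sprintf("%.9f", x)

write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses)
}

#' Read and write spike tables
#'
#' Spike tables are tab-delimited text with columns `channel_id` and
#' `spike_time_s` (header row, UTF-8, times as decimal seconds).
#'
#' @param spikes named list of per-channel spike-time vectors.
#' @param path file path.
#' @return `read_spike_table()` returns a named list of sorted spike-time
#'   vectors.
#' @export
write_spike_table <- function(spikes, path) {
  df <- data.frame(
    channel_id = rep(names(spikes), lengths(spikes)),
    spike_time_s = fmt_time(unlist(spikes, use.names = FALSE)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- read_tsv(path, colClasses = c("character", "numeric"))
  lapply(split(df$spike_time_s, df$channel_id), sort)
}

#' Read and write event tables
#'
#' Event tables hold stimulation and flash times: columns `event_time_s`,
#' `event_kind` (`stim` or `flash`) and `block_index`.
#'
#' @param schedule an [generate_stim_times()] event schedule.
#' @param path file path.
#' @return `read_event_table()` returns a data frame with those columns.
#' @export
write_event_table <- function(schedule, path) {
  df <- data.frame(event_time_s = fmt_time(schedule$stim_times),
                   event_kind = "stim", block_index = schedule$block,
                   stringsAsFactors = FALSE)
  if (!is.null(schedule$flash_times))
    df <- rbind(df, data.frame(event_time_s = fmt_time(schedule$flash_times),
                               event_kind = "flash",
                               block_index = schedule$block,
                               stringsAsFactors = FALSE))
  df <- df[order(as.numeric(df$event_time_s)), ]
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_event_table <- function(path) {
  read_tsv(path, colClasses = c("numeric", "character", "integer"))
}

#' Read and write the schedule/condition file
#'
#' A YAML key-value file recording the protocol, recording duration, and
#' condition epochs both in block indices and in seconds (epoch start/end
#' are the first/last stimulation times of the epoch's blocks).
#'
#' @param schedule an [generate_stim_times()] event schedule.
#' @param path file path.
#' @param seed generator seed to record, if any.
#' @export
write_schedule_config <- function(schedule, path, seed = NA) {
  pr <- schedule$protocol
  epochs <- list()
  if (!is.null(schedule$epochs)) {
    for (i in seq_len(nrow(schedule$epochs))) {
      e <- schedule$epochs[i, ]
      sel <- schedule$block >= e$first_block & schedule$block <= e$last_block
      epochs[[i]] <- list(
        label = e$label,
        first_block = e$first_block, last_block = e$last_block,
        start_s = if (any(sel)) min(schedule$stim_times[sel]) else NA,
        end_s = if (any(sel)) max(schedule$stim_times[sel]) else NA,
        drug_name = if (is.na(e$drug_name)) NULL else e$drug_name,
        light_paired = e$light_paired,
        colliculus_gated = e$colliculus_gated)
    }
  }
  cfg <- list(
    seed = if (is.na(seed)) NULL else as.integer(seed),
    protocol = list(nominal_rate_hz = pr$nominal_rate_hz,
                    jitter_fraction = pr$jitter_fraction,
                    block_size = pr$block_size,
                    n_blocks = pr$n_blocks,
                    flash_delay_s = if (is.na(pr$flash_delay_s)) NULL else pr$flash_delay_s,
                    flash_duration_s = pr$flash_duration_s),
    duration_s = schedule$duration_s,
    epochs = epochs)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_schedule_config
#' @export
read_schedule_config <- function(path) yaml::read_yaml(path)

## Rebuild an event_schedule from an event table + schedule config.
schedule_from_files <- function(event_path, config_path) {
  ev <- read_event_table(event_path)
  cfg <- read_schedule_config(config_path)
  stim <- ev[ev$event_kind == "stim", ]
  stim <- stim[order(stim$event_time_s), ]
  flash <- ev$event_time_s[ev$event_kind == "flash"]
  pr <- cfg$protocol
  protocol <- stim_protocol(pr$nominal_rate_hz, pr$jitter_fraction,
                            pr$block_size, pr$n_blocks,
                            flash_delay_s = if (is.null(pr$flash_delay_s)) NA_real_ else pr$flash_delay_s,
                            flash_duration_s = pr$flash_duration_s)
  epochs <- NULL
  if (length(cfg$epochs)) {
    epochs <- do.call(rbind, lapply(cfg$epochs, function(e)
      data.frame(label = e$label, first_block = as.integer(e$first_block),
                 last_block = as.integer(e$last_block),
                 drug_name = if (is.null(e$drug_name)) NA_character_ else e$drug_name,
                 light_paired = e$light_paired,
                 colliculus_gated = e$colliculus_gated,
                 stringsAsFactors = FALSE)))
  }
  structure(list(stim_times = stim$event_time_s,
                 flash_times = if (length(flash)) sort(flash) else NULL,
                 block = stim$block_index,
                 block_size = protocol$block_size,
                 n_blocks = protocol$n_blocks,
                 protocol = protocol,
                 epochs = epochs,
                 duration_s = cfg$duration_s),
            class = "event_schedule")
}

#' Read and write ground-truth tables
#'
#' Per-channel potentiation ground truth for recovery testing: columns
#' `channel`, `potentiated`, `onset_block`, `latencies_ms` (comma-joined).
#'
#' @param ground_truth the `ground_truth` data frame of a dataset.
#' @param path file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  write_tsv(ground_truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read_tsv(path, colClasses = c("character", "logical", "integer", "character"))
}

#' Write and read a complete simulated dataset
#'
#' Writes `spikes.tsv`, `events.tsv`, `schedule.yaml` and
#' `ground_truth.tsv` into a directory; `read_dataset()` reconstructs the
#' dataset from them.
#'
#' @param dataset a [simulate_experiment()] dataset.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the schedule config.
#' @export
write_dataset <- function(dataset, dir, seed = NA) {
  stopifnot(inherits(dataset, "striatpot_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create output directory ", dir)
  write_spike_table(dataset$spikes, file.path(dir, "spikes.tsv"))
  write_event_table(dataset$schedule, file.path(dir, "events.tsv"))
  write_schedule_config(dataset$schedule, file.path(dir, "schedule.yaml"), seed)
  write_ground_truth(dataset$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  schedule <- schedule_from_files(file.path(dir, "events.tsv"),
                                  file.path(dir, "schedule.yaml"))
  gt_path <- file.path(dir, "ground_truth.tsv")
  structure(list(spikes = read_spike_table(file.path(dir, "spikes.tsv")),
                 schedule = schedule,
                 ground_truth = if (file.exists(gt_path)) read_ground_truth(gt_path) else NULL),
            class = "striatpot_dataset")
}
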