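test_that("baseline threshold is mean + k population SD of the 500 baseline bins", {
  p <- make_psth(rep(2, 600))
  expect_equal(baseline_threshold(p), list(baseline_mean = 2, baseline_sd = 0,
                                           threshold = 2))
  p2 <- make_psth(c(rep(c(0, 2), 250), rep(0, 100)))
  thr <- baseline_threshold(p2)
  expect_equal(thr$baseline_mean, 1)
  expect_equal(thr$baseline_sd, 1)        # population SD over the 500 bins
  expect_equal(thr$threshold, 4)
  expect_error(baseline_threshold(build_psth(0.1, 0, c(0, 50))),
               "configuration error")
})

test_that("threshold matches an explicit-loop oracle on random baselines", {
  set.seed(33)
  for (i in 1:100) {
    counts <- rpois(600, runif(1, 0.5, 8))
    p <- make_psth(counts)
    o <- oracle_mean_sd(counts[1:500])
    thr <- baseline_threshold(p)
    expect_equal(thr$baseline_mean, o$mean)
    expect_equal(thr$baseline_sd, o$sd)
    expect_equal(thr$threshold, o$mean + 3 * o$sd)
  }
})

test_that("response detection finds peak, onset and offset around the contiguous run", {
  p <- make_response_psth(7:10, c(5, 9, 12, 6))
  r <- detect_response(p, list(baseline_mean = 0, baseline_sd = 0, threshold = 4))
  expect_equal(r$peak_latency_ms, 9)
  expect_equal(r$onset_ms, 7)
  expect_equal(r$offset_ms, 10)
  ## flat PSTH at baseline level: nothing detected
  flat <- make_psth(rep(3, 600))
  expect_null(detect_response(flat, baseline_threshold(flat)))
  ## ties at the peak resolve to the earliest bin
  p2 <- make_response_psth(c(8, 9, 14, 15), c(7, 12, 12, 5))
  r2 <- detect_response(p2, list(baseline_mean = 0, baseline_sd = 0, threshold = 6))
  expect_equal(r2$peak_latency_ms, 9)
  expect_equal(r2$onset_ms, 8)
  expect_equal(r2$offset_ms, 9)
})

test_that("response magnitude subtracts the expected baseline count", {
  p <- make_response_psth(10:12, c(10, 8, 6))
  r <- list(onset_ms = 10, offset_ms = 12, baseline_mean = 1)
  expect_equal(response_magnitude(p, r), 24 - 3)
  p0 <- make_response_psth(10:12, c(1, 1, 1))
  expect_equal(response_magnitude(p0, r), 0)
  set.seed(44)
  for (i in 1:50) {
    counts <- rpois(600, 3)
    p <- make_psth(counts)
    on <- sample(0:40, 1); off <- on + sample(0:9, 1)
    bm <- runif(1, 0, 4)
    r <- list(onset_ms = on, offset_ms = off, baseline_mean = bm)
    idx <- 500 + (on:off) + 1
    expect_equal(response_magnitude(p, r), sum(counts[idx]) - bm * (off - on + 1))
  }
})

test_that("normalization reports percent of the pre-disinhibition baseline", {
  expect_equal(as.numeric(normalize_series(c(10, 10, 10, 15), 1:3)),
               c(100, 100, 100, 150))
  expect_equal(as.numeric(normalize_series(rep(7, 6), 1:3)), rep(100, 6))
  expect_equal(as.numeric(normalize_series(c(10, 10, 20), 1:2, "percent_change")),
               c(0, 0, 100))
  expect_error(normalize_series(c(0, 0, 5), 1:2), "undefined normalization")
})

test_that("magnitude is invariant in expectation to the background rate", {
  proto <- exp1_protocol(6)
  mag_at <- function(rate, seed_base) {
    mags <- c()
    for (s in 1:6) {
      model <- channel_model(rate, list(response_component(8.5, 0.5, 1.2)))
      ds <- simulate_experiment(proto, list(model), seed = seed_base + s,
                                epochs = NULL)
      tb <- analyze_evoked(ds, baseline_blocks = 1:6)$table
      mags <- c(mags, tb$magnitude)
    }
    mags
  }
  m20 <- mag_at(20, 1100)
  m40 <- mag_at(40, 1200)
  se <- sqrt(var(m20) / length(m20) + var(m40) / length(m40))
  expect_lt(abs(mean(m20) - mean(m40)), 4 * se)
})

test_that("false detections on non-responsive channels match the Poisson tail oracle", {
  ## pipeline rate over simulated null blocks
  proto <- exp1_protocol(20)
  hits <- 0; blocks <- 0
  for (s in 1:5) {
    ds <- simulate_experiment(proto, list(channel_model(30, list())),
                              seed = 1300 + s, epochs = NULL)
    tb <- analyze_evoked(ds, baseline_blocks = 1:20)$table
    hits <- hits + sum(!is.na(tb$onset_ms))
    blocks <- blocks + nrow(tb)
  }
  ## independent oracle: same detection rule on raw Poisson bin counts
  set.seed(77)
  oracle_hits <- 0; n_oracle <- 2000
  for (i in seq_len(n_oracle)) {
    x <- rpois(550, 30 * 0.001 * 120)
    base <- x[1:500]
    thr <- mean(base) + 3 * sqrt(mean((base - mean(base))^2))
    oracle_hits <- oracle_hits + any(x[501:550] > thr)
  }
  p_pipe <- hits / blocks
  p_oracle <- oracle_hits / n_oracle
  se <- sqrt(p_pipe * (1 - p_pipe) / blocks + p_oracle * (1 - p_oracle) / n_oracle)
  expect_lt(abs(p_pipe - p_oracle), 4 * se + 0.01)
})

test_that("full-pipeline detection recovers onset near the leading evoked bin", {
  proto <- exp1_protocol(6)
  ds <- simulate_experiment(proto, list(merged_response_model(1)), seed = 55,
                            epochs = NULL)
  tb <- analyze_evoked(ds, baseline_blocks = 1:6)$table
  expect_true(all(!is.na(tb$onset_ms)))
  expect_true(all(abs(tb$onset_ms - 7) <= 1))
  expect_true(all(tb$peak_ms >= tb$onset_ms & tb$peak_ms <= tb$offset_ms))
})
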