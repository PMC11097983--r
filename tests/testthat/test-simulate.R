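test_that("background spike count follows the Poisson expectation", {
  sched <- generate_stim_times(stim_protocol(0.5, 0.3, 120, 2), seed = 1)
  model <- channel_model(baseline_rate_hz = 30, components = list())
  sp <- simulate_channel(model, sched, seed = 11)
  lambda <- 30 * sched$duration_s
  expect_lt(abs(length(sp) - lambda), 5 * sqrt(lambda))
  expect_false(is.unsorted(sp))
  expect_true(all(sp >= 0 & sp <= sched$duration_s))
})

test_that("a deterministic-latency component places spikes at the stated latency", {
  sched <- generate_stim_times(stim_protocol(0.5, 0.3, 120, 1), seed = 2)
  model <- channel_model(0, list(response_component(8, 0, 1)))
  sp <- simulate_channel(model, sched, seed = 3)
  expect_lt(abs(length(sp) - 120), 5 * sqrt(120))
  offs <- sapply(sp, function(s) min(abs(s - (sched$stim_times + 0.008))))
  expect_true(all(offs < 1e-9))
})

test_that("unit potentiation gain leaves evoked counts distributionally unchanged", {
  proto <- quick_protocol(rate = 1, blocks = 12, block_size = 20)
  diffs <- numeric(50)
  for (s in 1:50) {
    sched <- generate_stim_times(proto, seed = 700 + s)
    model <- channel_model(0, list(response_component(8, 0.5, 1, potentiable = TRUE)),
                           potentiation_onset_block = 7, potentiation_gain = 1)
    sp <- simulate_channel(model, sched, seed = 800 + s)
    pre <- sum(sp <= max(sched$stim_times[sched$block <= 6]) + 0.05)
    diffs[s] <- (length(sp) - pre) - pre
  }
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("expected evoked count per block tracks component probabilities and gains", {
  proto <- quick_protocol(rate = 1, blocks = 8, block_size = 100)
  sched <- generate_stim_times(proto, seed = 5)
  model <- channel_model(0, list(
    response_component(8, 0.5, 0.7, potentiable = TRUE),
    response_component(18, 1, 0.3)),
    potentiation_onset_block = 5, potentiation_gain = 2, ramp_blocks = 1)
  sp <- simulate_channel(model, sched, seed = 6)
  count_block <- function(b) {
    st <- sched$stim_times[sched$block == b]
    sum(sapply(sp, function(x) any(x - st >= 0 & x - st < 0.05)))
  }
  pre <- sum(sapply(1:4, count_block))
  post <- sum(sapply(5:8, count_block))
  expect_lt(abs(pre - 400), 5 * sqrt(400))       # 100 x (0.7 + 0.3) x 4
  expect_lt(abs(post - 680), 5 * sqrt(680))      # 100 x (1.4 + 0.3) x 4
})

test_that("experiment bookkeeping records exactly the potentiating channels", {
  ds <- simulate_experiment(quick_protocol(blocks = 14),
                            default_channel_models(16, 6, 4,
                                                   potentiation_onset_block = 13),
                            seed = 21, epochs = NULL)
  expect_length(ds$spikes, 16)
  expect_equal(sum(ds$ground_truth$potentiated), 4)
  expect_equal(ds$ground_truth$channel[ds$ground_truth$potentiated],
               sprintf("ch%02d", 1:4))
  expect_equal(ds$ground_truth$latencies_ms[1], "8")
})

test_that("identical seeds reproduce the dataset; distinct seeds decorrelate", {
  proto <- quick_protocol()
  models <- default_channel_models(4, 2, 0)
  a <- simulate_experiment(proto, models, seed = 31)
  b <- simulate_experiment(proto, models, seed = 31)
  expect_identical(a, b)
  c <- simulate_experiment(proto, models, seed = 32)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("block-level magnitude draws match the spike-level pipeline", {
  proto <- exp3_protocol(12)
  model <- channel_model(30, list(response_component(8, 0.5, 1),
                                  response_component(18, 1.5, 0.5)))
  full <- c()
  for (s in 1:6) {
    ds <- simulate_experiment(proto, list(model), seed = 900 + s,
                              epochs = NULL)
    full <- c(full, as.numeric(block_response_matrix(ds)))
  }
  quick <- as.numeric(simulate_block_magnitudes(rep(list(model), 10), 12, seed = 17))
  ## same mean within joint Monte-Carlo error, similar dispersion
  se <- sqrt(var(full) / length(full) + var(quick) / length(quick))
  expect_lt(abs(mean(full) - mean(quick)), 4 * se)
  expect_lt(abs(sd(full) - sd(quick)) / sd(full), 0.3)
})

test_that("raw traces reproduce spike times under noiseless extraction", {
  spikes <- c(0.01, 0.05, 0.123, 0.4)
  tr <- simulate_raw_trace(spikes, duration_s = 0.5, waveform_amplitude = 1,
                           noise_sd = 0, seed = 1)
  det <- detect_spikes(tr, threshold = -0.5)
  expect_length(det, length(spikes))
  expect_true(all(abs(det - spikes) <= 1 / tr$sampling_rate_hz + 1e-12))
})

test_that("a spike-free noisy trace yields no detections beyond the noise floor", {
  tr <- simulate_raw_trace(numeric(0), duration_s = 1, noise_sd = 0.1, seed = 4)
  ## 6-sigma threshold: expected false alarms ~ 15000 * 1e-9, i.e. none
  expect_length(detect_spikes(tr, threshold = -0.6), 0)
})

test_that("zero-amplitude templates leave only the noise false-alarm rate", {
  spikes <- seq(0.01, 0.99, by = 0.01)
  tr0 <- simulate_raw_trace(numeric(0), duration_s = 1, noise_sd = 0.1, seed = 8)
  tr <- simulate_raw_trace(spikes, duration_s = 1, waveform_amplitude = 0,
                           noise_sd = 0.1, seed = 8)
  thr <- -0.35   # ~3.5 sigma
  expect_equal(detect_spikes(tr, thr), detect_spikes(tr0, thr))
})
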