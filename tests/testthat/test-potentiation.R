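adj_vec <- function(values, bins = 0:(length(values) - 1), spont = 0) {
  attr(values, "bin_starts_ms") <- bins
  attr(values, "spontaneous_mean") <- spont
  values
}

test_that("spontaneous subtraction removes the pre-stimulus mean from every bin", {
  p <- make_psth(c(rep(2, 500), 7, rep(2, 99)))
  adj <- subtract_spontaneous(p)
  expect_equal(attr(adj, "spontaneous_mean"), 2)
  expect_equal(as.numeric(adj[501]), 5)
  expect_equal(as.numeric(adj[c(1:500, 502:600)]), rep(0, 599))
  set.seed(3)
  for (i in 1:30) {
    counts <- rpois(600, 4)
    m <- mean(counts[1:500])
    expect_equal(as.numeric(subtract_spontaneous(make_psth(counts))), counts - m)
  }
})

test_that("baseline profile is the per-bin mean and population SD over 8 blocks", {
  vals <- c(1, 1, 1, 1, 3, 3, 3, 3)
  blocks <- lapply(vals, function(v) adj_vec(c(rep(0, 10), v, rep(0, 39))))
  prof <- baseline_profile(blocks)
  expect_equal(prof$mean[11], 2)
  expect_equal(prof$sd[11], 1)
  ident <- lapply(1:8, function(i) adj_vec(c(0, 5, 1, rep(0, 47))))
  prof2 <- baseline_profile(ident)
  expect_equal(prof2$sd, rep(0, 50))
  expect_equal(prof2$mean, c(0, 5, 1, rep(0, 47)))
  expect_error(baseline_profile(ident[1:5]), "configuration error")
  expect_s3_class(baseline_profile(ident[1:5], expected_blocks = NULL),
                  "baseline_profile")
})

test_that("peak detection uses a strict mean + 2 SD per-bin rule", {
  blocks <- lapply(c(1, 1, 1, 1, 3, 3, 3, 3),
                   function(v) adj_vec(c(rep(0, 10), v, rep(0, 39))))
  prof <- baseline_profile(blocks)
  blk <- adj_vec(c(rep(0, 10), 5, rep(0, 39)))
  pk <- detect_peaks(blk, prof, sd_floor = FALSE)
  expect_equal(pk, data.frame(latency_ms = 10, excess = 3))
  ## boundary: exactly mean + 2 SD is not a peak
  blk4 <- adj_vec(c(rep(0, 10), 4, rep(0, 39)))
  expect_equal(nrow(detect_peaks(blk4, prof, sd_floor = FALSE)), 0)
  ## peaks outside the 0-50 ms window are never reported
  blk_neg <- adj_vec(c(rep(0, 10), 5, rep(0, 39)), bins = -20:29)
  pkn <- detect_peaks(blk_neg, prof = {
    p <- baseline_profile(lapply(1:8, function(i) adj_vec(rep(0, 50), bins = -20:29)))
    p
  }, sd_floor = FALSE)
  expect_true(all(pkn$latency_ms >= 0))
})

test_that("peak detection matches a brute-force bin scan on random instances", {
  set.seed(21)
  for (i in 1:100) {
    blocks <- lapply(1:8, function(b) adj_vec(rnorm(50, 0, 2)))
    prof <- baseline_profile(blocks)
    blk <- adj_vec(rnorm(50, 0, 3))
    got <- detect_peaks(blk, prof, sd_floor = FALSE)
    want <- oracle_peaks(as.numeric(blk), prof$mean, prof$sd, 0:49)
    expect_equal(got$latency_ms, want$latency_ms)
    expect_equal(got$excess, want$excess)
  }
})

test_that("the SD floor is the Poisson counting noise of the bin", {
  blocks <- lapply(1:8, function(i) adj_vec(c(rep(0, 10), 6, rep(0, 39)), spont = 3))
  prof <- baseline_profile(blocks)
  expect_equal(prof$sd[11], 0)
  expect_equal(prof$sd_floor[11], sqrt(6 + 3))
  ## identical blocks: without the floor any excess is a peak, with it only
  ## excesses beyond counting noise are
  blk <- adj_vec(c(rep(0, 10), 7, rep(0, 39)), spont = 3)
  expect_equal(nrow(detect_peaks(blk, prof, sd_floor = FALSE)), 1)
  expect_equal(nrow(detect_peaks(blk, prof, sd_floor = TRUE)), 0)  # 7 < 6 + 2*3
})

test_that("channel classification follows the consecutive-block run rules", {
  ## 6 consecutive post-disinhibition blocks -> potentiated, criterion run5
  pk <- make_peaks(20, 13:18)
  call <- classify_channel(pk, bicuculline_block = 13)
  expect_true(call$potentiated)
  expect_equal(call$criterion, "run5")
  expect_equal(call$latency_ms, 10)
  expect_equal(call$supporting_blocks, 13:18)
  ## 7+ consecutive blocks -> run7
  expect_equal(classify_channel(make_peaks(20, 13:20), 13)$criterion, "run7")
  ## only 4 consecutive blocks -> not potentiated
  expect_false(classify_channel(make_peaks(20, 13:16), 13)$potentiated)
  ## a gap breaks the run
  expect_false(classify_channel(make_peaks(20, c(13, 14, 16, 17, 18)), 13)$potentiated)
  expect_true(classify_channel(make_peaks(20, c(13, 14, 16, 17, 18)), 13,
                               max_gap_blocks = 1)$potentiated)
  expect_error(classify_channel(make_peaks(20, 13:18), 21),
               "configuration error")
})

test_that("pre-drug peaks at similar latencies veto the call", {
  ## literal veto: a single pre-drug peak suffices
  pk1 <- make_peaks(20, c(2, 13:18))
  expect_false(classify_channel(pk1, 13, veto_min_blocks = 1)$potentiated)
  ## default recurrence veto: one isolated pre-drug peak is noise, two are not
  expect_true(classify_channel(pk1, 13)$potentiated)
  pk2 <- make_peaks(20, c(2, 3, 13:18))
  expect_false(classify_channel(pk2, 13)$potentiated)
  ## pre-drug peaks at a distant latency do not veto
  pk3 <- make_peaks(20, 13:18)
  for (b in 1:4) pk3[[b]] <- data.frame(latency_ms = 30, excess = 2)
  expect_true(classify_channel(pk3, 13)$potentiated)
  ## same latency but within pre-drug blocks only when scoped
  pk4 <- make_peaks(20, c(6, 7, 13:18))
  expect_true(classify_channel(pk4, 13, pre_drug_blocks = 1:4)$potentiated)
  expect_false(classify_channel(pk4, 13, pre_drug_blocks = 1:12)$potentiated)
})

test_that("quantification sums excesses over distinct supporting bins", {
  pk <- lapply(1:20, function(b) {
    if (b %in% 13:18) data.frame(latency_ms = c(10, 11), excess = c(3, 4))
    else data.frame(latency_ms = numeric(0), excess = numeric(0))
  })
  call <- classify_channel(pk, 13)
  q <- quantify(call)
  expect_equal(q$latency_ms, 10)
  expect_equal(q$duration_bins, 2L)
  expect_equal(q$total_magnitude, 6 * 7)
  expect_equal(q$average_magnitude, 21)
  expect_equal(call$total_magnitude, q$total_magnitude)
  ## single-peak case
  call1 <- classify_channel(make_peaks(20, 13:17, excess = 5), 13)
  expect_equal(quantify(call1)$total_magnitude, 25)
  expect_equal(quantify(call1)$average_magnitude, 25)
  expect_error(quantify(classify_channel(make_peaks(20, 13:14), 13)),
               "contract error")
  ## random peak sets against a summation oracle (latencies within one
  ## tolerance window of each other)
  set.seed(61)
  for (i in 1:20) {
    lats <- sample(9:11, sample(1:3, 1))
    exc <- runif(length(lats), 1, 5)
    pkr <- lapply(1:20, function(b) {
      if (b %in% 13:19) data.frame(latency_ms = lats, excess = exc)
      else data.frame(latency_ms = numeric(0), excess = numeric(0))
    })
    cl <- classify_channel(pkr, 13)
    expect_equal(cl$total_magnitude, 7 * sum(exc))
    expect_equal(cl$duration_bins, length(lats))
    expect_equal(cl$latency_ms, min(lats))
  }
})

test_that("a new component at a novel latency is detected there", {
  proto <- exp3_protocol(20)
  model <- channel_model(30,
    list(response_component(18, 1, 0.8, potentiable = FALSE)),
    potentiation_onset_block = 13, potentiation_gain = 1,
    new_component = response_component(5, 0.5, 1))
  hits <- 0; modal <- c()
  for (s in 1:5) {
    ds <- simulate_experiment(proto, list(model), seed = 1400 + s,
                              epochs = epochs_exp3(20))
    res <- analyze_potentiation(ds)
    if (res$table$potentiated[1]) {
      hits <- hits + 1
      sp <- res$calls[[1]]$supporting_peaks$latency_ms
      modal <- c(modal, as.numeric(names(which.max(table(sp)))))
    }
  }
  expect_gte(hits, 4)
  ## the persistent peaks sit at the novel latency, not the pre-existing one
  expect_true(all(abs(modal - 5) <= 1))
})

test_that("the end-to-end classifier is insensitive to channel order", {
  proto <- exp3_protocol(16)
  models <- default_channel_models(4, 2, 1, potentiation_onset_block = 13)
  ds <- simulate_experiment(proto, models, seed = 71, epochs = epochs_exp3(16))
  r1 <- analyze_potentiation(ds)
  ds2 <- ds
  ds2$spikes <- rev(ds2$spikes)
  r2 <- analyze_potentiation(ds2)
  expect_equal(r1$table$potentiated,
               rev(r2$table$potentiated))
})
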