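test_that("5.5-SD detection has a negligible false-positive rate on noise", {
  fs <- 20000
  set.seed(21)
  fp <- vapply(1:10, function(i) {
    x <- bandpass_filter(rnorm(fs * 60, sd = 5), fs)
    length(detect_spikes_adaptive(x, fs, k_sd = 5.5)) / 60
  }, numeric(1))
  expect_lte(mean(fp), 0.2)
})

test_that("detection recovers ground-truth spikes at 10x noise amplitude", {
  fs <- 20000
  sim <- simulate_mea_recording(4, fs, 60, baseline_rate = 2,
                                evoked_multiplier = 1, stim = NULL, seed = 5)
  tr <- detect_spikes_all(sim$recording, k_sd = 5.5)
  tol <- 0.0005 + 1 / fs
  for (e in 1:4) {
    d <- tr$trains[[e]]
    g <- sim$ground_truth$spike_times[[e]]
    rec <- mean(vapply(g, function(t) any(abs(d - t) <= tol), logical(1)))
    prec <- mean(vapply(d, function(t) any(abs(g - t) <= tol), logical(1)))
    expect_gte(rec, 0.98)
    expect_gte(prec, 0.98)
  }
})

test_that("the dead time suppresses double counts and is never violated", {
  fs <- 20000
  tmpl <- spike_template(fs, 50, 1)
  x <- rnorm(fs, sd = 2)
  for (t0 in c(0.300, 0.301)) {           # two spikes 1 ms apart
    i <- round(t0 * fs) + 1
    x[i:(i + length(tmpl) - 1)] <- x[i:(i + length(tmpl) - 1)] + tmpl
  }
  d <- detect_spikes_adaptive(x, fs, k_sd = 5.5)
  expect_equal(sum(d >= 0.299 & d <= 0.304), 1L)

  # refractory invariant on noisy multi-spike recordings
  sim <- simulate_mea_recording(2, fs, 30, baseline_rate = 20,
                                evoked_multiplier = 1, stim = NULL, seed = 2)
  tr <- detect_spikes_all(sim$recording, k_sd = 5.5)
  isis <- unlist(lapply(tr$trains, diff))
  expect_true(all(isis >= 0.00216 - 1e-9))
})

test_that("biphasic validation suppresses chance events at a 3-SD threshold", {
  fs <- 20000
  set.seed(31)
  x <- bandpass_filter(rnorm(fs * 60, sd = 5), fs)
  bare <- detect_spikes_adaptive(x, fs, k_sd = 3)
  valid <- detect_spikes_adaptive(x, fs, k_sd = 3, validate_biphasic = TRUE)
  expect_gt(length(bare) / 60, 5)          # bare 3-SD crossings are frequent
  expect_lte(length(valid) / 60, 0.3)      # shape validation removes them

  # true spikes survive validation
  sim <- simulate_mea_recording(1, fs, 30, baseline_rate = 3,
                                evoked_multiplier = 1, stim = NULL, seed = 6)
  xf <- bandpass_filter(sim$recording$raw[1, ], fs)
  d <- detect_spikes_adaptive(xf, fs, k_sd = 3, validate_biphasic = TRUE)
  g <- sim$ground_truth$spike_times[[1]]
  rec <- mean(vapply(g, function(t) any(abs(d - t) <= 0.001), logical(1)))
  expect_gte(rec, 0.95)
})

test_that("active-electrode classification uses the spikes-per-minute rule", {
  tr <- spike_train_set(list(
    A = seq(0.5, 59.5, length.out = 4),    # 4 per minute: inactive
    B = seq(0.5, 59.5, length.out = 5),    # 5 per minute: active (boundary)
    C = numeric(0)), 60)
  expect_setequal(active_electrodes(tr), "B")

  tr2 <- spike_train_set(list(A = seq(1, 119, length.out = 9)), 120)
  expect_length(active_electrodes(tr2), 0L)  # 4.5/min
})
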