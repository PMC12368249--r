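test_that("lag times pair each pulse with its first following peak", {
  l1 <- lag_times(10.135, 10.0)
  expect_equal(l1$lag, 0.135)

  l2 <- lag_times(2.5, c(0, 1))
  expect_equal(l2$lag, c(NA, 1.5))

  # peaks before any stimulation are never assigned
  l3 <- lag_times(c(0.5, 3.2), c(1, 3))
  expect_equal(l3$lag, c(NA, 0.2))

  # a peak is claimed only by the immediately preceding pulse
  l4 <- lag_times(c(1.2, 1.4), c(1, 2))
  expect_equal(l4$lag, c(0.2, NA))
})

test_that("MFR metrics compute rates, folds and normalisation", {
  tr <- spike_train_set(list(
    A = c(seq(0.5, 9.5, 1), seq(10.05, 19.95, length.out = 80), seq(20.5, 29.5, 1)),
    B = c(seq(0.5, 9.5, 1), seq(10.5, 19.5, 1), seq(20.5, 29.5, 1))), 30)
  rep_ <- mfr_metrics(tr, list(before = c(0, 10), during = c(10, 20),
                               after = c(20, 30)))
  a <- rep_$rates[rep_$rates$electrode == "A", ]
  expect_equal(a$rate_before, 1)
  expect_equal(a$rate_during, 8)
  expect_equal(a$fold_change, 8)
  expect_equal(a$norm_during, 8)
  b <- rep_$rates[rep_$rates$electrode == "B", ]
  expect_equal(b$fold_change, 1)

  # zero before-rate yields NA fold
  tr0 <- spike_train_set(list(A = c(15, 16)), 30)
  r0 <- mfr_metrics(tr0, list(before = c(0, 10), during = c(10, 20),
                              after = c(20, 30)))
  expect_true(is.na(r0$rates$fold_change))

  expect_error(mfr_metrics(tr, list(before = c(0, 10), during = c(5, 20),
                                    after = c(20, 30))), "disjoint")
  expect_error(mfr_metrics(tr, list(before = c(0, 0.5), during = c(1, 2),
                                    after = c(2, 3))), "1 s")
})

test_that("the MFR pipeline recovers the generator's evoked multiplier", {
  folds <- vapply(1:5, function(s) {
    stim <- stim_schedule(200, 200)        # one long pulse covering [200, 400)
    sim <- simulate_mea_recording(16, 20000, 600, baseline_rate = 1,
                                  evoked_multiplier = 3, stim = stim,
                                  seed = s, render = FALSE)
    tr <- spike_train_set(sim$ground_truth$spike_times, 600)
    rep_ <- mfr_metrics(tr, list(before = c(0, 200), during = c(200, 400),
                                 after = c(400, 600)))
    stats::median(rep_$rates$fold_change)
  }, numeric(1))
  expect_true(all(abs(folds - 3) <= 0.5))
})

test_that("spike sorting separates template families and is deterministic", {
  fs <- 20000
  t1 <- spike_template(fs, 50, 1)
  t2 <- -0.8 * rev(spike_template(fs, 70, 1))
  set.seed(91)
  wf <- rbind(t(replicate(200, t1 + rnorm(length(t1), sd = 1))),
              t(replicate(200, t2 + rnorm(length(t2), sd = 1))))
  sr <- sort_spikes(wf, seed = 3)
  expect_equal(sr$n_units, 2L)
  truth <- rep(1:2, each = 200)
  agree <- max(mean(sr$labels == truth), mean(sr$labels == 3 - truth))
  expect_gte(agree, 0.98)
  expect_equal(dim(sr$pc_scores), c(400L, 5L))
  expect_length(sr$labels, 400L)

  sr2 <- sort_spikes(wf, seed = 3)
  expect_identical(sr$labels, sr2$labels)

  # identical waveforms collapse to one unit
  same <- matrix(rep(t1, 40), nrow = 40, byrow = TRUE)
  expect_equal(sort_spikes(same, seed = 1)$n_units, 1L)

  expect_warning(sort_spikes(wf[1:12, ], seed = 1), "max_k")
})

test_that("waveform extraction windows spikes and drops edge cases", {
  fs <- 20000
  x <- rnorm(fs, sd = 1)
  w <- extract_waveforms(x, fs, c(0.0001, 0.5, 0.99999))
  expect_equal(nrow(w$waveforms), 1L)
  expect_equal(w$times, 0.5)
  expect_equal(ncol(w$waveforms), round(0.0006 * fs) + round(0.0014 * fs) + 1)
})
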