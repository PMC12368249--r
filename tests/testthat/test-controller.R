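poisson_trains <- function(n_electrodes, rate, duration, seed) {
  set.seed(seed)
  trains <- lapply(seq_len(n_electrodes), function(e)
    sort(stats::runif(stats::rpois(1, rate * duration), 0, duration)))
  names(trains) <- paste0("E", seq_len(n_electrodes))
  spike_train_set(trains, duration)
}

test_that("baseline estimation averages active electrodes over the window", {
  # constant 1 Hz on all electrodes
  tr <- spike_train_set(setNames(lapply(1:4, function(e) seq(0.5, 59.5, 1)),
                                 paste0("E", 1:4)), 60)
  bl <- estimate_baseline(tr, 60)
  expect_equal(unname(bl$rates), rep(1, 4))
  expect_equal(bl$well_rate, 1)

  # silent well: baseline zero and trigger disabled
  tr0 <- spike_train_set(setNames(rep(list(numeric(0)), 4), paste0("E", 1:4)), 60)
  bl0 <- estimate_baseline(tr0, 60)
  expect_equal(bl0$well_rate, 0)
  expect_warning(
    trig <- evaluate_trigger(setNames(rep(10, 4), paste0("E", 1:4)),
                             bl0$rates, trigger_rule(min_active_electrodes = 2)),
    "zero baseline")
  expect_false(as.logical(trig))

  expect_error(estimate_baseline(tr, 60, t_ref = 2), "5 s")

  # Poisson rates concentrate near the true rate
  set.seed(10)
  errs <- replicate(100, {
    tr <- poisson_trains(1, 1, 60, sample.int(1e6, 1))
    abs(estimate_baseline(tr, 60)$rates[[1]] - 1)
  })
  expect_gte(mean(errs <= 0.4), 0.95)
})

test_that("the trigger gates on electrode count and fold increase", {
  rule <- trigger_rule()
  mk <- function(rates) setNames(rates, paste0("E", seq_along(rates)))
  base <- mk(rep(1, 16))

  # 12 of 16 active at exactly 2x the mean baseline: boundary, fires
  cur <- mk(rep(2, 16))
  expect_true(as.logical(evaluate_trigger(cur, base, rule)))

  # only 7 active electrodes, however strong: no trigger
  base7 <- mk(c(rep(1, 7), rep(0, 9)))
  cur7 <- mk(c(rep(10, 7), rep(0, 9)))
  expect_false(as.logical(evaluate_trigger(cur7, base7, rule)))

  # 16 active at 1.9x: below the fold gate
  expect_false(as.logical(evaluate_trigger(mk(rep(1.9, 16)), base, rule)))

  expect_error(evaluate_trigger(mk(rep(1, 3)), mk(rep(1, 4)), rule), "match")
  expect_error(trigger_rule(min_fold_increase = -1), "positive")
})

test_that("the controller logs every window and follows the state machine", {
  st <- make_stim_schedule(1, 0.01, 60, 90)
  # deterministic strong response on 12 of 16 electrodes
  trains <- lapply(1:16, function(e) {
    base <- seq(0.25, 119, by = 1) + e * 0.01
    if (e <= 12) sort(c(base, seq(60, 89.9, by = 0.25) + e * 0.003)) else base
  })
  names(trains) <- paste0("E", 1:16)
  tr <- spike_train_set(trains, 120)
  cl <- run_controller(tr, st, trigger_rule())

  expect_equal(nrow(cl$log), 120L)           # floor(duration / window)
  expect_equal(sum(cl$commands$command == "AVOID"), 1L)
  expect_equal(sum(cl$commands$command == "RESUME"), 1L)
  # avoidance only during the stimulation epoch, resume after it
  t_avoid <- cl$commands$time[cl$commands$command == "AVOID"]
  expect_true(t_avoid > 60 && t_avoid <= 91)
  expect_gt(cl$commands$time[cl$commands$command == "RESUME"], 90)
  # no command is ever emitted while the trigger is false
  expect_true(all(cl$log$trigger[!is.na(cl$log$command) &
                                 cl$log$command == "AVOID"]))
  # states are confined to the defined set and alternate legally
  expect_true(all(cl$log$state %in% c("FORWARD", "AVOID")))
})

test_that("null recordings never trigger and stronger modulation triggers more", {
  st <- make_stim_schedule(1, 0.01, 60, 90)
  count_trials <- function(mult, seeds) {
    sum(vapply(seeds, function(s) {
      sim <- simulate_mea_recording(16, 20000, 120, baseline_rate = 1,
                                    evoked_multiplier = mult, stim = st,
                                    responding_electrodes = 1:12, seed = s,
                                    render = FALSE)
      tr <- spike_train_set(sim$ground_truth$spike_times, 120)
      cl <- run_controller(tr, st, trigger_rule())
      sum(cl$commands$command == "AVOID") > 0
    }, logical(1)))
  }
  seeds <- 1:12
  n1 <- count_trials(1, seeds)
  n15 <- count_trials(1.5, seeds)
  n2 <- count_trials(2, seeds)
  n3 <- count_trials(3, seeds)
  expect_equal(n1, 0L)
  expect_true(n1 <= n15 && n15 <= n2 && n2 <= n3)
  expect_equal(n3, length(seeds))
})
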