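test_that("activation maps recover the chain fixture delays", {
  st <- stim_schedule(1.0, 0.01)
  sim <- simulate_calcium_movie(chain_network(), st, 30, 10, noise_sd = 0,
                                seed = 1)
  am <- activation_map(sim$movie, active_pixel_mask(sim$movie, 5), 1.0)
  med <- vapply(1:3, function(i)
    stats::median(am$T[sim$ground_truth$cell_pixel_masks[[i]]], na.rm = TRUE),
    numeric(1))
  expect_true(all(abs(med - c(0, 0.5, 1.0)) <= 1 / 30))
})

test_that("activation maps match ground truth on noiseless wave simulations", {
  st <- stim_schedule(1.0, 0.01)
  net <- generate_network(30, c(64, 64), mean_degree = 3, seed = 7)
  sim <- simulate_calcium_movie(net, st, 30, 20, noise_sd = 0, seed = 3)
  gt <- sim$ground_truth
  am <- activation_map(sim$movie, active_pixel_mask(sim$movie, 5), 1.0)
  errs <- unlist(lapply(seq_along(gt$activation_time), function(i) {
    if (is.na(gt$activation_time[i])) return(NULL)
    am$T[gt$cell_pixel_masks[[i]]] - (gt$activation_time[i] - 1.0)
  }))
  expect_gte(mean(abs(errs) <= 2 / 30 + 1e-9, na.rm = TRUE), 0.99)

  # T increases with shortest-path delay from the stimulated cell
  act <- gt$activation_time
  medT <- vapply(seq_along(act), function(i)
    stats::median(am$T[gt$cell_pixel_masks[[i]]], na.rm = TRUE), numeric(1))
  ok <- !is.na(act) & !is.na(medT)
  expect_gte(stats::cor(act[ok], medT[ok], method = "spearman"), 0.99)
})

test_that("map edge cases behave by contract", {
  st <- stim_schedule(1.0, 0.01)
  sim <- simulate_calcium_movie(chain_network(), st, 30, 10, noise_sd = 0,
                                seed = 1)
  allfalse <- matrix(FALSE, 40, 40)
  am <- activation_map(sim$movie, allfalse, 1.0)
  expect_true(all(is.na(am$T)))
  expect_error(activation_map(sim$movie, matrix(TRUE, 3, 3), 1.0), "shape")
  expect_error(activation_map(sim$movie, allfalse, 99), "stim_time")

  # events before the stimulus are rejected and counted
  am2 <- activation_map(sim$movie, active_pixel_mask(sim$movie, 5), 2.6)
  expect_true(all(is.na(am2$T) | am2$T >= 0))
  expect_gt(attr(am2, "n_pre_stimulus"), 0)
})

test_that("spike-count maps count repeated activations per pixel", {
  st <- stim_schedule(3.0, 0.01)
  net <- generate_network(5, c(48, 48), mean_degree = 2, seed = 9)
  sim <- simulate_calcium_movie(net, st, 30, 25, noise_sd = 0, seed = 1,
                                extra_spikes = list("3" = c(10, 17)))
  gt <- sim$ground_truth
  mask <- active_pixel_mask(sim$movie, 5)
  scm <- spike_count_map(sim$movie, mask)
  # the thrice-firing cell is flagged in multi_mask
  px3 <- gt$cell_pixel_masks[[3]]
  expect_equal(unname(stats::median(scm$counts[px3])), 3)
  expect_true(all(scm$multi_mask[px3][scm$counts[px3] > 1]))
  # single-event cells are not multi
  for (i in seq_along(gt$spike_times)) {
    if (length(gt$spike_times[[i]]) == 1) {
      expect_true(all(scm$counts[gt$cell_pixel_masks[[i]]] <= 1))
    }
  }
  # unmasked pixels have zero counts by contract
  expect_true(all(scm$counts[!mask$mask] == 0))
  expect_equal(scm$multi_mask, scm$counts > 1)
})
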