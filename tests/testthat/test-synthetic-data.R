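test_that("stimulation schedules follow the periodic contract", {
  expect_equal(make_stim_schedule(1, 0.010, 0, 5)$pulse_times, c(0, 1, 2, 3, 4))
  expect_equal(make_stim_schedule(2, 0.010, 0, 1)$pulse_times, c(0, 0.5))
  expect_error(make_stim_schedule(1, 0.01, 5, 5), "t_end")
  expect_error(make_stim_schedule(10, 0.2, 0, 1), "duty")
  expect_error(stim_schedule(c(1, 0.5), 0.01), "ascending")
})

test_that("network generation is deterministic and honours its contracts", {
  n1 <- generate_network(1, c(32, 32), mean_degree = 0, seed = 5)
  expect_equal(nrow(n1$cell_positions), 1L)
  expect_false(any(n1$adjacency))
  expect_equal(n1$stimulated_cell, 1L)

  a <- generate_network(40, c(96, 96), mean_degree = 4, seed = 11)
  b <- generate_network(40, c(96, 96), mean_degree = 4, seed = 11)
  expect_identical(a, b)
  expect_true(all(diag(a$adjacency) == FALSE))
  expect_true(all(a$conduction_delay[a$adjacency] > 0))
  expect_true(all(a$cell_positions[, 1] > 0 &
                  a$cell_positions[, 1] < a$field_shape[1]))

  # realised mean degree close to requested
  degs <- sapply(1:6, function(s) {
    g <- generate_network(50, c(128, 128), mean_degree = 4, seed = s)
    mean(rowSums(g$adjacency))
  })
  expect_true(all(abs(degs - 4) <= 1.5))

  expect_error(generate_network(5, c(32, 32), delay_range = c(-1, 1)), "delay")
  expect_error(generate_network(5, c(3, 3)), "degenerate")
})

test_that("calcium simulation renders the propagation wave it reports", {
  st <- stim_schedule(1.0, 0.01)
  # chain with forced delays: activation times 1.0, 1.5, 2.0 s
  sim <- simulate_calcium_movie(chain_network(), st, frame_rate = 30,
                                duration = 8, noise_sd = 0, seed = 1)
  expect_equal(sim$ground_truth$activation_time, c(1.0, 1.5, 2.0))

  # single isolated cell, noiseless: one transient starting at the pulse
  n1 <- generate_network(1, c(32, 32), mean_degree = 0, seed = 2)
  s1 <- simulate_calcium_movie(n1, st, frame_rate = 30, duration = 6,
                               noise_sd = 0, seed = 1)
  px <- s1$ground_truth$cell_pixel_masks[[1]][1]
  X <- s1$movie$data; dim(X) <- c(dim(X)[1], prod(dim(X)[2:3]))
  tr <- X[, px]
  onset_frame <- which(tr > tr[1])[1] - 1L  # 0-based first supra-baseline frame
  expect_lte(abs(onset_frame - round(1.0 * 30)), 1)
  expect_equal(length(s1$ground_truth$spike_times[[1]]), 1L)

  # determinism
  s2 <- simulate_calcium_movie(n1, st, frame_rate = 30, duration = 6,
                               noise_sd = 0.3, seed = 9)
  s3 <- simulate_calcium_movie(n1, st, frame_rate = 30, duration = 6,
                               noise_sd = 0.3, seed = 9)
  expect_identical(s2$movie$data, s3$movie$data)

  # truncation warning when the wave outruns the movie
  expect_warning(
    simulate_calcium_movie(chain_network(), st, 30, 2, noise_sd = 0),
    "truncated")
})

test_that("wave causality holds along shortest paths", {
  st <- stim_schedule(0.5, 0.01)
  for (s in 1:5) {
    net <- generate_network(20, c(72, 72), mean_degree = 3, seed = s)
    sim <- simulate_calcium_movie(net, st, 30, 30, noise_sd = 0, seed = s)
    act <- sim$ground_truth$activation_time
    stimc <- net$stimulated_cell
    expect_equal(act[stimc], 0.5)
    # every edge (i, j): activation(j) <= activation(i) + delay(i, j)
    edges <- which(net$adjacency, arr.ind = TRUE)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      if (!is.na(act[i]) && !is.na(act[j]))
        expect_lte(act[j], act[i] + net$conduction_delay[i, j] + 1e-9)
    }
  }
})

test_that("rendered transients match ground-truth spike counts", {
  st <- stim_schedule(1.0, 0.01)
  net <- generate_network(6, c(48, 48), mean_degree = 2, seed = 3)
  sim <- simulate_calcium_movie(net, st, 30, 25, noise_sd = 0, seed = 1,
                                extra_spikes = list("2" = c(8, 15)))
  gt <- sim$ground_truth
  scm <- spike_count_map(sim$movie, active_pixel_mask(sim$movie, 5))
  for (i in seq_along(gt$spike_times)) {
    px <- gt$cell_pixel_masks[[i]]
    expect_equal(unname(stats::median(scm$counts[px])),
                 length(gt$spike_times[[i]]), info = paste("cell", i))
  }
})

test_that("MEA simulation obeys its rate law and refractory contract", {
  # silent network
  s0 <- simulate_mea_recording(2, 20000, 5, baseline_rate = 0, stim = NULL,
                               seed = 1)
  expect_equal(sum(lengths(s0$ground_truth$spike_times)), 0L)
  expect_equal(dim(s0$recording$raw), c(2L, 100000L))

  # evoked/baseline rate ratio ~ multiplier (ground-truth spike counts)
  st <- make_stim_schedule(1, 0.01, 10, 50)
  sim <- simulate_mea_recording(16, 20000, 60, baseline_rate = 1,
                                evoked_multiplier = 3, stim = st,
                                seed = 4, render = FALSE)
  gt <- sim$ground_truth
  inw <- 0; inl <- 0; outw <- 0; outl <- 0
  for (e in 1:16) {
    w <- gt$evoked_windows[[e]]
    t <- gt$spike_times[[e]]
    if (nrow(w)) {
      inside <- findInterval(t, as.vector(t(w))) %% 2 == 1
      len <- sum(w[, 2] - w[, 1])
      inw <- inw + sum(inside); inl <- inl + len
      outw <- outw + sum(!inside); outl <- outl + (60 - len)
    }
  }
  ratio <- (inw / inl) / (outw / outl)
  expect_true(abs(ratio - 3) <= 0.5)

  # refractory period enforced in ground truth
  isis <- unlist(lapply(gt$spike_times, function(t) diff(t)))
  expect_true(all(isis >= 0.0025))

  # determinism
  a <- simulate_mea_recording(2, 20000, 3, baseline_rate = 2, stim = NULL, seed = 7)
  b <- simulate_mea_recording(2, 20000, 3, baseline_rate = 2, stim = NULL, seed = 7)
  expect_identical(a$recording$raw, b$recording$raw)

  expect_error(simulate_mea_recording(2, 20000, 3, evoked_multiplier = -1),
               "evoked_multiplier")
})

test_that("a unit multiplier leaves stimulation windows at baseline rate", {
  # two-sided Poisson rate test between in-window and matched baseline counts
  st <- make_stim_schedule(1, 0.01, 20, 220)
  sim <- simulate_mea_recording(1, 20000, 440, baseline_rate = 4,
                                evoked_multiplier = 1, stim = st,
                                seed = 8, render = FALSE)
  t <- sim$ground_truth$spike_times[[1]]
  n_stim <- sum(t >= 20 & t < 220)
  n_base <- sum(t >= 220 & t < 420)
  p <- stats::poisson.test(c(n_stim, n_base), c(200, 200))$p.value
  expect_gt(p, 0.01)
})

test_that("the long-run evoked/baseline ratio converges to the multiplier", {
  st <- stim_schedule(seq(50, 549), 0.01)
  sim <- simulate_mea_recording(4, 20000, 600, baseline_rate = 1,
                                evoked_multiplier = 3, stim = st,
                                seed = 12, render = FALSE)
  gt <- sim$ground_truth
  rin <- 0; lin <- 0; rout <- 0; lout <- 0
  for (e in 1:4) {
    w <- gt$evoked_windows[[e]]; t <- gt$spike_times[[e]]
    inside <- findInterval(t, as.vector(t(w))) %% 2 == 1
    len <- sum(w[, 2] - w[, 1])
    rin <- rin + sum(inside); lin <- lin + len
    rout <- rout + sum(!inside); lout <- lout + 600 - len
  }
  ratio <- (rin / lin) / (rout / lout)
  expect_true(abs(ratio - 3) / 3 <= 0.10)
})
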