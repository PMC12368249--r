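test_that("STTC satisfies its analytic identities", {
  a <- c(1, 2.5, 4, 7)
  expect_equal(sttc(a, a, 0.02, 10), 1)
  expect_true(is.na(sttc(numeric(0), a, 0.02, 10)))
  expect_error(sttc(a, a, -0.1, 10), "dt")
  expect_error(sttc(a, a, 6, 10), "T")
  # symmetry
  set.seed(71)
  b <- random_train(6, 10)
  expect_equal(sttc(a, b, 0.05, 10), sttc(b, a, 0.05, 10))
})

test_that("STTC equals the hand-evaluated tiling formula on a small case", {
  a <- c(1, 5); b <- c(1.01, 9); T <- 10; dt <- 0.05
  # literal evaluation: P_A = 1/2 (only a=1 is within dt of b), P_B = 1/2,
  # T_A = 0.2/10, T_B = 0.2/10
  PA <- 0.5; PB <- 0.5; TA <- 0.02; TB <- 0.02
  want <- 0.5 * ((PA - TB) / (1 - PA * TB) + (PB - TA) / (1 - PB * TA))
  expect_equal(sttc(a, b, dt, T), want, tolerance = 1e-12)
  expect_equal(brute_sttc(a, b, dt, T), want, tolerance = 1e-12)
})

test_that("STTC matches the brute-force computation on random cases", {
  set.seed(72)
  for (i in 1:1000) {
    T <- stats::runif(1, 1, 10)
    a <- random_train(sample(1:12, 1), T)
    b <- random_train(sample(1:12, 1), T)
    dt <- stats::runif(1, 0.01, 0.3)
    if (2 * dt >= T) next
    expect_equal(sttc(a, b, dt, T), brute_sttc(a, b, dt, T),
                 tolerance = 1e-10, info = paste("case", i))
  }
})

test_that("STTC is invariant to a common time shift", {
  set.seed(73)
  for (i in 1:50) {
    a <- random_train(10, 5) + 1
    b <- random_train(8, 5) + 1
    s0 <- sttc(a, b, 0.05, 11)
    s1 <- sttc(a + 1.5, b + 1.5, 0.05, 11)  # shifted, window margins kept
    expect_equal(s0, s1, tolerance = 1e-10)
  }
})

test_that("independent Poisson trains have near-zero mean STTC", {
  set.seed(74)
  vals <- replicate(100, {
    a <- random_train(stats::rpois(1, 600), 600)
    b <- random_train(stats::rpois(1, 600), 600)
    sttc(a, b, 0.02, 600)
  })
  expect_lte(abs(mean(vals)), 0.02)
})

test_that("the STTC matrix is symmetric with unit diagonal over active electrodes", {
  set.seed(75)
  trains <- list(E1 = random_train(100, 60), E2 = random_train(80, 60),
                 E3 = random_train(120, 60), E4 = random_train(2, 60))
  sm <- sttc_matrix(spike_train_set(trains, 60))
  expect_setequal(sm$electrodes, c("E1", "E2", "E3"))  # E4 below 5/min
  expect_equal(sm$sttc, t(sm$sttc))
  expect_equal(unname(diag(sm$sttc)), rep(1, 3))
})

test_that("the synchrony index separates locked from independent firing", {
  set.seed(76)
  # identical sparse trains: all correlogram mass at lag zero
  a <- seq(0.5, 59.5, by = 2)            # spacing beyond the +-1 s support
  tr_same <- spike_train_set(list(E1 = a, E2 = a), 60)
  expect_equal(synchrony_index(tr_same)$well_raw, 1)

  # independent trains: raw index near the chance level window/support
  raws <- replicate(100, {
    x <- random_train(120, 60); y <- random_train(120, 60)
    synchrony_index(spike_train_set(list(E1 = x, E2 = y), 60))$well_raw
  })
  expect_lte(abs(mean(raws) - 0.02), 0.005)

  # tighter jitter scores higher than looser jitter
  wins <- replicate(50, {
    base <- random_train(150, 60) + 0.3
    jit <- function(sd) sort(pmin(60.9, pmax(0, base + rnorm(150, 0, sd))))
    j5 <- spike_train_set(list(a = base, b = jit(0.005)), 61)
    j50 <- spike_train_set(list(a = base, b = jit(0.05)), 61)
    synchrony_index(j5)$well_raw > synchrony_index(j50)$well_raw
  })
  expect_gte(mean(wins), 0.95)
})
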