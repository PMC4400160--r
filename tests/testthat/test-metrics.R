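test_that("vector strength matches its closed forms", {
  expect_equal(vector_strength(c(0, 50, 100, 150), 50), 1)
  # phases 0, 90, 180, 270 degrees cancel
  expect_equal(vector_strength(c(0, 12.5, 25, 37.5), 50), 0, tolerance = 1e-12)
  # phases 0 and 90 degrees: |(1 + i)/2| = sqrt(2)/2
  expect_equal(vector_strength(c(0, 12.5), 50), sqrt(2) / 2)
  expect_true(is.na(vector_strength(numeric(0), 50)))
  expect_error(vector_strength(1, 0))
})

test_that("vector strength equals the complex resultant oracle on random spikes", {
  for (case in 1:1000) {
    seed <- synchrate:::derive_seed_cpp(c(314, case))
    n <- 1 + (case %% 40)
    sp <- synchrate:::runif_seeded_cpp(n, 0, 500, seed)
    ipi <- c(3, 7.5, 20, 50, 75)[1 + (case %% 5)]
    oracle <- Mod(mean(exp(2i * pi * sp / ipi)))
    expect_equal(vector_strength(sp, ipi), oracle, tolerance = 1e-12)
  }
})

test_that("Rayleigh statistic arithmetic, cut, and shift invariance", {
  expect_equal(rayleigh_statistic(0, NA), 0)
  expect_equal(rayleigh_statistic(100, 0.5), 50)
  expect_equal(rayleigh_statistic(27, 0.5), 13.5) # just below the 13.8 cut
  expect_gt(rayleigh_statistic(28, 0.5), rayleigh_cut() - 0.0001)

  sp <- synchrate:::runif_seeded_cpp(30, 0, 500, 99)
  r0 <- rayleigh_statistic(30, vector_strength(sp, 25))
  r1 <- rayleigh_statistic(30, vector_strength(sp + 4 * 25, 25))
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("the 13.8 cut rejects uniform spiking at the 0.001 level (Monte Carlo)", {
  sig <- vapply(1:10000, function(s) {
    sp <- synchrate:::runif_seeded_cpp(20, 0, 500,
                                       synchrate:::derive_seed_cpp(c(77, s)))
    rayleigh_statistic(20, vector_strength(sp, 50)) > rayleigh_cut()
  }, logical(1))
  # nominal level 0.001; allow its ~99.9% binomial upper range
  expect_lt(mean(sig), 0.002)
})

test_that("evoked rate subtracts the spontaneous rate", {
  expect_equal(evoked_rate(10, 500, 1, 4), 16)
  expect_equal(evoked_rate(0, 500, 1, 4), -4)
  expect_equal(evoked_rate(2, 200, 1, 4), 6)
  expect_equal(evoked_rate(20, 500, 10, 0), 4)
})

test_that("discharge rate ratio handles its degenerate cases", {
  ipis <- c(3, 35, 55, 75)
  expect_equal(discharge_rate_ratio(c(20, 5, 2, 1), ipis), 4)
  expect_equal(discharge_rate_ratio(c(5, 5, 5, 5), ipis), 1)
  expect_equal(discharge_rate_ratio(c(10, -1, 0, -2), ipis), Inf)
  expect_true(is.na(discharge_rate_ratio(c(-1, -1, 0, -2), ipis)))
  expect_error(discharge_rate_ratio(c(1, 2), c(5, 50)), "IPI 3")
})

test_that("onset/sustained ratio separates onset from sustained responses", {
  expect_equal(onset_sustained_ratio(c(5, 20, 45)), 1)
  expect_equal(onset_sustained_ratio(seq(0.5, 199.5, by = 1)), 0.25)
  expect_equal(onset_sustained_ratio(c(runif(5, 0, 49), runif(15, 51, 199))),
               0.25)
  expect_true(is.na(onset_sustained_ratio(numeric(0))))
  expect_equal(onset_sustained_ratio(c(60, 80, 150, 199), onset_window = 100),
               0.5)
})

test_that("sync limit applies the neighbour-continuity rule", {
  ipis <- default_ipis()
  ray <- ifelse(ipis >= 10, 20, 1)
  expect_equal(sync_limit(ipis, ray), 10)
  expect_true(is.na(sync_limit(ipis, rep(1, 18))))
  # isolated significant IPI does not define the limit
  ray2 <- rep(1, 18); ray2[ipis == 20] <- 50
  expect_true(is.na(sync_limit(ipis, ray2)))
  # the longest IPI qualifies on its own significance
  ray3 <- rep(1, 18); ray3[ipis == 75] <- 50
  expect_equal(sync_limit(ipis, ray3), 75)
})

test_that("max vector strength only considers significant IPIs", {
  expect_equal(max_vector_strength(c(0.9, 0.6), c(5, 20)), 0.6)
  expect_true(is.na(max_vector_strength(c(0.9, 0.6), c(5, 5))))
  expect_equal(max_vector_strength(c(0.3, 0.8, 0.5), c(20, 30, 40)), 0.8)
})

test_that("minimum latency finds the first sustained threshold crossing", {
  # 10 trials, spikes only in bins [4,6), [6,8), [8,10) ms after onset
  trials <- lapply(1:10, function(j) 200 + c(4.5, 5.2, 6.5, 7.1, 8.3))
  ts <- toy_trial_set(list(trials), ipis = 50, n_trials = 10,
                      spont_rate = 1, spont_sd = 1)
  expect_equal(minimum_latency(ts), 4)
  # all-silent response: undefined
  ts0 <- toy_trial_set(list(lapply(1:10, function(j) numeric(0))),
                       ipis = 50, n_trials = 10, spont_rate = 1, spont_sd = 1)
  expect_true(is.na(minimum_latency(ts0)))
})

test_that("compute_metrics assembles per-IPI and summary statistics", {
  # perfectly locked toy neuron: one spike per pulse, plus a tone onset burst
  ipis <- c(3, 35, 75)
  conds <- lapply(ipis, function(ipi) {
    on <- 200 + pulse_onsets(ipi, 500) + 12
    lapply(1:5, function(j) on)
  })
  tone <- lapply(1:5, function(j) 200 + c(12, 15, 20, 30, 160))
  ts <- toy_trial_set(conds, ipis, 5, spont_rate = 0, spont_sd = 0,
                      tone_spikes = tone)
  m <- compute_metrics(ts)
  expect_s3_class(m, "response_metrics")
  expect_equal(m$per_ipi$vs, rep(1, 3), tolerance = 1e-9)
  expect_true(all(m$per_ipi$significant))
  expect_equal(m$rayleigh_75, 2 * (7 * 5) * 1, tolerance = 1e-9)
  # IPI 3 ms: pulses whose spike (onset + 12 ms) stays inside the 500 ms
  # window: onsets 0..486, i.e. 163 spikes/trial over 0.5 s
  expect_equal(m$per_ipi$rate[1], 163 / 0.5)
  # IPI 35 ms: onsets 0..455 qualify, 14 spikes/trial
  expect_equal(m$discharge_rate_ratio, 326 / 28)
  expect_equal(m$tone_rate, 25)
  expect_equal(m$onset_sustained, 0.8)
  expect_equal(m$onset_sustained_100, 0.8)
  expect_equal(m$sync_limit, 3)
  expect_equal(m$max_vs, 1, tolerance = 1e-9)
})

test_that("metrics are deterministic functions of the trial set", {
  ts <- sim_cell(3, 1.5, 5, n_trials = 3, ipis = c(3, 50, 75))
  m1 <- compute_metrics(ts)
  m2 <- compute_metrics(ts)
  expect_identical(m1, m2)
})
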