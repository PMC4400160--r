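test_that("alpha kernel matches its closed form", {
  expect_equal(alpha_kernel(0, 2, 5), 0)
  expect_equal(alpha_kernel(5, 2, 5), 2)          # peak at t = tau
  expect_equal(alpha_kernel(10, 2, 5), 2 * 2 * exp(-1)) # t = 2 tau
  expect_equal(alpha_kernel(-1, 2, 5), 0)         # causal

  t <- seq(0, 50, by = 0.01)
  g <- alpha_kernel(t, 3.7, 5)
  expect_equal(t[which.max(g)], 5)
  expect_equal(max(g), 3.7)

  expect_error(alpha_kernel(1, 1, 0), "tau")
  expect_error(alpha_kernel(1, -1, 5), "amplitude")
})

test_that("pulse onsets tile the stimulus duration", {
  expect_equal(pulse_onsets(50, 500), seq(0, 450, by = 50))
  expect_length(pulse_onsets(75, 500), 7)
  expect_length(pulse_onsets(3, 500), 167)
  expect_true(all(pulse_onsets(7.5, 500) < 500))
})

test_that("parameter constructors validate their ranges", {
  expect_error(synapse_params(0), "e_strength")
  expect_error(synapse_params(1, ie_ratio = -0.5))
  expect_error(synapse_params(1, nmda_weights = c(0.5, 0.4)), "sum to 1")
  expect_error(stimulus_spec("pulse_train"), "ipi")
  s <- stimulus_spec("pulse_train", ipi = 75)
  expect_equal(s$duration, 500)
  expect_equal(s$trial_length, 1000)
  expect_equal(stimulus_spec("pure_tone")$duration, 200)
})

test_that("zero-jitter pulse rendering sums kernels to the expected peak", {
  syn <- synapse_params(3, ie_ratio = 0.5, ie_delay = 4, jitter_sd = 0)
  stim <- stimulus_spec("pulse_train", ipi = 400, duration = 300, onset = 100,
                        trial_length = 600)
  tr <- render_pulse_train(stim, syn, seed = 1)
  tgrid <- (seq_along(tr$g_e) - 1) * tr$dt
  # 10 coincident inputs, each peak e_strength: summed peak 10 * 3 at
  # onset + conduction delay + tau
  expect_equal(max(tr$g_e), 10 * 3, tolerance = 1e-9)
  expect_equal(tgrid[which.max(tr$g_e)], 100 + 10 + 5)
  expect_equal(max(tr$g_i), 0.5 * 10 * 3, tolerance = 1e-9)
  expect_equal(tgrid[which.max(tr$g_i)], 100 + 10 + 4 + 5)

  # the "summed" amplitude convention divides the per-input peak by n_inputs
  syn2 <- synapse_params(3, ie_ratio = 0, jitter_sd = 0,
                         amplitude_convention = "summed")
  tr2 <- render_pulse_train(stim, syn2, seed = 1)
  expect_equal(max(tr2$g_e), 3, tolerance = 1e-9)
})

test_that("rendered conductances are finite, non-negative and reproducible", {
  syn <- synapse_params(2, ie_ratio = 1.5, ie_delay = -2)
  stim <- stimulus_spec("pulse_train", ipi = 10)
  a <- render_pulse_train(stim, syn, seed = 42)
  b <- render_pulse_train(stim, syn, seed = 42)
  expect_identical(a, b)
  expect_true(all(is.finite(a$g_e)) && all(a$g_e >= 0))
  expect_true(all(is.finite(a$g_i)) && all(a$g_i >= 0))
  c <- render_pulse_train(stim, syn, seed = 43)
  expect_false(identical(a$g_e, c$g_e))

  syn0 <- synapse_params(2, ie_ratio = 0)
  expect_true(all(render_pulse_train(stim, syn0, seed = 1)$g_i == 0))
})

test_that("kernel mass per pulse scales linearly with excitatory strength", {
  stim <- stimulus_spec("pulse_train", ipi = 400, duration = 300)
  es <- c(0.5, 1, 2, 4)
  mass <- vapply(es, function(e) {
    syn <- synapse_params(e, ie_ratio = 0)
    sum(render_pulse_train(stim, syn, seed = 9)$g_e)
  }, numeric(1))
  expect_equal(mass / mass[1], es / es[1], tolerance = 1e-6)
})

test_that("per-pulse peak converges to the zero-jitter peak as jitter shrinks", {
  stim <- stimulus_spec("pulse_train", ipi = 400, duration = 300)
  peak <- vapply(c(1, 0.1, 0.01), function(sd) {
    syn <- synapse_params(2, ie_ratio = 0, jitter_sd = sd)
    max(render_pulse_train(stim, syn, seed = 5)$g_e)
  }, numeric(1))
  target <- 10 * 2
  err <- abs(peak - target)
  expect_true(all(diff(err) < 0))       # monotone convergence
  expect_lt(err[3] / target, 0.001)
})

test_that("rendering is linear over unions of pulse trains", {
  # same per-pulse seeds: a two-pulse train equals the sum of two one-pulse
  # renders placed at the component onsets
  syn <- synapse_params(2, ie_ratio = 1, ie_delay = 3, jitter_sd = 0)
  len <- 800
  one <- function(onset) {
    stim <- stimulus_spec("pulse_train", ipi = 900, duration = 100,
                          onset = onset, trial_length = len)
    render_pulse_train(stim, syn, seed = 11)
  }
  both <- stimulus_spec("pulse_train", ipi = 200, duration = 300,
                        onset = 100, trial_length = len)
  tr <- render_pulse_train(both, syn, seed = 11)
  expect_equal(tr$g_e, one(100)$g_e + one(300)$g_e, tolerance = 1e-10)
})

test_that("pure tones rise after the conduction delay and plateau at the drive", {
  syn <- synapse_params(3, ie_ratio = 0.8, ie_delay = 2, jitter_sd = 0)
  stim <- stimulus_spec("pure_tone")
  tr <- render_pure_tone(stim, syn, seed = 1)
  tgrid <- (seq_along(tr$g_e) - 1) * tr$dt
  expect_true(all(tr$g_e[tgrid < 200 + 10] == 0))  # causal up to onset + delay
  drive <- 10 * 3
  plateau <- tr$g_e[tgrid >= 300 & tgrid <= 380]
  expect_lt(max(abs(plateau - drive)) / drive, 1e-5)
  expect_equal(max(tr$g_i), 0.8 * drive, tolerance = 1e-4)
  # decays back toward zero within ~5 tau of tone offset + delay
  expect_lt(tr$g_e[[which.min(abs(tgrid - 450))]], 0.05 * drive)
})
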