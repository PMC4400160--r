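mini_ipis <- c(3, 5, 35, 50, 75) # keeps ratio/sync statistics defined

test_that("grid sweeps are reproducible and record every cell", {
  g <- sweep_grid(ie_delay = c(0, 5), ie_ratio = c(0.5, 1.5),
                  e_strength = c(1.2, 3), n_trials = 3, base_seed = 7)
  r1 <- run_grid(g, ipis = mini_ipis)
  r2 <- run_grid(g, ipis = mini_ipis)
  expect_equal(nrow(r1), 8)
  expect_identical(r1, r2)
  expect_true(all(is.na(r1$error)))
  expect_equal(r1$net_excitation, r1$e_strength * (1 - r1$ie_ratio))
  # a different seed changes the stochastic outcome
  g2 <- g; g2$base_seed <- 8
  expect_false(identical(run_grid(g2, ipis = mini_ipis)$rayleigh_75,
                         r1$rayleigh_75))
})

test_that("reclassification under a lower ceiling only excludes cells", {
  g <- sweep_grid(ie_delay = c(0, 3), ie_ratio = c(0.6, 1, 1.6),
                  e_strength = c(1.8, 3.6), n_trials = 3, base_seed = 3)
  res <- run_grid(g, ipis = mini_ipis)
  r20 <- reclassify(res, max_tone_rate = 20)
  moved <- res$label != r20$label
  expect_true(all(r20$label[moved] == "excluded_high"))
  expect_s3_class(r20, "sweep_result")
})

test_that("spontaneous rate grows monotonically with the noise amplitude", {
  cal <- calibrate_spont(c(3e-8, 4.5e-8, 6e-8), total_s = 15, base_seed = 5)
  expect_true(all(diff(cal$rate) > 0))
  expect_gt(cal$rate[3], cal$rate[1])
})

test_that("correlations recover monotone and anti-monotone synthetic inputs", {
  syn <- data.frame(ie_delay = 5, ie_ratio = 2,
                    e_strength = seq(0.3, 6, by = 0.3))
  syn$net_excitation <- syn$e_strength * (1 - syn$ie_ratio)
  syn$rayleigh_75 <- syn$e_strength          # perfectly monotone
  syn$discharge_rate_ratio <- 0.5
  syn$label <- "synchronized"; syn$error <- NA_character_
  class(syn) <- c("sweep_result", "data.frame")
  expect_equal(correlate_sync(syn), 1)

  ns <- syn
  ns$ie_delay <- 0
  ns$label <- "non_synchronized"
  ns$discharge_rate_ratio <- -ns$net_excitation  # anti-monotone
  expect_equal(as.numeric(correlate_nonsync(ns)), -1)
  # infinite sentinels are excluded from the ranking and counted
  ns$discharge_rate_ratio[1] <- Inf
  r <- correlate_nonsync(ns)
  expect_equal(attr(r, "n_excluded"), 1)
  expect_error(correlate_sync(syn[1:3, ]), "need >=")
})

test_that("population comparisons report group means and rank-sum p-values", {
  df <- data.frame(ie_delay = 0, ie_ratio = 1,
                   e_strength = rep(c(2, 4), times = 30),
                   min_latency = c(rnorm(30, 10, 1), rnorm(30, 17, 1)),
                   label = rep(c("synchronized", "non_synchronized"), each = 30),
                   error = NA_character_)
  class(df) <- c("sweep_result", "data.frame")
  pc <- population_compare(df, "min_latency",
                           groups = c("synchronized", "non_synchronized"))
  expect_equal(unname(pc$n), c(30L, 30L))
  expect_lt(pc$means["synchronized"], pc$means["non_synchronized"])
  expect_lt(pc$p_values$p, 1e-6)
  pcr <- population_compare(df, "min_latency",
                            groups = c("synchronized", "non_synchronized"),
                            restrict_e = c(3, 6))
  expect_equal(unname(pcr$n), c(15L, 15L)) # only the 4 nS cells remain
  expect_error(population_compare(df, "min_latency",
                                  groups = c("synchronized", "mixed")),
               "at least one")
})

test_that("single-sigma invariance is trivial; labels drive the fractions", {
  g <- sweep_grid(ie_delay = c(0, 5), ie_ratio = c(1, 2),
                  e_strength = c(1.8, 3.6), n_trials = 3, base_seed = 2)
  res <- run_grid(g, ipis = mini_ipis)
  inv <- invariance_analysis(g, sigmas = 4e-8, ref_result = res)
  keep <- res$label %in% c("synchronized", "non_synchronized", "mixed")
  expect_equal(inv$per_cell$invariant, keep)
  for (lb in c("synchronized", "non_synchronized", "mixed")) {
    if (any(res$label == lb)) expect_equal(unname(inv$fractions[lb]), 1)
  }
})

test_that("removing internal noise nearly eliminates non-synchronized cells", {
  # full IPI battery on a subgrid spanning the parameter ranges evenly;
  # sparse IPI sets misestimate the discharge rate ratio
  g_off <- sweep_grid(ie_delay = c(0, 2, 5), ie_ratio = seq(0, 2, by = 0.4),
                      e_strength = c(0.6, 1.8, 3, 4.2, 6), n_trials = 4,
                      base_seed = 9, noise = noise_spec("none"))
  off <- run_grid(g_off)
  inc <- off$label %in% c("synchronized", "non_synchronized", "mixed",
                          "atypical")
  expect_lt(sum(off$label == "non_synchronized") / max(1, sum(inc)), 0.05)

  # wide uniform input jitter alone restores non-synchronized responses
  g_jit <- g_off; g_jit$noise <- noise_spec("jitter_only")
  jit <- run_grid(g_jit)
  inc_j <- jit$label %in% c("synchronized", "non_synchronized", "mixed",
                            "atypical")
  expect_gt(sum(jit$label == "non_synchronized") / sum(inc_j), 0.1)
})

test_that("NMDA kernels lengthen the synchronization limit", {
  dense_ipis <- c(3, 5, 7.5, 10, 12.5, 15, 20, 25, 35, 75)
  g_ampa <- sweep_grid(ie_delay = 5, ie_ratio = c(1.6, 2),
                       e_strength = c(3, 4.5, 6), n_trials = 4, base_seed = 4)
  g_nmda <- g_ampa; g_nmda$nmda <- TRUE
  ampa <- run_grid(g_ampa, ipis = dense_ipis)
  nmda <- run_grid(g_nmda, ipis = dense_ipis)
  sa <- sync_limit_summary(ampa)["synchronized"]
  sn <- sync_limit_summary(nmda)["synchronized"]
  expect_gt(sn, sa)
  # the flag off is a no-op: same seeds give the identical baseline
  g_same <- g_nmda; g_same$nmda <- FALSE
  expect_identical(run_grid(g_same, ipis = dense_ipis), ampa)
})
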