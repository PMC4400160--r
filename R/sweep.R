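#' Define a 3-D parameter grid for a sweep
#'
#' The grid spans the physiological ranges of the three synaptic parameters:
#' I-E delay -2..7 ms, I/E ratio 0..2, excitatory strength 0.3..6 nS. Step
#' sizes are configurable; the defaults give a 10 x 21 x 20 grid.
#'
#' @param ie_delay I-E delay values (ms).
#' @param ie_ratio I/E ratio values.
#' @param e_strength excitatory strengths (nS).
#' @param noise a [noise_spec()] shared by all cells.
#' @param n_trials trials per stimulus condition (default 10).
#' @param base_seed integer seed; every cell, condition and trial derives its
#'   own stream from it.
#' @param nmda enable the NMDA kernel variant for every cell.
#' @return an object of class \code{"sweep_grid"}.
#' @export
sweep_grid <- function(ie_delay = seq(-2, 7, by = 1),
                       ie_ratio = seq(0, 2, by = 0.1),
                       e_strength = seq(0.3, 6, by = 0.3),
                       noise = noise_spec(), n_trials = 10, base_seed = 1,
                       nmda = FALSE) {
  stopifnot(length(ie_delay) > 0, length(ie_ratio) > 0, length(e_strength) > 0,
            all(e_strength > 0), all(ie_ratio >= 0),
            inherits(noise, "noise_spec"), n_trials >= 1)
  cells <- expand.grid(ie_delay = ie_delay, ie_ratio = ie_ratio,
                       e_strength = e_strength, KEEP.OUT.ATTRS = FALSE)
  structure(list(cells = cells, noise = noise, n_trials = as.integer(n_trials),
                 base_seed = base_seed, nmda = isTRUE(nmda)),
            class = "sweep_grid")
}

#' Run a parameter-grid sweep
#'
#' Simulates the full stimulus battery (all IPIs plus the pure tone) for
#' every grid cell, computes the response metrics and classifies the coding
#' regime. Per-cell failures are recorded in the \code{error} column rather
#' than aborting the sweep.
#'
#' @param grid a [sweep_grid()].
#' @param params a [neuron_params()] object.
#' @param ipis IPIs to test (default [default_ipis()]).
#' @param progress print a progress line every 100 cells.
#' @return a \code{"sweep_result"} data frame with one row per cell:
#'   parameters, \code{net_excitation} (= e_strength * (1 - ie_ratio)), the
#'   summary metrics and the \code{label}.
#' @export
run_grid <- function(grid, params = neuron_params(), ipis = default_ipis(),
                     progress = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- grid$cells
  n <- nrow(cells)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      syn <- synapse_params(e_strength = cells$e_strength[i],
                            ie_ratio = cells$ie_ratio[i],
                            ie_delay = cells$ie_delay[i],
                            nmda = grid$nmda)
      cell_seed <- derive_seed_cpp(c(grid$base_seed,
                                     round(cells$ie_delay[i] * 100),
                                     round(cells$ie_ratio[i] * 100),
                                     round(cells$e_strength[i] * 100)))
      ts <- simulate_trial_set(syn, params, grid$noise, ipis = ipis,
                               n_trials = grid$n_trials, base_seed = cell_seed)
      m <- compute_metrics(ts)
      cl <- classify(m)
      data.frame(ie_delay = cells$ie_delay[i], ie_ratio = cells$ie_ratio[i],
                 e_strength = cells$e_strength[i],
                 net_excitation = cells$e_strength[i] * (1 - cells$ie_ratio[i]),
                 spont_rate = m$spont_rate,
                 tone_rate = m$tone_rate,
                 onset_sustained = m$onset_sustained,
                 onset_sustained_100 = m$onset_sustained_100,
                 rayleigh_75 = m$rayleigh_75, vs_75 = m$vs_75,
                 discharge_rate_ratio = m$discharge_rate_ratio,
                 min_latency = m$min_latency, max_vs = m$max_vs,
                 sync_limit = m$sync_limit,
                 sync_criterion = cl$flags$sync_criterion,
                 rate_criterion = cl$flags$rate_criterion,
                 label = cl$label, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(ie_delay = cells$ie_delay[i], ie_ratio = cells$ie_ratio[i],
                 e_strength = cells$e_strength[i],
                 net_excitation = cells$e_strength[i] * (1 - cells$ie_ratio[i]),
                 spont_rate = NA_real_, tone_rate = NA_real_,
                 onset_sustained = NA_real_, onset_sustained_100 = NA_real_,
                 rayleigh_75 = NA_real_, vs_75 = NA_real_,
                 discharge_rate_ratio = NA_real_, min_latency = NA_real_,
                 max_vs = NA_real_, sync_limit = NA_real_,
                 sync_criterion = NA, rate_criterion = NA,
                 label = NA_character_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    if (progress && i %% 100 == 0)
      message(sprintf("cell %d / %d", i, n))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Re-run the classification of a sweep under a different tone-rate window
#'
#' Uses the stored criteria columns, so no re-simulation is needed; supports
#' the inclusion-ceiling variant in which the maximum allowed pure-tone rate
#' is lowered from 50 to 20 spk/s.
#'
#' @param result a \code{"sweep_result"}.
#' @param max_tone_rate new inclusion ceiling (spk/s).
#' @param min_tone_rate new inclusion floor (spk/s, default 1).
#' @return the result with an updated \code{label} column.
#' @export
reclassify <- function(result, max_tone_rate = 50, min_tone_rate = 1) {
  stopifnot(inherits(result, "sweep_result"))
  ok <- is.na(result$error)
  result$label[ok] <- classify_from_columns(result$sync_criterion[ok],
                                            result$rate_criterion[ok],
                                            result$tone_rate[ok],
                                            max_tone_rate, min_tone_rate)
  result
}

#' Proportions of coding regimes in a sweep
#'
#' @param result a \code{"sweep_result"}.
#' @return list with \code{counts} (all labels), \code{classified_fraction}
#'   (share of included cells -- those not excluded by the tone-rate window --
#'   that are synchronized, non-synchronized or mixed) and
#'   \code{regime_proportions} (shares of the three regimes among classified
#'   cells).
#' @export
label_summary <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  lab <- result$label[!is.na(result$label)]
  counts <- table(factor(lab, levels = c("synchronized", "non_synchronized",
                                         "mixed", "atypical", "excluded_low",
                                         "excluded_high")))
  included <- sum(counts[c("synchronized", "non_synchronized", "mixed",
                           "atypical")])
  classified <- sum(counts[c("synchronized", "non_synchronized", "mixed")])
  list(counts = counts,
       classified_fraction = if (included > 0) classified / included else NA,
       regime_proportions = if (classified > 0)
         counts[c("synchronized", "non_synchronized", "mixed")] / classified
       else NULL)
}

#' Spontaneous-rate calibration curve
#'
#' Simulates the neuron without any stimulus for a range of conductance-noise
#' amplitudes and reports the resulting spontaneous rate. The rate increases
#' monotonically with the noise amplitude; sigma = 4e-8 is calibrated to ~4
#' spk/s.
#'
#' @param sigmas conductance-noise amplitudes (Siemens).
#' @param params a [neuron_params()] object.
#' @param total_s simulated time per sigma (s, default 10).
#' @param base_seed integer seed.
#' @param scale noise scale passed to [noise_spec()].
#' @return data frame with columns \code{sigma} and \code{rate} (spk/s).
#' @export
calibrate_spont <- function(sigmas = c(3e-8, 4e-8, 5e-8, 6e-8),
                            params = neuron_params(), total_s = 10,
                            base_seed = 1, scale = noise_scale_default()) {
  stopifnot(all(sigmas >= 0), total_s > 0)
  n_samples <- as.integer(round(total_s * 1000 / params$dt))
  zero <- new_conductance_trace(numeric(n_samples), numeric(n_samples),
                                params$dt)
  rate <- vapply(seq_along(sigmas), function(k) {
    ns <- noise_spec("conductance", sigma = sigmas[k], scale = scale)
    sp <- simulate_trial(zero, params, ns,
                         seed = derive_seed_cpp(c(base_seed, k)))
    length(sp) / total_s
  }, numeric(1))
  data.frame(sigma = sigmas, rate = rate)
}

#' Correlation between excitatory strength and phase-locking confidence
#'
#' Spearman rank correlation between the excitatory input strength and the
#' Rayleigh statistic at IPI = 75 ms over synchronized cells at a fixed I-E
#' delay. Ties are resolved by average ranks.
#'
#' @param result a \code{"sweep_result"}.
#' @param fixed_delay I-E delay slice (ms, default 5).
#' @param min_cells minimum number of cells required (default 10).
#' @return the Spearman coefficient.
#' @export
correlate_sync <- function(result, fixed_delay = 5, min_cells = 10) {
  stopifnot(inherits(result, "sweep_result"))
  sub <- result[!is.na(result$label) & result$label == "synchronized" &
                  result$ie_delay == fixed_delay, ]
  if (nrow(sub) < min_cells)
    stop(sprintf("only %d synchronized cells at delay %g ms (need >= %d)",
                 nrow(sub), fixed_delay, min_cells))
  stats::cor(sub$e_strength, sub$rayleigh_75, method = "spearman")
}

#' Correlation between net excitation and the discharge rate ratio
#'
#' Spearman rank correlation between net excitatory input
#' (e_strength * (1 - I/E ratio)) and the discharge rate ratio over
#' non-synchronized cells at a fixed I-E delay. Infinite-ratio sentinels are
#' excluded from the ranking; the number excluded is reported as an
#' attribute.
#'
#' @param result a \code{"sweep_result"}.
#' @param fixed_delay I-E delay slice (ms, default 0).
#' @param min_cells minimum number of finite-ratio cells (default 10).
#' @return the Spearman coefficient, with attribute \code{n_excluded}.
#' @export
correlate_nonsync <- function(result, fixed_delay = 0, min_cells = 10) {
  stopifnot(inherits(result, "sweep_result"))
  sub <- result[!is.na(result$label) & result$label == "non_synchronized" &
                  result$ie_delay == fixed_delay, ]
  fin <- is.finite(sub$discharge_rate_ratio)
  if (sum(fin) < min_cells)
    stop(sprintf("only %d finite-ratio non-synchronized cells at delay %g ms (need >= %d)",
                 sum(fin), fixed_delay, min_cells))
  r <- stats::cor(sub$net_excitation[fin], sub$discharge_rate_ratio[fin],
                  method = "spearman")
  attr(r, "n_excluded") <- sum(!fin)
  r
}

#' Compare a response metric across coding regimes
#'
#' Group means and pairwise two-sided Wilcoxon rank-sum tests for any summary
#' metric of a sweep, optionally restricted to a band of excitatory strengths
#' (the temporal-fidelity comparison between synchronized and mixed cells
#' uses 3-6 nS so both groups share a similar excitation range).
#'
#' @param result a \code{"sweep_result"}.
#' @param metric name of the column to compare (e.g. \code{"min_latency"},
#'   \code{"onset_sustained"}, \code{"tone_rate"}, \code{"max_vs"},
#'   \code{"sync_limit"}).
#' @param groups regime labels to compare (default the three classified
#'   regimes).
#' @param restrict_e optional length-2 band of e_strength values (nS).
#' @param bonferroni multiply p-values by the number of pairwise comparisons.
#' @return list with \code{means}, \code{n} per group, and a data frame of
#'   pairwise \code{p_values}.
#' @export
population_compare <- function(result, metric,
                               groups = c("synchronized", "non_synchronized",
                                          "mixed"),
                               restrict_e = NULL, bonferroni = TRUE) {
  stopifnot(inherits(result, "sweep_result"), metric %in% names(result))
  sub <- result[!is.na(result$label) & result$label %in% groups, ]
  if (!is.null(restrict_e))
    sub <- sub[sub$e_strength >= restrict_e[1] & sub$e_strength <= restrict_e[2], ]
  vals <- split(sub[[metric]], factor(sub$label, levels = groups))
  vals <- lapply(vals, function(v) v[is.finite(v)])
  if (any(vapply(vals, length, 1L) == 0L))
    stop("every group must contain at least one finite value")
  means <- vapply(vals, mean, numeric(1))
  ns <- vapply(vals, length, integer(1))
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    n_cmp <- ncol(pairs)
    pv <- apply(pairs, 2, function(g) {
      p <- stats::wilcox.test(vals[[g[1]]], vals[[g[2]]], exact = FALSE)$p.value
      if (bonferroni) min(1, p * n_cmp) else p
    })
    pvals <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = pv,
                        stringsAsFactors = FALSE)
  } else {
    pvals <- data.frame(group1 = character(), group2 = character(),
                        p = numeric())
  }
  list(means = means, n = ns, p_values = pvals)
}

#' Invariance of the coding regime across spontaneous rates
#'
#' Repeats the sweep at several conductance-noise amplitudes and flags each
#' cell as invariant when its regime label (synchronized, non-synchronized or
#' mixed) is identical at every amplitude. Fractions of invariant cells are
#' reported per regime, with regimes assigned at the reference amplitude.
#'
#' @param grid a [sweep_grid()]; its own noise spec supplies the reference
#'   sigma.
#' @param sigmas conductance-noise amplitudes to test (Siemens); should span
#'   the spontaneous-rate range of interest (default 3e-8, 4e-8, 6e-8,
#'   covering roughly 0-40 spk/s).
#' @param params a [neuron_params()] object.
#' @param ipis IPIs to test.
#' @param ref_result optional pre-computed \code{"sweep_result"} for the
#'   reference sigma (the grid's own), to avoid re-simulating it.
#' @details Each sigma level is simulated with an independently derived seed
#'   stream: repeating the sweep at a different spontaneous rate is an
#'   independent experiment, and sharing noise draws across levels would
#'   artificially stabilize borderline cells.
#' @return list with \code{per_cell} (parameters, label at each sigma,
#'   invariant flag) and \code{fractions} (invariant share per regime at the
#'   reference sigma).
#' @export
invariance_analysis <- function(grid, sigmas = c(3e-8, 4e-8, 6e-8),
                                params = neuron_params(),
                                ipis = default_ipis(), ref_result = NULL) {
  stopifnot(inherits(grid, "sweep_grid"), length(sigmas) >= 1)
  ref_sigma <- grid$noise$sigma
  if (!ref_sigma %in% sigmas) sigmas <- sort(c(ref_sigma, sigmas))
  results <- lapply(seq_along(sigmas), function(k) {
    if (sigmas[k] == ref_sigma && !is.null(ref_result)) return(ref_result)
    g <- grid
    g$noise <- noise_spec("conductance", sigma = sigmas[k],
                          scale = grid$noise$scale)
    if (sigmas[k] != ref_sigma)
      g$base_seed <- derive_seed_cpp(c(grid$base_seed,
                                       round(sigmas[k] * 1e10)))
    run_grid(g, params, ipis)
  })
  labels <- vapply(results, function(r) r$label, character(nrow(grid$cells)))
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1)
  invariant <- apply(labels, 1, function(l)
    all(!is.na(l)) && length(unique(l)) == 1L &&
      l[1] %in% c("synchronized", "non_synchronized", "mixed"))
  ref_label <- results[[which(sigmas == ref_sigma)[1]]]$label
  per_cell <- cbind(grid$cells,
                    as.data.frame(labels,
                                  col.names = paste0("label_", seq_along(sigmas))),
                    invariant = invariant, ref_label = ref_label)
  names(per_cell)[seq_along(sigmas) + ncol(grid$cells)] <-
    paste0("label_sigma_", signif(sigmas, 3))
  fractions <- vapply(c(synchronized = "synchronized",
                        non_synchronized = "non_synchronized",
                        mixed = "mixed"), function(lb) {
    sel <- !is.na(ref_label) & ref_label == lb
    if (!any(sel)) return(NA_real_)
    mean(invariant[sel])
  }, numeric(1))
  list(per_cell = per_cell, fractions = fractions, sigmas = sigmas)
}

#' Synchronization-limit summary for kernel variants
#'
#' Mean synchronization limit per regime; used to quantify how slower
#' synaptic kinetics (e.g. the NMDA kernel variant) shift the limit toward
#' longer IPIs.
#'
#' @param result a \code{"sweep_result"}.
#' @param groups regimes to summarize (default synchronized and mixed).
#' @return named numeric vector of mean sync limits (ms).
#' @export
sync_limit_summary <- function(result, groups = c("synchronized", "mixed")) {
  stopifnot(inherits(result, "sweep_result"))
  vapply(stats::setNames(groups, groups), function(lb) {
    v <- result$sync_limit[!is.na(result$label) & result$label == lb]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
}
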