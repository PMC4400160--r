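#' Membrane and spiking parameters of the integrate-and-fire neuron
#'
#' Defaults follow in-vivo whole-cell estimates for auditory cortical
#' neurons: C = 0.25 nF, leak conductance 25 nS (membrane time constant
#' 10 ms), excitatory/inhibitory reversal potentials 0 / -85 mV, and a spiking
#' threshold of -45 mV. The resting potential is set to -60 mV, a
#' physiological 15 mV below threshold, and the post-spike reset returns the
#' membrane to rest with no refractory period.
#'
#' @param C membrane capacitance (nF).
#' @param g_rest leak conductance (nS).
#' @param E_e,E_i,E_rest excitatory, inhibitory and leak reversal potentials
#'   (mV).
#' @param V_thresh spiking threshold (mV).
#' @param V_reset post-spike reset potential (mV, defaults to \code{E_rest}).
#' @param refractory absolute refractory period (ms, default 0).
#' @param dt integration time step (ms, default 0.1).
#' @return an object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(C = 0.25, g_rest = 25, E_e = 0, E_i = -85,
                          E_rest = -60, V_thresh = -45, V_reset = E_rest,
                          refractory = 0, dt = 0.1) {
  stopifnot(C > 0, g_rest > 0, dt > 0, refractory >= 0)
  if (!(E_i < V_reset && V_reset <= E_rest && E_rest < V_thresh &&
        V_thresh < E_e))
    stop("potentials must satisfy E_i < V_reset <= E_rest < V_thresh < E_e")
  structure(list(C = C, g_rest = g_rest, E_e = E_e, E_i = E_i,
                 E_rest = E_rest, V_thresh = V_thresh, V_reset = V_reset,
                 refractory = refractory, dt = dt),
            class = "neuron_params")
}

#' Internal-noise model generating the spontaneous rate
#'
#' Selects how stochasticity enters the simulation. \code{"conductance"}
#' (default) adds independent zero-mean Gaussian draws to the excitatory and
#' inhibitory conductances at every time step; \code{sigma} is expressed in
#' Siemens (the default 4e-8 yields a spontaneous rate of about 4 spk/s) and
#' is converted to nS through a fixed dimensionless \code{scale} calibrated
#' against that spontaneous-rate anchor (see the package vignette). Noise
#' draws are not clipped, so the noise term has exactly zero mean.
#' \code{"current"} adds a Gaussian voltage increment (SD \code{sigma} mV) per
#' step after the Euler update; \code{"threshold"} redraws the spiking
#' threshold each step around its nominal value (SD \code{sigma} mV);
#' \code{"jitter_only"} disables membrane noise and instead widens the
#' synaptic-input jitter to a uniform distribution with SD 8.7 ms;
#' \code{"none"} disables all noise.
#'
#' @param mode one of \code{"none"}, \code{"conductance"}, \code{"current"},
#'   \code{"threshold"}, \code{"jitter_only"}.
#' @param sigma noise amplitude; Siemens for \code{"conductance"} (default
#'   4e-8), mV for \code{"current"} (default 1) and \code{"threshold"}
#'   (default 3); ignored otherwise.
#' @param scale dimensionless conversion applied to the conductance-mode
#'   sigma (default [noise_scale_default()]).
#' @param jitter_sd jitter SD used by \code{"jitter_only"} (ms, default 8.7).
#' @return an object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(mode = c("conductance", "none", "current", "threshold",
                                "jitter_only"),
                       sigma = NULL, scale = noise_scale_default(),
                       jitter_sd = 8.7) {
  mode <- match.arg(mode)
  if (is.null(sigma))
    sigma <- switch(mode, conductance = 4e-8, current = 1, threshold = 3, 0)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0, scale >= 0)
  structure(list(mode = mode, sigma = sigma, scale = scale,
                 jitter_sd = jitter_sd),
            class = "noise_spec")
}

#' Calibrated scale for the conductance-noise amplitude
#'
#' The conductance-noise sigma is quoted in Siemens; the per-step draws are
#' \code{sigma * 1e9 * scale} nS. The scale below was calibrated once so that
#' sigma = 4e-8 produces a spontaneous rate of ~4 spk/s (see
#' [calibrate_spont()] and the vignette) and is held fixed everywhere.
#'
#' @return the dimensionless scale factor.
#' @export
noise_scale_default <- function() 0.89

noise_mode_code <- function(noise) {
  switch(noise$mode, none = 0L, conductance = 1L, current = 2L,
         threshold = 3L, jitter_only = 0L)
}

#' One forward-Euler step of the membrane equation
#'
#' \deqn{V \leftarrow V - \frac{dt}{C}\left[ g_e (V - E_e) + g_i (V - E_i) +
#'   g_{rest} (V - E_{rest}) \right]}
#' with V in mV, conductances in nS, C in nF and dt in ms (the ms-to-s
#' conversion supplies a factor 1e-3). Vectorized over \code{V}, \code{g_e}
#' and \code{g_i}; useful for testing and for inspecting fixed points.
#'
#' @param V membrane potential(s) (mV).
#' @param g_e,g_i excitatory and inhibitory conductances (nS).
#' @param params a [neuron_params()] object.
#' @return updated membrane potential(s) (mV).
#' @export
step_membrane <- function(V, g_e, g_i, params) {
  stopifnot(inherits(params, "neuron_params"))
  k <- params$dt * 1e-3 / params$C
  V - k * (g_e * (V - params$E_e) + g_i * (V - params$E_i) +
             params$g_rest * (V - params$E_rest))
}

#' Simulate one trial of the integrate-and-fire neuron
#'
#' Integrates the membrane equation over a conductance trace with the selected
#' noise model. When the membrane potential reaches the (possibly noisy)
#' threshold a spike is recorded at that step and the potential resets to
#' \code{V_reset}. Identical seeds give identical spike trains.
#'
#' @param trace a \code{"conductance_trace"} (its \code{dt} must equal
#'   \code{params$dt}).
#' @param params a [neuron_params()] object.
#' @param noise a [noise_spec()] object.
#' @param seed integer seed for the noise stream.
#' @param return_voltage if \code{TRUE}, attach the voltage trajectory as the
#'   \code{"voltage"} attribute.
#' @return numeric vector of spike times (ms from trial start), strictly
#'   increasing.
#' @export
simulate_trial <- function(trace, params = neuron_params(),
                           noise = noise_spec("none"), seed = 1,
                           return_voltage = FALSE) {
  stopifnot(inherits(trace, "conductance_trace"),
            inherits(params, "neuron_params"), inherits(noise, "noise_spec"))
  if (abs(trace$dt - params$dt) > 1e-12)
    stop("trace dt and neuron dt differ")
  sigma_ns <- if (noise$mode == "conductance") noise$sigma * 1e9 * noise$scale else 0
  sigma_mv <- if (noise$mode %in% c("current", "threshold")) noise$sigma else 0
  res <- simulate_trial_cpp(trace$g_e, trace$g_i, params$dt, params$C,
                            params$g_rest, params$E_e, params$E_i,
                            params$E_rest, params$V_thresh, params$V_reset,
                            params$refractory, noise_mode_code(noise),
                            sigma_ns, sigma_mv, derive_seed_cpp(c(seed, 7)),
                            return_voltage)
  spikes <- res$spike_times
  if (return_voltage) attr(spikes, "voltage") <- res$voltage
  spikes
}

# Effective synapse parameters under a noise model: the jitter-only mode
# replaces the default 1 ms Gaussian jitter with wide uniform jitter.
effective_synapse <- function(syn, noise) {
  if (noise$mode == "jitter_only") {
    syn$jitter_sd <- noise$jitter_sd
    syn$jitter_kind <- "uniform"
  }
  syn
}

#' Simulate repeated trials of one stimulus condition
#'
#' Runs \code{n_trials} independent trials of the same stimulus, each with its
#' own derived jitter and noise seeds. The silent pre-stimulus window of each
#' trial doubles as the spontaneous-activity sample.
#'
#' @param stim a [stimulus_spec()].
#' @param syn a [synapse_params()] object.
#' @param params a [neuron_params()] object.
#' @param noise a [noise_spec()] object.
#' @param n_trials number of trials (default 10).
#' @param base_seed integer seed from which all per-trial seeds are derived.
#' @return list with \code{spikes} (list of per-trial spike-time vectors, ms
#'   from trial start) and \code{stim}.
#' @export
simulate_condition <- function(stim, syn, params = neuron_params(),
                               noise = noise_spec(), n_trials = 10,
                               base_seed = 1) {
  stopifnot(n_trials >= 1)
  syn <- effective_synapse(syn, noise)
  renderer <- if (stim$kind == "pulse_train") render_pulse_train else render_pure_tone
  cond_key <- if (stim$kind == "pulse_train") stim$ipi else -1
  spikes <- vector("list", n_trials)
  for (j in seq_len(n_trials)) {
    trial_seed <- derive_seed_cpp(c(base_seed, cond_key * 1000, j))
    trace <- renderer(stim, syn, seed = derive_seed_cpp(c(trial_seed, 1)),
                      dt = params$dt)
    spikes[[j]] <- simulate_trial(trace, params, noise,
                                  seed = derive_seed_cpp(c(trial_seed, 2)))
  }
  list(spikes = spikes, stim = stim)
}

#' Simulate the full stimulus battery for one model neuron
#'
#' Runs all pulse-train IPIs plus the 200 ms pure tone and assembles a
#' \code{"trial_set"}: the container consumed by [compute_metrics()] and
#' [classify()]. Spontaneous rate (and its trial-to-trial SD) is estimated
#' from the pooled pre-stimulus windows of all trials.
#'
#' @inheritParams simulate_condition
#' @param ipis interpulse intervals to test (ms, default [default_ipis()]).
#' @param include_tone simulate the pure tone as well (default \code{TRUE}).
#' @return an object of class \code{"trial_set"}; see [trial_set()].
#' @export
simulate_trial_set <- function(syn, params = neuron_params(),
                               noise = noise_spec(), ipis = default_ipis(),
                               n_trials = 10, base_seed = 1,
                               include_tone = TRUE) {
  conds <- list()
  for (ipi in ipis) {
    stim <- stimulus_spec("pulse_train", ipi = ipi)
    conds[[paste0("ipi_", ipi)]] <-
      simulate_condition(stim, syn, params, noise, n_trials, base_seed)
  }
  if (include_tone) {
    stim <- stimulus_spec("pure_tone")
    conds[["tone"]] <- simulate_condition(stim, syn, params, noise, n_trials,
                                          base_seed)
  }
  trial_set(lapply(conds, `[[`, "spikes"), lapply(conds, `[[`, "stim"))
}

#' Assemble a trial set from spike times and stimulus metadata
#'
#' A \code{trial_set} holds, for every stimulus condition, the spike times of
#' each trial (ms from trial start) together with the stimulus layout, plus
#' the pooled spontaneous-rate estimate taken from the pre-stimulus windows.
#' Use this constructor directly to analyze spike trains from external
#' recordings; simulated neurons get one from [simulate_trial_set()].
#'
#' @param spikes named list (one element per condition) of lists of numeric
#'   spike-time vectors, one per trial.
#' @param stims named list of [stimulus_spec()] objects matching
#'   \code{spikes}.
#' @param spont_rate,spont_sd optional spontaneous rate and its across-window
#'   SD (spk/s); estimated from the pre-stimulus windows when omitted.
#' @return an object of class \code{"trial_set"}.
#' @export
trial_set <- function(spikes, stims, spont_rate = NULL, spont_sd = NULL) {
  stopifnot(is.list(spikes), is.list(stims),
            identical(names(spikes), names(stims)), length(spikes) >= 1L)
  if (is.null(spont_rate) || is.null(spont_sd)) {
    win_rates <- unlist(lapply(names(spikes), function(nm) {
      onset <- stims[[nm]]$onset
      if (onset <= 0) return(NULL)
      vapply(spikes[[nm]], function(s) sum(s < onset) / (onset / 1000),
             numeric(1))
    }))
    if (is.null(spont_rate))
      spont_rate <- if (length(win_rates)) mean(win_rates) else 0
    if (is.null(spont_sd))
      spont_sd <- if (length(win_rates) > 1) stats::sd(win_rates) else 0
  }
  structure(list(spikes = spikes, stims = stims, spont_rate = spont_rate,
                 spont_sd = spont_sd,
                 pre_window = min(vapply(stims, `[[`, numeric(1), "onset"))),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  n_sp <- sum(unlist(lapply(x$spikes, function(tr) vapply(tr, length, 1L))))
  cat(sprintf("<trial_set> %d conditions x %d trials, %d spikes; spontaneous rate %.2f spk/s (SD %.2f)\n",
              length(x$spikes), length(x$spikes[[1]]), n_sp,
              x$spont_rate, x$spont_sd))
  invisible(x)
}
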