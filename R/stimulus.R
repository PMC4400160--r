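#' Alpha-function synaptic conductance kernel
#'
#' Evaluates the peak-normalized alpha function
#' \deqn{g(t) = A \, (t/\tau) \, e^{1 - t/\tau}}
#' which rises from zero at \code{t = 0} to its maximum \code{amplitude} at
#' \code{t = tau} and decays back toward zero. This is the elementary
#' time-varying conductance evoked by one synaptic input; the default time
#' constant of 5 ms approximates fast AMPA/GABA-A kinetics.
#'
#' @param t numeric vector of times (ms). Values before the kernel onset
#'   (\code{t < 0}) evaluate to 0.
#' @param amplitude peak conductance (nS), must be >= 0.
#' @param tau time-to-peak (ms), must be > 0.
#' @return numeric vector of conductances (nS), same length as \code{t}.
#' @examples
#' alpha_kernel(c(0, 5, 10), amplitude = 1, tau = 5)
#' @export
alpha_kernel <- function(t, amplitude, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("'amplitude' must be a single non-negative number")
  x <- t / tau
  out <- amplitude * x * exp(1 - x)
  out[t < 0] <- 0
  out
}

#' Onset times of an acoustic pulse train
#'
#' Pulses start at time 0 and repeat every \code{ipi} ms for as long as the
#' onset falls strictly inside the stimulus duration.
#'
#' @param ipi interpulse interval (ms), > 0.
#' @param duration stimulus duration (ms), > 0.
#' @return numeric vector of onset times (ms) relative to stimulus onset.
#' @examples
#' pulse_onsets(50, 500) # 10 pulses
#' @export
pulse_onsets <- function(ipi, duration) {
  stopifnot(is.numeric(ipi), length(ipi) == 1L, ipi > 0,
            is.numeric(duration), length(duration) == 1L, duration > 0)
  onsets <- (0:ceiling(duration / ipi)) * ipi
  onsets[onsets < duration]
}

#' Tested interpulse intervals
#'
#' The 18 interpulse intervals (ms) spanning the perceptual range from fusion
#' to flutter at which pulse-train responses are probed.
#'
#' @return numeric vector of IPIs in ms.
#' @export
default_ipis <- function() {
  c(3, 5, 7.5, 10, 12.5, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75)
}

#' Synaptic input parameters
#'
#' Bundles the three model parameters that control feedforward inhibition --
#' excitatory strength, I/E ratio, and I-E delay -- together with the kernel
#' kinetics and input statistics. Each acoustic pulse is converted into
#' \code{n_inputs} excitatory and \code{n_inputs} inhibitory alpha-kernel
#' inputs, each jittered in time. Under the default \code{"per_input"}
#' amplitude convention each individual input has peak \code{e_strength}, so
#' the summed zero-jitter conductance per pulse peaks at \code{n_inputs *
#' e_strength}; this is required for the physiological 0.3-6 nS range to
#' drive spiking at all (a 6 nS total drive saturates the membrane 3 mV below
#' threshold). The alternative \code{"summed"} convention makes
#' \code{e_strength} the summed peak instead.
#'
#' @param e_strength total excitatory peak conductance per pulse (nS, > 0;
#'   physiological sweep range 0.3-6).
#' @param ie_ratio inhibitory/excitatory amplitude ratio (>= 0; sweep range
#'   0-2).
#' @param ie_delay onset delay of inhibition relative to excitation (ms;
#'   positive = inhibition lags; sweep range -2..7).
#' @param n_inputs synaptic inputs per pulse per channel (default 10).
#' @param jitter_sd SD of the temporal jitter of each input (ms, default 1).
#' @param jitter_kind \code{"gaussian"} (default) or \code{"uniform"}; the
#'   uniform variant draws from \code{[-w/2, w/2]} with \code{w = jitter_sd *
#'   sqrt(12)} so that \code{jitter_sd} is its SD.
#' @param conduction_delay delay between the acoustic pulse and the cortical
#'   synaptic input (ms, default 10).
#' @param ampa_tau alpha-kernel time-to-peak of the fast (AMPA/GABA-A-like)
#'   conductance (ms, default 5).
#' @param nmda logical; add a slow two-component NMDA-like kernel to every
#'   excitatory input (default \code{FALSE}).
#' @param nmda_tau time constants of the fast and slow NMDA components (ms,
#'   default \code{c(63, 200)}).
#' @param nmda_weights relative peak weights of the two NMDA components
#'   (default \code{c(0.88, 0.12)}; must sum to 1).
#' @param nmda_peak_ratio NMDA peak amplitude relative to the AMPA peak
#'   (default 0.3, i.e. an AMPA:NMDA ratio of 1:0.3).
#' @param amplitude_convention \code{"per_input"} (default): each input has
#'   peak \code{e_strength}; \code{"summed"}: the summed zero-jitter per-pulse
#'   peak is \code{e_strength}.
#' @return an object of class \code{"synapse_params"}.
#' @export
synapse_params <- function(e_strength, ie_ratio = 1, ie_delay = 0,
                           n_inputs = 10, jitter_sd = 1,
                           jitter_kind = c("gaussian", "uniform"),
                           conduction_delay = 10, ampa_tau = 5,
                           nmda = FALSE, nmda_tau = c(63, 200),
                           nmda_weights = c(0.88, 0.12),
                           nmda_peak_ratio = 0.3,
                           amplitude_convention = c("per_input", "summed")) {
  jitter_kind <- match.arg(jitter_kind)
  amplitude_convention <- match.arg(amplitude_convention)
  stopifnot(is.numeric(e_strength), length(e_strength) == 1L, e_strength > 0,
            is.numeric(ie_ratio), length(ie_ratio) == 1L, ie_ratio >= 0,
            is.numeric(ie_delay), length(ie_delay) == 1L, is.finite(ie_delay),
            n_inputs >= 1, jitter_sd >= 0, conduction_delay >= 0,
            ampa_tau > 0, length(nmda_tau) == 2L, all(nmda_tau > 0),
            length(nmda_weights) == 2L, nmda_peak_ratio >= 0)
  if (abs(sum(nmda_weights) - 1) > 1e-8)
    stop("'nmda_weights' must sum to 1")
  structure(list(e_strength = e_strength, ie_ratio = ie_ratio,
                 ie_delay = ie_delay, n_inputs = as.integer(n_inputs),
                 jitter_sd = jitter_sd, jitter_kind = jitter_kind,
                 conduction_delay = conduction_delay, ampa_tau = ampa_tau,
                 nmda = isTRUE(nmda), nmda_tau = nmda_tau,
                 nmda_weights = nmda_weights,
                 nmda_peak_ratio = nmda_peak_ratio,
                 amplitude_convention = amplitude_convention),
            class = "synapse_params")
}

#' Stimulus specification
#'
#' Describes one stimulus presentation embedded in a simulated trial: an
#' acoustic pulse train (default 500 ms) or a pure tone (default 200 ms),
#' preceded by a silent pre-stimulus window used to estimate spontaneous
#' activity and followed by a silent post-stimulus window.
#'
#' @param kind \code{"pulse_train"} or \code{"pure_tone"}.
#' @param ipi interpulse interval (ms); required for pulse trains.
#' @param duration stimulus duration (ms); defaults to 500 for trains and 200
#'   for tones.
#' @param onset stimulus onset within the trial (ms, default 200).
#' @param trial_length total simulated time (ms); defaults to
#'   \code{onset + duration + 300}.
#' @return an object of class \code{"stimulus_spec"}.
#' @export
stimulus_spec <- function(kind = c("pulse_train", "pure_tone"), ipi = NULL,
                          duration = NULL, onset = 200, trial_length = NULL) {
  kind <- match.arg(kind)
  if (is.null(duration)) duration <- if (kind == "pulse_train") 500 else 200
  if (kind == "pulse_train") {
    if (is.null(ipi) || !is.numeric(ipi) || length(ipi) != 1L || ipi <= 0)
      stop("pulse trains require a single positive 'ipi'")
  } else {
    ipi <- NA_real_
  }
  if (is.null(trial_length)) trial_length <- onset + duration + 300
  stopifnot(onset >= 0, duration > 0, trial_length >= onset + duration)
  structure(list(kind = kind, ipi = ipi, duration = duration, onset = onset,
                 trial_length = trial_length),
            class = "stimulus_spec")
}

new_conductance_trace <- function(g_e, g_i, dt) {
  structure(list(dt = dt, g_e = g_e, g_i = g_i), class = "conductance_trace")
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf("<conductance_trace> %d samples at dt = %g ms (%.1f ms); peak g_e = %.3g nS, peak g_i = %.3g nS\n",
              length(x$g_e), x$dt, length(x$g_e) * x$dt,
              max(x$g_e), max(x$g_i)))
  invisible(x)
}

# Peak conductance of one synaptic input under the chosen convention.
per_input_amplitude <- function(syn) {
  if (syn$amplitude_convention == "per_input") syn$e_strength
  else syn$e_strength / syn$n_inputs
}

# Draw per-input temporal jitter (ms) for one trial from a seeded stream.
draw_jitter <- function(n, syn, seed) {
  if (syn$jitter_sd == 0 || n == 0L) return(numeric(n))
  if (syn$jitter_kind == "gaussian") {
    rnorm_seeded_cpp(n, 0, syn$jitter_sd, seed)
  } else {
    half <- syn$jitter_sd * sqrt(12) / 2
    runif_seeded_cpp(n, -half, half, seed)
  }
}

# Place jittered synaptic event times for one channel and accumulate the
# kernels (AMPA plus optional two-component NMDA) onto the sampling grid.
render_events <- function(n_samples, dt, event_times, per_input_amp, syn) {
  g <- add_alpha_kernels_cpp(n_samples, dt, event_times,
                             rep(per_input_amp, length(event_times)),
                             syn$ampa_tau)
  if (syn$nmda && syn$nmda_peak_ratio > 0) {
    for (j in 1:2) {
      amp <- per_input_amp * syn$nmda_peak_ratio * syn$nmda_weights[j]
      g <- g + add_alpha_kernels_cpp(n_samples, dt, event_times,
                                     rep(amp, length(event_times)),
                                     syn$nmda_tau[j])
    }
  }
  g
}

#' Render an acoustic pulse train as excitatory and inhibitory conductances
#'
#' Each pulse contributes \code{n_inputs} excitatory and \code{n_inputs}
#' inhibitory alpha-kernel inputs. Excitatory inputs are centered at
#' \code{pulse onset + conduction_delay}, inhibitory inputs additionally lag
#' by \code{ie_delay}; every input is independently jittered in time. Kernels
#' sum linearly across inputs and pulses; inputs jittered before \code{t = 0}
#' are truncated at 0. With \code{nmda = TRUE} each excitatory input also
#' contributes the slow two-component NMDA kernel.
#'
#' @param stim a pulse-train [stimulus_spec()].
#' @param syn a [synapse_params()] object.
#' @param seed integer seed for the jitter draws; identical seeds give
#'   bit-identical traces.
#' @param dt sampling step (ms, default 0.1).
#' @return a \code{"conductance_trace"}: list with \code{dt}, \code{g_e},
#'   \code{g_i} (nS, length \code{trial_length / dt}).
#' @export
render_pulse_train <- function(stim, syn, seed = 1, dt = 0.1) {
  stopifnot(inherits(stim, "stimulus_spec"), inherits(syn, "synapse_params"))
  if (stim$kind != "pulse_train") stop("'stim' must be a pulse train")
  n_samples <- as.integer(round(stim$trial_length / dt))
  onsets <- stim$onset + pulse_onsets(stim$ipi, stim$duration)
  n_ev <- length(onsets) * syn$n_inputs
  base <- rep(onsets, each = syn$n_inputs) + syn$conduction_delay
  jit_e <- draw_jitter(n_ev, syn, derive_seed_cpp(c(seed, 101)))
  jit_i <- draw_jitter(n_ev, syn, derive_seed_cpp(c(seed, 102)))
  amp_e <- per_input_amplitude(syn)
  g_e <- render_events(n_samples, dt, base + jit_e, amp_e, syn)
  if (syn$ie_ratio > 0) {
    g_i <- render_events(n_samples, dt, base + syn$ie_delay + jit_i,
                         amp_e * syn$ie_ratio, syn)
  } else {
    g_i <- numeric(n_samples)
  }
  new_conductance_trace(g_e, g_i, dt)
}

#' Render a pure tone as excitatory and inhibitory conductances
#'
#' The tone-evoked conductance is the convolution of a unit step of the tone's
#' duration with the conductance evoked by a single acoustic pulse (as
#' rendered by [render_pulse_train()], including jitter, conduction delay and
#' I-E delay), rescaled so that the steady-state plateau equals the summed
#' zero-jitter per-pulse peak conductance (\code{n_inputs * e_strength} under
#' the default amplitude convention) for the excitatory channel, times
#' \code{ie_ratio} for the inhibitory channel. This keeps pulse-train and
#' pure-tone drives commensurate.
#'
#' @inheritParams render_pulse_train
#' @param stim a pure-tone [stimulus_spec()].
#' @return a \code{"conductance_trace"}.
#' @export
render_pure_tone <- function(stim, syn, seed = 1, dt = 0.1) {
  stopifnot(inherits(stim, "stimulus_spec"), inherits(syn, "synapse_params"))
  if (stim$kind != "pure_tone") stop("'stim' must be a pure tone")
  n_samples <- as.integer(round(stim$trial_length / dt))
  n_dur <- as.integer(round(stim$duration / dt))

  # Single-pulse conductance at the tone onset, rendered on the same grid.
  single <- stimulus_spec("pulse_train", ipi = stim$duration + 1,
                          duration = stim$duration,
                          onset = stim$onset, trial_length = stim$trial_length)
  pulse <- render_pulse_train(single, syn, seed = seed, dt = dt)

  step_conv <- function(g, plateau) {
    if (all(g == 0)) return(g)
    cs <- cumsum(g)
    conv <- cs - c(rep(0, n_dur), cs[seq_len(n_samples - n_dur)])
    # The plateau of step * pulse equals the kernel mass; rescale it to the
    # target steady-state conductance.
    conv * (plateau / sum(g))
  }
  drive <- per_input_amplitude(syn) * syn$n_inputs
  new_conductance_trace(step_conv(pulse$g_e, drive),
                        step_conv(pulse$g_i, syn$ie_ratio * drive),
                        dt)
}
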