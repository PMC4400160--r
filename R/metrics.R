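#' Vector strength of phase locking
#'
#' Mean resultant length of spike phases relative to the stimulus period:
#' \deqn{VS = \frac{1}{n}\sqrt{\left(\sum_i \sin \frac{2\pi t_i}{IPI}\right)^2 +
#'   \left(\sum_i \cos \frac{2\pi t_i}{IPI}\right)^2}}
#' where \eqn{t_i} are spike times relative to stimulus onset and IPI the
#' interpulse interval. 1 indicates perfect locking, 0 a uniform phase
#' distribution.
#'
#' @param spike_times spike times (ms), referenced to stimulus onset.
#' @param ipi interpulse interval (ms), > 0.
#' @return vector strength in \[0, 1\], or \code{NA} when there are no spikes
#'   (an empty train has no phase distribution).
#' @export
vector_strength <- function(spike_times, ipi) {
  stopifnot(is.numeric(ipi), length(ipi) == 1L, ipi > 0)
  n <- length(spike_times)
  if (n == 0L) return(NA_real_)
  ph <- 2 * pi * spike_times / ipi
  sqrt(sum(sin(ph))^2 + sum(cos(ph))^2) / n
}

#' Rayleigh statistic
#'
#' \eqn{2 n \, VS^2}; values above 13.8 reject the uniform-phase null at
#' P < 0.001.
#'
#' @param n number of spikes.
#' @param vs vector strength.
#' @return the Rayleigh statistic (0 when \code{n} = 0).
#' @export
rayleigh_statistic <- function(n, vs) {
  stopifnot(n >= 0)
  if (n == 0L || is.na(vs)) return(0)
  2 * n * vs^2
}

#' Significance cut for the Rayleigh statistic (P < 0.001)
#' @return the critical value 13.8.
#' @export
rayleigh_cut <- function() 13.8

#' Spontaneous-subtracted discharge rate
#'
#' @param n_spikes total spike count across trials in the analysis window.
#' @param window_ms analysis-window length (ms), > 0.
#' @param n_trials number of trials pooled.
#' @param spont_rate mean spontaneous rate (spk/s), subtracted.
#' @return evoked rate (spk/s); may be negative for suppressed responses.
#' @export
evoked_rate <- function(n_spikes, window_ms, n_trials = 1, spont_rate = 0) {
  stopifnot(window_ms > 0, n_trials >= 1)
  n_spikes / (n_trials * window_ms / 1000) - spont_rate
}

#' Discharge rate ratio
#'
#' Rate at the shortest tested IPI (3 ms) divided by the maximum rate over
#' IPIs between 35 and 75 ms, using spontaneous-subtracted rates. A ratio
#' above 1 indicates a monotonic rate code (higher discharge at shorter
#' IPIs). Degenerate cases: a non-positive denominator with a positive
#' numerator yields \code{Inf} (the rate criterion passes); when both are
#' non-positive the ratio is \code{NA} (the criterion fails).
#'
#' @param rates spontaneous-subtracted rates (spk/s), one per IPI.
#' @param ipis the corresponding IPIs (ms); must include 3 and at least one
#'   value in \[35, 75\].
#' @return the discharge rate ratio (possibly \code{Inf} or \code{NA}).
#' @export
discharge_rate_ratio <- function(rates, ipis) {
  stopifnot(length(rates) == length(ipis))
  i3 <- which(ipis == 3)
  long <- which(ipis >= 35 & ipis <= 75)
  if (length(i3) != 1L || length(long) == 0L)
    stop("rates at IPI 3 ms and at least one IPI in [35, 75] ms are required")
  num <- rates[i3]
  den <- max(rates[long])
  if (den > 0) return(num / den)
  if (num > 0) return(Inf)
  NA_real_
}

#' Onset/sustained ratio of a pure-tone response
#'
#' Spike count in the first \code{onset_window} ms of the tone divided by the
#' count over the full \code{total_window} (200 ms tone). 1 indicates a pure
#' onset response; 0.25 a sustained (uniform) response for the default 50/200
#' windows.
#'
#' @param tone_spikes spike times (ms) relative to tone onset.
#' @param onset_window onset window (ms, default 50; 100 for the robustness
#'   variant).
#' @param total_window full analysis window (ms, default 200).
#' @return ratio in \[0, 1\], or \code{NA} when no spikes fall in the window.
#' @export
onset_sustained_ratio <- function(tone_spikes, onset_window = 50,
                                  total_window = 200) {
  tot <- sum(tone_spikes >= 0 & tone_spikes < total_window)
  if (tot == 0L) return(NA_real_)
  sum(tone_spikes >= 0 & tone_spikes < onset_window) / tot
}

#' Synchronization limit across IPIs
#'
#' The shortest IPI at which the response still phase-locks significantly
#' (Rayleigh > 13.8). To guard against isolated false-positive conditions, an
#' IPI qualifies only if the next-longer tested IPI is also significant; the
#' longest tested IPI qualifies on its own significance.
#'
#' @param ipis tested IPIs (ms), any order.
#' @param rayleigh Rayleigh statistics matching \code{ipis}.
#' @return the limit (ms) or \code{NA} if no IPI qualifies.
#' @export
sync_limit <- function(ipis, rayleigh) {
  stopifnot(length(ipis) == length(rayleigh))
  o <- order(ipis)
  ipis <- ipis[o]; ray <- rayleigh[o]
  sig <- !is.na(ray) & ray > rayleigh_cut()
  k <- length(sig)
  qual <- sig & c(sig[-1], TRUE) # last IPI has no longer neighbour
  if (!any(qual)) return(NA_real_)
  ipis[which(qual)[1]]
}

#' Maximum vector strength over significantly synchronized IPIs
#'
#' @param vs vector strengths, one per IPI.
#' @param rayleigh matching Rayleigh statistics.
#' @return the maximum VS among IPIs with Rayleigh > 13.8, or \code{NA} if
#'   none is significant.
#' @export
max_vector_strength <- function(vs, rayleigh) {
  stopifnot(length(vs) == length(rayleigh))
  sig <- !is.na(rayleigh) & rayleigh > rayleigh_cut() & !is.na(vs)
  if (!any(sig)) return(NA_real_)
  max(vs[sig])
}

# Rescale the SD of spontaneous window rates to the SD expected for a rate
# estimated over a window of win_ms averaged across n_trials trials
# (Poisson-like 1/T scaling of the count variance).
scale_spont_sd <- function(spont_sd, pre_ms, win_ms, n_trials) {
  spont_sd * sqrt(pre_ms / win_ms) / sqrt(n_trials)
}

#' Minimum response latency from pooled pulse-train PSTHs
#'
#' Builds a 2 ms-bin PSTH (relative to stimulus onset) pooled over all
#' pulse-train conditions whose evoked rate exceeds the spontaneous rate by
#' more than 2 sigma. The latency is the start of the first bin whose
#' discharge rate exceeds the spontaneous rate by more than 3 sigma with at
#' least 2 pooled spikes, and whose next two bins also exceed the 3 sigma
#' level. Both rules use the same sigma: the SD of the spontaneous-rate
#' estimate for one condition (the trial-to-trial SD of pre-stimulus window
#' rates rescaled to the analysis-window length and trial count).
#'
#' The latency is searched within the first \code{search_window} ms after
#' stimulus onset: a first threshold crossing beyond that reflects sustained
#' or offset activity rather than response onset (every tested pulse train
#' has delivered at least two pulses by then), and the latency is undefined.
#'
#' @param ts a \code{"trial_set"}.
#' @param bin_ms PSTH bin width (ms, default 2).
#' @param search_window response-onset search window (ms, default 100).
#' @return latency (ms from stimulus onset) or \code{NA} if no bin qualifies.
#' @export
minimum_latency <- function(ts, bin_ms = 2, search_window = 100) {
  stopifnot(inherits(ts, "trial_set"))
  train <- names(ts$stims)[vapply(ts$stims, function(s) s$kind == "pulse_train",
                                  logical(1))]
  if (length(train) == 0L) return(NA_real_)

  pooled <- numeric(0)
  n_sweeps <- 0L
  dur <- NULL
  sd_conds <- numeric(0)
  for (nm in train) {
    stim <- ts$stims[[nm]]
    trials <- ts$spikes[[nm]]
    n_tr <- length(trials)
    cnt <- sum(vapply(trials, function(s)
      sum(s >= stim$onset & s < stim$onset + stim$duration), numeric(1)))
    rate <- evoked_rate(cnt, stim$duration, n_tr, ts$spont_rate)
    sd_cond <- scale_spont_sd(ts$spont_sd, ts$pre_window, stim$duration, n_tr)
    if (rate > 2 * sd_cond) {
      rel <- unlist(lapply(trials, function(s) s - stim$onset))
      pooled <- c(pooled, rel[rel >= 0 & rel < stim$duration])
      n_sweeps <- n_sweeps + n_tr
      dur <- stim$duration
      sd_conds <- c(sd_conds, sd_cond)
    }
  }
  if (n_sweeps == 0L) return(NA_real_)

  brk <- seq(0, dur, by = bin_ms)
  counts <- graphics::hist(pooled, breaks = brk, plot = FALSE)$counts
  bin_rate <- counts / (n_sweeps * bin_ms / 1000)
  thr <- ts$spont_rate + 3 * mean(sd_conds)

  above <- bin_rate > thr
  nb <- min(length(above) - 2, ceiling(search_window / bin_ms))
  for (b in seq_len(nb)) {
    if (above[b] && counts[b] >= 2 && above[b + 1] && above[b + 2] &&
        brk[b] < search_window)
      return(brk[b])
  }
  NA_real_
}

#' Compute the full response-metrics summary for one neuron
#'
#' Evaluates every per-IPI statistic (spontaneous-subtracted rate, vector
#' strength, Rayleigh statistic) plus the summary statistics used for
#' classification and population comparisons: discharge rate ratio, minimum
#' latency, pure-tone rate, onset/sustained ratios (50 and 100 ms variants),
#' maximum vector strength and synchronization limit. Pulse-train statistics
#' use the window from stimulus onset to onset + duration.
#'
#' @param ts a \code{"trial_set"}.
#' @return an object of class \code{"response_metrics"}: a list with
#'   \code{per_ipi} (data frame: ipi, n_spikes, rate, rate_sd, vs, rayleigh,
#'   significant) and the summary fields described above.
#' @export
compute_metrics <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  train <- names(ts$stims)[vapply(ts$stims, function(s) s$kind == "pulse_train",
                                  logical(1))]
  per <- lapply(train, function(nm) {
    stim <- ts$stims[[nm]]
    trials <- ts$spikes[[nm]]
    n_tr <- length(trials)
    rel <- unlist(lapply(trials, function(s) s - stim$onset))
    rel <- rel[rel >= 0 & rel < stim$duration]
    n <- length(rel)
    vs <- vector_strength(rel, stim$ipi)
    ray <- rayleigh_statistic(n, vs)
    data.frame(ipi = stim$ipi, n_spikes = n,
               rate = evoked_rate(n, stim$duration, n_tr, ts$spont_rate),
               rate_sd = scale_spont_sd(ts$spont_sd, ts$pre_window,
                                        stim$duration, n_tr),
               vs = vs, rayleigh = ray,
               significant = ray > rayleigh_cut())
  })
  per <- do.call(rbind, per)
  per <- per[order(per$ipi), , drop = FALSE]
  rownames(per) <- NULL

  drr <- tryCatch(discharge_rate_ratio(per$rate, per$ipi),
                  error = function(e) NA_real_)

  tone_rate <- NA_real_; onset50 <- NA_real_; onset100 <- NA_real_
  if ("tone" %in% names(ts$stims)) {
    stim <- ts$stims[["tone"]]
    trials <- ts$spikes[["tone"]]
    rel <- unlist(lapply(trials, function(s) s - stim$onset))
    n <- sum(rel >= 0 & rel < stim$duration)
    tone_rate <- evoked_rate(n, stim$duration, length(trials), ts$spont_rate)
    onset50 <- onset_sustained_ratio(rel, 50, stim$duration)
    onset100 <- onset_sustained_ratio(rel, 100, stim$duration)
  }

  i75 <- which(per$ipi == 75)
  structure(list(
    per_ipi = per,
    spont_rate = ts$spont_rate,
    spont_sd = ts$spont_sd,
    rayleigh_75 = if (length(i75)) per$rayleigh[i75] else NA_real_,
    vs_75 = if (length(i75)) per$vs[i75] else NA_real_,
    discharge_rate_ratio = drr,
    min_latency = minimum_latency(ts),
    tone_rate = tone_rate,
    onset_sustained = onset50,
    onset_sustained_100 = onset100,
    max_vs = max_vector_strength(per$vs, per$rayleigh),
    sync_limit = sync_limit(per$ipi, per$rayleigh)
  ), class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat("<response_metrics>\n")
  cat(sprintf("  spontaneous rate: %.2f spk/s | tone rate: %.2f spk/s | onset/sustained: %s\n",
              x$spont_rate, x$tone_rate, format(round(x$onset_sustained, 2))))
  cat(sprintf("  Rayleigh(75 ms): %.1f | discharge rate ratio: %s | sync limit: %s ms | max VS: %s\n",
              x$rayleigh_75, format(round(x$discharge_rate_ratio, 2)),
              format(x$sync_limit), format(round(x$max_vs, 2))))
  cat(sprintf("  min latency: %s ms\n", format(x$min_latency)))
  invisible(x)
}
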