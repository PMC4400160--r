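#' Classify a neuron's coding regime from its response metrics
#'
#' Two criteria define the regimes: the synchronization criterion (Rayleigh
#' statistic at the longest tested IPI, 75 ms, above 13.8) and the rate
#' criterion (discharge rate ratio above 1). Passing both yields a mixed
#' response; only the first, synchronized; only the second, non-synchronized;
#' neither, atypical. Neurons with spontaneous-subtracted pure-tone rates
#' above \code{max_tone_rate} are excluded as physiologically unrealistic;
#' rates below \code{min_tone_rate} are excluded as unresponsive unless the
#' synchronization criterion holds (synchronized and mixed neurons are exempt
#' from the lower bound).
#'
#' @param metrics a \code{"response_metrics"} object from [compute_metrics()].
#' @param max_tone_rate inclusion ceiling on the pure-tone rate (spk/s,
#'   default 50; set to 20 for the stricter criterion variant).
#' @param min_tone_rate inclusion floor (spk/s, default 1).
#' @param require_responsive apply the [is_responsive()] screen to atypical
#'   candidates (intended for imported recordings); failing neurons are
#'   labelled \code{excluded_low}. Default \code{FALSE}: simulated neurons
#'   failing both criteria inside the tone-rate window are atypical directly.
#' @return an object of class \code{"classification"}: list with \code{label}
#'   (one of \code{synchronized}, \code{non_synchronized}, \code{mixed},
#'   \code{atypical}, \code{excluded_low}, \code{excluded_high}) and
#'   \code{flags} (the individual criteria).
#' @export
classify <- function(metrics, max_tone_rate = 50, min_tone_rate = 1,
                     require_responsive = FALSE) {
  stopifnot(inherits(metrics, "response_metrics"))
  if (is.na(metrics$rayleigh_75))
    stop("classification requires the Rayleigh statistic at IPI = 75 ms")
  sync_c <- metrics$rayleigh_75 > rayleigh_cut()
  rate_c <- !is.na(metrics$discharge_rate_ratio) &&
    metrics$discharge_rate_ratio > 1
  tone <- metrics$tone_rate
  tone_high <- !is.na(tone) && tone > max_tone_rate
  tone_low <- is.na(tone) || tone < min_tone_rate

  label <- if (tone_high) {
    "excluded_high"
  } else if (tone_low && !sync_c) {
    "excluded_low"
  } else if (sync_c && rate_c) {
    "mixed"
  } else if (sync_c) {
    "synchronized"
  } else if (rate_c) {
    "non_synchronized"
  } else if (require_responsive && !is_responsive(metrics)) {
    "excluded_low"
  } else {
    "atypical"
  }
  structure(list(label = label,
                 flags = list(sync_criterion = sync_c,
                              rate_criterion = rate_c,
                              tone_rate = tone,
                              tone_in_range = !tone_high && !tone_low)),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s (sync criterion: %s, rate criterion: %s, tone rate: %.2f spk/s)\n",
              x$label, x$flags$sync_criterion, x$flags$rate_criterion,
              x$flags$tone_rate))
  invisible(x)
}

#' Responsiveness screen for recorded neurons
#'
#' A neuron responds to the pulse-train battery if it shows significant
#' phase locking (Rayleigh > 13.8) at two neighbouring tested IPIs, or a
#' discharge rate at least 2 SD above or below the spontaneous rate at two
#' neighbouring tested IPIs.
#'
#' @param metrics a \code{"response_metrics"} object.
#' @return logical.
#' @export
is_responsive <- function(metrics) {
  stopifnot(inherits(metrics, "response_metrics"))
  per <- metrics$per_ipi
  if (nrow(per) < 2L) return(FALSE)
  sig <- per$significant
  if (any(sig[-length(sig)] & sig[-1])) return(TRUE)
  dev <- abs(per$rate) >= 2 * per$rate_sd & per$rate_sd > 0
  any(dev[-length(dev)] & dev[-1])
}

# Vectorized relabelling from stored criteria columns; used to re-run the
# classification under a different tone-rate ceiling without re-simulating.
classify_from_columns <- function(sync_c, rate_c, tone_rate,
                                  max_tone_rate = 50, min_tone_rate = 1) {
  ifelse(!is.na(tone_rate) & tone_rate > max_tone_rate, "excluded_high",
  ifelse((is.na(tone_rate) | tone_rate < min_tone_rate) & !sync_c, "excluded_low",
  ifelse(sync_c & rate_c, "mixed",
  ifelse(sync_c, "synchronized",
  ifelse(rate_c, "non_synchronized", "atypical")))))
}
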