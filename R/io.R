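results_schema_version <- "1"

#' Default run configuration
#'
#' Nested list of every tunable parameter with its default value: membrane
#' constants, synaptic kernel settings, noise model, sweep grid and analysis
#' windows. [load_config()] fills omitted fields from these defaults.
#'
#' @return a named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    neuron = list(C = 0.25, g_rest = 25, E_e = 0, E_i = -85, E_rest = -60,
                  V_thresh = -45, V_reset = -60, refractory = 0, dt = 0.1),
    synapse = list(n_inputs = 10, jitter_sd = 1, jitter_kind = "gaussian",
                   conduction_delay = 10, ampa_tau = 5, nmda = FALSE,
                   nmda_tau = c(63, 200), nmda_weights = c(0.88, 0.12),
                   nmda_peak_ratio = 0.3),
    noise = list(mode = "conductance", sigma = 4e-8,
                 scale = noise_scale_default(), jitter_sd = 8.7),
    grid = list(ie_delay = seq(-2, 7, by = 1),
                ie_ratio = seq(0, 2, by = 0.1),
                e_strength = seq(0.3, 6, by = 0.3),
                n_trials = 10),
    analysis = list(ipis = default_ipis(), onset_window = 50,
                    max_tone_rate = 50, min_tone_rate = 1)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop(sprintf("configuration key '%s' must be a section", full))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], full)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  # YAML parses mixed-type sequences (e.g. [1.6, 2]) as lists
  num <- function(v) as.numeric(unlist(v))
  for (nm in c("ie_delay", "ie_ratio", "e_strength"))
    cfg$grid[[nm]] <- num(cfg$grid[[nm]])
  cfg$grid$n_trials <- as.integer(cfg$grid$n_trials)
  cfg$analysis$ipis <- num(cfg$analysis$ipis)
  for (nm in c("nmda_tau", "nmda_weights"))
    cfg$synapse[[nm]] <- num(cfg$synapse[[nm]])
  with(cfg, {
    do.call(neuron_params, neuron)  # range checks
    if (!noise$mode %in% c("none", "conductance", "current", "threshold",
                           "jitter_only"))
      stop("noise.mode must be one of none/conductance/current/threshold/jitter_only")
    if (any(grid$ie_ratio < 0)) stop("grid.ie_ratio values must be >= 0")
    if (any(grid$e_strength <= 0)) stop("grid.e_strength values must be > 0")
    if (grid$n_trials < 1) stop("grid.n_trials must be >= 1")
    if (any(cfg$analysis$ipis <= 0)) stop("analysis.ipis must be positive")
  })
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a (possibly partial) configuration file, fills every omitted field
#' from [default_config()], rejects unknown keys and validates ranges. An
#' empty file yields the all-defaults configuration.
#'
#' @param path file path; format chosen by extension (\code{.json} parsed
#'   with jsonlite, anything else with yaml).
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  validate_config(merge_config(default_config(), user))
}

#' Write a configuration to YAML
#'
#' @param cfg a configuration list.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build sweep objects from a configuration
#'
#' @param cfg a configuration list from [load_config()].
#' @return list with \code{grid} ([sweep_grid()]), \code{params}
#'   ([neuron_params()]) and \code{analysis} settings.
#' @export
config_to_grid <- function(cfg) {
  params <- do.call(neuron_params, cfg$neuron)
  noise <- noise_spec(cfg$noise$mode, sigma = cfg$noise$sigma,
                      scale = cfg$noise$scale, jitter_sd = cfg$noise$jitter_sd)
  grid <- sweep_grid(ie_delay = cfg$grid$ie_delay,
                     ie_ratio = cfg$grid$ie_ratio,
                     e_strength = cfg$grid$e_strength,
                     noise = noise, n_trials = cfg$grid$n_trials,
                     base_seed = cfg$seed, nmda = isTRUE(cfg$synapse$nmda))
  list(grid = grid, params = params, analysis = cfg$analysis)
}

#' Write spike trains to CSV
#'
#' Fixed schema: \code{neuron_id, condition, trial, spike_time_ms}, one row
#' per spike, times measured from trial start.
#'
#' @param ts a \code{"trial_set"}.
#' @param path output file.
#' @param neuron_id identifier written in the first column.
#' @return \code{path}, invisibly.
#' @export
write_spikes_csv <- function(ts, path, neuron_id = "sim1") {
  stopifnot(inherits(ts, "trial_set"))
  rows <- do.call(rbind, lapply(names(ts$spikes), function(nm) {
    do.call(rbind, lapply(seq_along(ts$spikes[[nm]]), function(j) {
      s <- ts$spikes[[nm]][[j]]
      if (!length(s)) return(NULL)
      data.frame(neuron_id = neuron_id, condition = nm, trial = j,
                 spike_time_ms = s, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(neuron_id = character(), condition = character(),
                       trial = integer(), spike_time_ms = numeric())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV into a trial set
#'
#' Accepts the schema written by [write_spikes_csv()] (columns
#' \code{neuron_id, condition, trial, spike_time_ms}); conditions named
#' \code{ipi_<value>} are interpreted as pulse trains and \code{tone} as the
#' pure tone. Use this to run the metric and classification suite on
#' external recordings.
#'
#' @param path CSV file.
#' @param neuron_id which neuron to extract (default: the first present).
#' @param n_trials trials per condition (default: the largest trial index).
#' @param onset,train_duration,tone_duration stimulus layout (ms) assumed for
#'   the recordings.
#' @return a \code{"trial_set"}.
#' @export
read_spikes_csv <- function(path, neuron_id = NULL, n_trials = NULL,
                            onset = 200, train_duration = 500,
                            tone_duration = 200) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "condition", "trial", "spike_time_ms")
  if (!all(need %in% names(df)))
    stop("spike CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(neuron_id)) neuron_id <- df$neuron_id[1]
  df <- df[df$neuron_id == neuron_id, ]
  if (is.null(n_trials)) n_trials <- max(df$trial, 1)
  conds <- unique(df$condition)
  spikes <- list(); stims <- list()
  for (nm in conds) {
    sub <- df[df$condition == nm, ]
    spikes[[nm]] <- lapply(seq_len(n_trials), function(j)
      sort(sub$spike_time_ms[sub$trial == j]))
    stims[[nm]] <- if (identical(nm, "tone")) {
      stimulus_spec("pure_tone", duration = tone_duration, onset = onset)
    } else {
      ipi <- suppressWarnings(as.numeric(sub("^ipi_", "", nm)))
      if (is.na(ipi)) stop("unrecognized condition name: ", nm)
      stimulus_spec("pulse_train", ipi = ipi, duration = train_duration,
                    onset = onset)
    }
  }
  trial_set(spikes, stims)
}

#' Export a sweep result to CSV
#'
#' One row per grid cell with all parameters, summary metrics and the regime
#' label; a \code{# synchrate-results-v<N>} header line records the schema
#' version.
#'
#' @param result a \code{"sweep_result"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_results <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# synchrate-results-v", results_schema_version), con)
  utils::write.csv(result, con, row.names = FALSE)
  invisible(path)
}

#' Import a sweep result written by [export_results()]
#'
#' @param path CSV file.
#' @return a \code{"sweep_result"}.
#' @export
import_results <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# synchrate-results-v", first))
    stop("not a synchrate results file (missing schema header)")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("sweep_result", "data.frame")
  df
}

#' Generate spike-time fixtures with known metric values
#'
#' Deterministically seeded toy spike tables for testing the metric and
#' classification pipeline end to end: \code{"locked"} places one spike
#' exactly on every pulse (vector strength 1 at every IPI);
#' \code{"poisson"} draws homogeneous random spikes (vector strength near 0,
#' Rayleigh below the significance cut with overwhelming probability);
#' \code{"mixed_toy"} combines pulse-locked spikes at long IPIs with a rate
#' that grows as the IPI shrinks, so the classifier returns a mixed label.
#'
#' @param kind \code{"locked"}, \code{"poisson"} or \code{"mixed_toy"}.
#' @param seed integer seed.
#' @param ipis pulse-train IPIs to cover (default [default_ipis()]).
#' @param n_trials trials per condition (default 10).
#' @param path optional CSV path; when given the table is also written via
#'   the [write_spikes_csv()] schema.
#' @return a \code{"trial_set"} (invisibly also written to \code{path}).
#' @export
generate_fixture <- function(kind = c("locked", "poisson", "mixed_toy"),
                             seed = 1, ipis = default_ipis(), n_trials = 10,
                             path = NULL) {
  kind <- match.arg(kind)
  onset <- 200
  spikes <- list(); stims <- list()
  ci <- 0L
  for (ipi in ipis) {
    ci <- ci + 1L
    stim <- stimulus_spec("pulse_train", ipi = ipi)
    onsets <- onset + pulse_onsets(ipi, stim$duration)
    spikes[[paste0("ipi_", ipi)]] <- lapply(seq_len(n_trials), function(j) {
      s <- derive_seed_cpp(c(seed, ci, j))
      switch(kind,
        locked = onsets,
        poisson = sort(runif_seeded_cpp(20, onset, onset + stim$duration, s)),
        mixed_toy = {
          # locked response at every pulse plus extra drive at short IPIs
          extra <- if (ipi < 10)
            sort(runif_seeded_cpp(as.integer(120 / ipi), onset,
                                  onset + stim$duration, s))
          else numeric(0)
          sort(c(onsets, extra))
        })
    })
    stims[[paste0("ipi_", ipi)]] <- stim
  }
  stim <- stimulus_spec("pure_tone")
  spikes[["tone"]] <- lapply(seq_len(n_trials), function(j) {
    s <- derive_seed_cpp(c(seed, 999, j))
    switch(kind,
      locked = onset + 10,
      poisson = sort(runif_seeded_cpp(2, onset, onset + 200, s)),
      mixed_toy = sort(runif_seeded_cpp(4, onset, onset + 200, s)))
  })
  stims[["tone"]] <- stim
  ts <- trial_set(spikes, stims, spont_rate = 0, spont_sd = 0)
  if (!is.null(path)) write_spikes_csv(ts, path, neuron_id = kind)
  ts
}
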