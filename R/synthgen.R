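#' Configure the synthetic recording generator
#'
#' The generator emulates the stimulation paradigm used for engram
#' induction experiments in cultured networks: a low-frequency test-pulse
#' epoch (viability check), a spontaneous prestimulation control, a short
#' stimulation epoch in which the pattern is superimposed on ongoing
#' activity, a poststimulation epoch in which a configurable subset of
#' cells replays ("reverberates") components of the stimulus, and a final
#' test-pulse epoch.
#'
#' @param n_cells Number of cells (paper-scale networks are ~100--1,000).
#' @param background_rate Homogeneous Poisson background firing rate per
#'   cell, Hz. Default 0.2 Hz, typical of mature low-bursting cultures.
#' @param test_pulse_rate Test-pulse frequency in Hz (0.2--0.5).
#' @param epoch_durations Named vector of epoch lengths in seconds:
#'   `test1`, `prestim`, `stim`, `poststim`, `test2`.
#' @param reverb_fraction Proportion of active cells that emit poststim
#'   reverberations.
#' @param reverb_duration Reverberation length in seconds from poststim
#'   onset (default 20 s; the effect is transitory and its duration is a
#'   free parameter).
#' @param reverb_jitter_sd Gaussian timing jitter (SD, seconds) applied to
#'   each replayed spike. Default 0.01 s, below one 20 ms frame, consistent
#'   with replay ISIs concentrating within +/- 1 histogram bin.
#' @param component_assignment For doublet patterns: `"whole_pattern"`
#'   (every reverberating cell replays the full pattern) or
#'   `"split_by_frequency"` (cells are split between the high-frequency
#'   component `d` and the low-frequency component `P`).
#' @param ei_fraction Proportion of excitatory cells (default 0.8).
#' @param inhibitory_reverb_odds Odds ratio favouring inhibitory cells when
#'   drawing reverberating cells (1 = no skew, the default).
#' @param stim_response_prob Probability that a cell fires to each test or
#'   stimulation pulse (default 0.9; individual pulses occasionally fail).
#' @param exposure Frame exposure in seconds (default 0.02).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cells = 200,
                             background_rate = 0.2,
                             test_pulse_rate = 0.5,
                             epoch_durations = c(test1 = 20, prestim = 60,
                                                 stim = 10, poststim = 60,
                                                 test2 = 20),
                             reverb_fraction = 0.25,
                             reverb_duration = 20,
                             reverb_jitter_sd = 0.01,
                             component_assignment = c("whole_pattern",
                                                      "split_by_frequency"),
                             ei_fraction = 0.8,
                             inhibitory_reverb_odds = 1,
                             stim_response_prob = 0.9,
                             exposure = 0.02,
                             seed = 1L) {
  component_assignment <- match.arg(component_assignment)
  assert_scalar_num(n_cells, "n_cells", 1)
  assert_scalar_num(background_rate, "background_rate", 0)
  assert_scalar_num(test_pulse_rate, "test_pulse_rate", 0,
                    strict_lower = TRUE)
  need <- c("test1", "prestim", "stim", "poststim", "test2")
  if (!all(need %in% names(epoch_durations)))
    stopf("epoch_durations must name: %s", paste(need, collapse = ", "))
  epoch_durations <- epoch_durations[need]
  if (any(epoch_durations <= 0)) stopf("epoch durations must be positive")
  assert_prob(reverb_fraction, "reverb_fraction")
  assert_scalar_num(reverb_duration, "reverb_duration", 0,
                    strict_lower = TRUE)
  assert_scalar_num(reverb_jitter_sd, "reverb_jitter_sd", 0)
  assert_prob(ei_fraction, "ei_fraction")
  assert_scalar_num(inhibitory_reverb_odds, "inhibitory_reverb_odds", 0,
                    strict_lower = TRUE)
  assert_prob(stim_response_prob, "stim_response_prob")
  assert_scalar_num(exposure, "exposure", 0, strict_lower = TRUE)
  structure(
    list(n_cells = as.integer(n_cells), background_rate = background_rate,
         test_pulse_rate = test_pulse_rate,
         epoch_durations = epoch_durations,
         reverb_fraction = reverb_fraction,
         reverb_duration = reverb_duration,
         reverb_jitter_sd = reverb_jitter_sd,
         component_assignment = component_assignment,
         ei_fraction = ei_fraction,
         inhibitory_reverb_odds = inhibitory_reverb_odds,
         stim_response_prob = stim_response_prob,
         exposure = exposure, seed = as.integer(seed)),
    class = "generator_config")
}

# Replay template for one cell, starting at `start`, before jitter.
# "high" replays the doublet ISI as a regular train, "low" the pattern
# period, "both" the full pattern (or the single frequency).
replay_times <- function(pattern, component, start, duration) {
  eps <- 1e-9
  if (pattern$kind == "single" || component == "both") {
    if (pattern$kind == "single") {
      p <- 1 / pattern$frequency
      start + seq(0, duration - eps, by = p)
    } else {
      pattern_spike_times(pattern, onset = start, duration = duration)
    }
  } else {
    p <- if (component == "high") pattern$doublet_isi else pattern$pattern_period
    start + seq(0, duration - eps, by = p)
  }
}

#' Generate a synthetic recording with known ground truth
#'
#' Produces a spike raster with the full paradigm structure: test pulses
#' answered with probability `stim_response_prob`, homogeneous Poisson
#' background everywhere, pattern-locked spikes superimposed on background
#' during stimulation, and poststimulation replay of the assigned stimulus
#' component by a known subset of cells. Replayed spikes fail with the
#' same per-spike probability (`1 - stim_response_prob`) as driven ones,
#' which is what lets whole-pattern replayers also express the
#' pattern-period ISI. A 5 ms refractory floor removes degenerate
#' near-zero ISIs.
#'
#' @param config A [generator_config()].
#' @param pattern A [stim_pattern()]; its onset is set to the stimulation
#'   epoch start and its duration must equal `epoch_durations["stim"]`.
#' @return A list with components `raster` ([spike_raster()]), `timeline`
#'   ([paradigm_timeline()]) and `truth` (class `ground_truth`: vectors
#'   `reverb_cells`, `component_of_cell`, `cell_type`, `active_cells`, and
#'   `replay_windows`, a data frame of true replay intervals).
#' @examples
#' cfg <- generator_config(n_cells = 20, seed = 42)
#' out <- generate_raster(cfg, stim_pattern("single", frequency = 3))
#' out$raster
#' @export
generate_raster <- function(config, pattern) {
  stopifnot(inherits(config, "generator_config"),
            inherits(pattern, "stim_pattern"))
  check_resolvable(pattern, config$exposure)
  ed <- config$epoch_durations
  if (abs(pattern$duration - ed[["stim"]]) > 1e-9)
    stopf("pattern duration (%g) must equal the stim epoch duration (%g)",
          pattern$duration, ed[["stim"]])
  timeline <- build_timeline(config, pattern)
  pattern <- timeline$pattern      # onset aligned to stim epoch start
  duration <- sum(ed)
  stim_ideal <- pattern_spike_times(pattern)
  pulses1 <- timeline$test_pulses[timeline$test_pulses <
                                    epoch_window(timeline, "test1")[2]]
  pulses2 <- setdiff(timeline$test_pulses, pulses1)
  post_win <- epoch_window(timeline, "poststim")

  with_seed_(config$seed, {
    n <- config$n_cells
    cell_type <- ifelse(stats::runif(n) < config$ei_fraction,
                        "excitatory", "inhibitory")

    # test-pulse responses (bernoulli per pulse, short random latency)
    respond <- function(pulses) {
      lapply(seq_len(n), function(i) {
        hit <- stats::runif(length(pulses)) < config$stim_response_prob
        pulses[hit] + stats::runif(sum(hit), 0, 0.04)
      })
    }
    test1_sp <- respond(pulses1)
    test2_sp <- respond(pulses2)

    # active = responded to at least half the first test-epoch pulses
    resp_frac <- vapply(test1_sp, length, 1L) / max(length(pulses1), 1L)
    active <- which(resp_frac >= 0.5)

    # reverberating subset, optionally skewed toward inhibitory cells
    n_rev <- round(config$reverb_fraction * length(active))
    w <- ifelse(cell_type[active] == "inhibitory",
                config$inhibitory_reverb_odds, 1)
    reverb_cells <- if (n_rev > 0)
      sort(sample(active, n_rev, prob = w)) else integer(0)
    component <- rep(NA_character_, n)
    if (n_rev > 0) {
      if (pattern$kind == "doublet" &&
          config$component_assignment == "split_by_frequency") {
        hi <- sample(reverb_cells, ceiling(n_rev / 2))
        component[reverb_cells] <- ifelse(reverb_cells %in% hi, "high", "low")
      } else {
        component[reverb_cells] <- "both"
      }
    }

    spikes <- vector("list", n)
    for (i in seq_len(n)) {
      bg_n <- stats::rpois(1, config$background_rate * duration)
      t <- stats::runif(bg_n, 0, duration)
      hit <- stats::runif(length(stim_ideal)) < config$stim_response_prob
      t <- c(t, stim_ideal[hit], test1_sp[[i]], test2_sp[[i]])
      if (i %in% reverb_cells) {
        rt <- replay_times(pattern, component[i], post_win[1],
                           min(config$reverb_duration, diff(post_win)))
        # replayed spikes fail at the same per-spike rate as driven ones
        rt <- rt[stats::runif(length(rt)) < config$stim_response_prob]
        if (config$reverb_jitter_sd > 0)
          rt <- rt + stats::rnorm(length(rt), 0, config$reverb_jitter_sd)
        t <- c(t, rt)
      }
      t <- t[t >= 0 & t < duration]
      spikes[[i]] <- enforce_refractory(sort(t))
    }

    truth <- structure(
      list(reverb_cells = reverb_cells,
           component_of_cell = component,
           cell_type = cell_type,
           active_cells = active,
           response_frac = resp_frac,
           replay_windows = if (n_rev > 0) data.frame(
             cell_id = reverb_cells,
             start_s = post_win[1],
             end_s = post_win[1] + min(config$reverb_duration,
                                       diff(post_win)),
             component = component[reverb_cells]) else
               data.frame(cell_id = integer(0), start_s = numeric(0),
                          end_s = numeric(0), component = character(0))),
      class = "ground_truth")

    list(raster = spike_raster(spikes, duration = duration,
                               exposure = config$exposure),
         timeline = timeline, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d active cells, %d reverberating (%d excitatory)\n",
    length(x$active_cells), length(x$reverb_cells),
    sum(x$cell_type[x$reverb_cells] == "excitatory")))
  invisible(x)
}
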