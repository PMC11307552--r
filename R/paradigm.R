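#' Paradigm timeline: epoch boundaries of a recording
#'
#' The paradigm consists of five ordered, non-overlapping epochs:
#' `test1` (viability pulses), `prestim` (spontaneous control), `stim`
#' (pattern delivery), `poststim` (response window) and `test2` (final
#' viability pulses). Epoch intervals are half-open `[start, end)`.
#'
#' @param epochs Data frame with columns `epoch`, `start_s`, `end_s` in
#'   paradigm order.
#' @param pattern The [stim_pattern()] delivered during `stim`; its onset
#'   and duration must match the stim epoch.
#' @param test_pulses Numeric vector of test-pulse times (seconds), lying
#'   within the test epochs.
#' @return An object of class `paradigm_timeline`.
#' @export
paradigm_timeline <- function(epochs, pattern, test_pulses = numeric(0)) {
  need <- c("test1", "prestim", "stim", "poststim", "test2")
  stopifnot(is.data.frame(epochs),
            all(c("epoch", "start_s", "end_s") %in% names(epochs)))
  if (!identical(as.character(epochs$epoch), need))
    stopf("epochs must be exactly: %s, in order", paste(need, collapse = ", "))
  if (any(epochs$end_s <= epochs$start_s))
    stopf("each epoch must have end_s > start_s")
  if (any(diff(as.vector(rbind(epochs$start_s, epochs$end_s))) < -1e-9))
    stopf("epochs must be ordered and non-overlapping")
  stim <- epochs[epochs$epoch == "stim", ]
  if (abs(pattern$onset - stim$start_s) > 1e-9 ||
      abs(pattern$onset + pattern$duration - stim$end_s) > 1e-9)
    stopf("stim epoch [%g, %g) must equal pattern onset/duration",
          stim$start_s, stim$end_s)
  structure(list(epochs = epochs, pattern = pattern,
                 test_pulses = sort(test_pulses)),
            class = "paradigm_timeline")
}

#' @export
print.paradigm_timeline <- function(x, ...) {
  cat("<paradigm_timeline>\n")
  for (i in seq_len(nrow(x$epochs)))
    cat(sprintf("  %-8s [%6.1f, %6.1f) s\n", x$epochs$epoch[i],
                x$epochs$start_s[i], x$epochs$end_s[i]))
  invisible(x)
}

#' Build the timeline implied by a generator configuration
#'
#' @param config A [generator_config()].
#' @param pattern A [stim_pattern()]; its onset is set to the stimulation
#'   epoch start.
#' @return A [paradigm_timeline()].
#' @export
build_timeline <- function(config, pattern) {
  ed <- config$epoch_durations
  ends <- cumsum(ed)
  starts <- ends - ed
  epochs <- data.frame(epoch = names(ed), start_s = unname(starts),
                       end_s = unname(ends))
  pattern$onset <- epochs$start_s[epochs$epoch == "stim"]
  pattern$duration <- ed[["stim"]]
  pulse_gap <- 1 / config$test_pulse_rate
  pulses <- function(w) {
    p <- seq(w[1], w[2] - 1e-9, by = pulse_gap)
    p[p < w[2]]
  }
  tp <- c(pulses(c(epochs$start_s[1], epochs$end_s[1])),
          pulses(c(epochs$start_s[5], epochs$end_s[5])))
  paradigm_timeline(epochs, pattern, tp)
}

#' Epoch window lookup
#' @param timeline A [paradigm_timeline()].
#' @param epoch One of `"test1"`, `"prestim"`, `"stim"`, `"poststim"`,
#'   `"test2"`.
#' @return `c(start_s, end_s)` of the half-open epoch interval.
#' @export
epoch_window <- function(timeline, epoch) {
  stopifnot(inherits(timeline, "paradigm_timeline"))
  i <- match(epoch, timeline$epochs$epoch)
  if (is.na(i)) stopf("unknown epoch '%s'", epoch)
  c(timeline$epochs$start_s[i], timeline$epochs$end_s[i])
}

#' Segment a raster into per-epoch spike views
#'
#' Each spike is assigned to exactly one epoch under the half-open
#' convention `[start, end)`; a spike at exactly the stimulation start
#' belongs to the stimulation epoch.
#'
#' @param raster A [spike_raster()].
#' @param timeline A [paradigm_timeline()] lying within the recording.
#' @return Named list of five `epoch_view` objects (spike rasters carrying
#'   `epoch` and `window` fields; spike times stay absolute).
#' @export
segment <- function(raster, timeline) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(timeline, "paradigm_timeline"))
  if (max(timeline$epochs$end_s) > raster$duration + 1e-9)
    stopf("timeline end (%g s) exceeds recording duration (%g s)",
          max(timeline$epochs$end_s), raster$duration)
  out <- lapply(seq_len(nrow(timeline$epochs)), function(i) {
    w <- c(timeline$epochs$start_s[i], timeline$epochs$end_s[i])
    sp <- lapply(raster$spikes, function(t) t[t >= w[1] & t < w[2]])
    v <- raster
    v$spikes <- sp
    v$epoch <- timeline$epochs$epoch[i]
    v$window <- w
    class(v) <- c("epoch_view", "spike_raster")
    v
  })
  names(out) <- timeline$epochs$epoch
  out
}

#' @export
print.epoch_view <- function(x, ...) {
  cat(sprintf("<epoch_view:%s> [%g, %g) s, %d cells, %d spikes\n",
              x$epoch, x$window[1], x$window[2], x$n_cells,
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Select active (viable) cells by test-pulse response
#'
#' A cell is active iff it fires within `response_window` seconds after at
#' least `min_response_frac` of the test pulses of the first test epoch.
#'
#' @param raster A [spike_raster()].
#' @param timeline A [paradigm_timeline()] carrying test-pulse times.
#' @param min_response_frac Minimum fraction of answered pulses
#'   (default 0.5).
#' @param response_window Post-pulse response window in seconds
#'   (default 0.1).
#' @return An object of class `active_cells`: list with `cells` (ids) and
#'   `response_frac` (per-cell fraction of answered pulses).
#' @export
select_active <- function(raster, timeline, min_response_frac = 0.5,
                          response_window = 0.1) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(timeline, "paradigm_timeline"))
  assert_prob(min_response_frac, "min_response_frac")
  assert_scalar_num(response_window, "response_window", 0,
                    strict_lower = TRUE)
  w <- epoch_window(timeline, "test1")
  pulses <- timeline$test_pulses[timeline$test_pulses >= w[1] &
                                   timeline$test_pulses < w[2]]
  if (length(pulses) == 0) stopf("timeline has no test pulses in test1")
  frac <- vapply(raster$spikes, function(t) {
    hit <- vapply(pulses, function(p)
      any(t >= p & t < p + response_window), logical(1))
    mean(hit)
  }, numeric(1))
  structure(list(cells = raster$cell_ids[frac >= min_response_frac],
                 response_frac = stats::setNames(frac,
                                                 raster$cell_ids)),
            class = "active_cells")
}

#' @export
print.active_cells <- function(x, ...) {
  cat(sprintf("<active_cells> %d of %d cells viable\n",
              length(x$cells), length(x$response_frac)))
  invisible(x)
}
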