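#' Define a stimulation pattern
#'
#' A stimulation pattern is either a single-frequency pulse train or a
#' doublet pattern: two pulses separated by a short interval `doublet_isi`
#' (`d`, typically 80--160 ms), the pair repeated every `pattern_period`
#' (`P`, typically 280--880 ms). A doublet pattern produces characteristic
#' inter-spike-interval peaks at `d`, `P - d` and -- when individual pulses
#' fail -- at `P`.
#'
#' @param kind `"single"` or `"doublet"`.
#' @param frequency Pulse frequency in Hz (single-frequency patterns).
#' @param doublet_isi Within-doublet interval `d` in seconds.
#' @param pattern_period Doublet repetition period `P` in seconds; must
#'   exceed `doublet_isi`.
#' @param onset Stimulation onset in seconds from the start of the
#'   recording. Usually set by [build_timeline()].
#' @param duration Stimulation duration in seconds (default 10).
#' @return An object of class `stim_pattern`.
#' @examples
#' stim_pattern("single", frequency = 3)
#' stim_pattern("doublet", doublet_isi = 0.16, pattern_period = 0.46)
#' @export
stim_pattern <- function(kind = c("single", "doublet"), frequency = NULL,
                         doublet_isi = NULL, pattern_period = NULL,
                         onset = 0, duration = 10) {
  kind <- match.arg(kind)
  assert_scalar_num(onset, "onset", 0)
  assert_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  if (kind == "single") {
    if (is.null(frequency))
      stopf("single-frequency pattern requires `frequency`")
    assert_scalar_num(frequency, "frequency", 0, strict_lower = TRUE)
  } else {
    if (is.null(doublet_isi) || is.null(pattern_period))
      stopf("doublet pattern requires `doublet_isi` and `pattern_period`")
    assert_scalar_num(doublet_isi, "doublet_isi", 0, strict_lower = TRUE)
    assert_scalar_num(pattern_period, "pattern_period", 0, strict_lower = TRUE)
    if (doublet_isi >= pattern_period)
      stopf("doublet_isi (%g) must be smaller than pattern_period (%g)",
            doublet_isi, pattern_period)
  }
  structure(
    list(kind = kind, frequency = frequency, doublet_isi = doublet_isi,
         pattern_period = pattern_period, onset = onset, duration = duration),
    class = "stim_pattern")
}

#' @export
print.stim_pattern <- function(x, ...) {
  if (x$kind == "single") {
    cat(sprintf("<stim_pattern> single %g Hz, onset %g s, duration %g s\n",
                x$frequency, x$onset, x$duration))
  } else {
    cat(sprintf(
      "<stim_pattern> doublet d = %g s, period = %g s, onset %g s, duration %g s\n",
      x$doublet_isi, x$pattern_period, x$onset, x$duration))
  }
  invisible(x)
}

#' Cycle period of a stimulation pattern
#'
#' One cycle is `1/frequency` for a single-frequency pattern and
#' `pattern_period` for a doublet pattern; the cycle is the unit used for
#' classifier training sequences.
#'
#' @param pattern A [stim_pattern()].
#' @return Cycle length in seconds.
#' @export
cycle_period <- function(pattern) {
  stopifnot(inherits(pattern, "stim_pattern"))
  if (pattern$kind == "single") 1 / pattern$frequency else pattern$pattern_period
}

#' Ideal pulse times of a stimulation pattern
#'
#' Enumerates the noiseless stimulus pulse times within
#' `[onset, onset + duration)`.
#'
#' @param pattern A [stim_pattern()].
#' @param onset Override the pattern's onset (seconds).
#' @param duration Override the pattern's duration (seconds).
#' @return Sorted numeric vector of pulse times in seconds.
#' @export
pattern_spike_times <- function(pattern, onset = pattern$onset,
                                duration = pattern$duration) {
  stopifnot(inherits(pattern, "stim_pattern"))
  end <- onset + duration
  eps <- 1e-9
  if (pattern$kind == "single") {
    p <- 1 / pattern$frequency
    k <- floor((duration - eps) / p)
    t <- onset + (0:k) * p
  } else {
    P <- pattern$pattern_period
    k <- floor((duration - eps) / P)
    starts <- onset + (0:k) * P
    t <- sort(c(starts, starts + pattern$doublet_isi))
  }
  t[t < end - eps]
}

# Smallest resolvable period check against the imaging exposure; patterns
# faster than Nyquist at the frame rate cannot be represented in the data.
check_resolvable <- function(pattern, exposure) {
  fastest <- if (pattern$kind == "single") 1 / pattern$frequency
             else pattern$doublet_isi
  if (fastest < 2 * exposure - 1e-12)
    stopf(paste0("pattern is unresolvable at exposure %g s: shortest interval",
                 " %g s is below two frames"), exposure, fastest)
  invisible(TRUE)
}
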