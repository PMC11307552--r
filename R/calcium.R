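#' Calcium fluorescence forward model
#'
#' Each spike adds an instantaneous-rise, exponentially decaying transient
#' of height `amplitude` (dF/F) and decay constant `kernel_decay_tau`.
#' Optional astrocytic ("glial") calcium waves are slow-onset transients:
#' a linear ramp to `glial_amplitude` over `glial_rise_time / 0.8` seconds
#' (so the 10--90% rise time equals `glial_rise_time`) followed by an
#' exponential decay with constant `glial_decay_tau`. Gaussian noise of
#' SD `noise_sd` is added per frame.
#'
#' @param kernel_decay_tau Spike transient decay constant, seconds
#'   (default 0.5).
#' @param amplitude Transient height per spike, dF/F (default 1).
#' @param noise_sd Frame noise SD, dF/F (default 0.1).
#' @param glial_wave_rate Glial wave rate per cell, events/min (default 0,
#'   i.e. no waves).
#' @param glial_rise_time 10--90% rise time of a glial wave, seconds
#'   (default 2; must exceed the rise-time threshold used for slow-wave
#'   exclusion, typically 1 s).
#' @param glial_amplitude Glial wave height, dF/F (default 2).
#' @param glial_decay_tau Glial wave decay constant, seconds (default 5).
#' @return An object of class `calcium_model`.
#' @export
calcium_model <- function(kernel_decay_tau = 0.5, amplitude = 1,
                          noise_sd = 0.1, glial_wave_rate = 0,
                          glial_rise_time = 2, glial_amplitude = 2,
                          glial_decay_tau = 5) {
  assert_scalar_num(kernel_decay_tau, "kernel_decay_tau", 0,
                    strict_lower = TRUE)
  assert_scalar_num(amplitude, "amplitude", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(glial_wave_rate, "glial_wave_rate", 0)
  assert_scalar_num(glial_rise_time, "glial_rise_time", 0,
                    strict_lower = TRUE)
  structure(list(kernel_decay_tau = kernel_decay_tau, amplitude = amplitude,
                 noise_sd = noise_sd, glial_wave_rate = glial_wave_rate,
                 glial_rise_time = glial_rise_time,
                 glial_amplitude = glial_amplitude,
                 glial_decay_tau = glial_decay_tau),
            class = "calcium_model")
}

#' Trace matrix container
#'
#' @param values Numeric matrix, cells x frames, dF/F.
#' @param exposure Frame exposure in seconds.
#' @param t0 Time of the first frame start (default 0).
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, exposure, t0 = 0) {
  stopifnot(is.matrix(values))
  assert_scalar_num(exposure, "exposure", 0, strict_lower = TRUE)
  if (any(!is.finite(values)))
    stopf("trace values must be finite (no NaN/NA/Inf)")
  structure(list(values = values, exposure = exposure, t0 = t0,
                 n_cells = nrow(values), n_frames = ncol(values)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d frames, exposure %g s\n",
              x$n_cells, x$n_frames, x$exposure))
  invisible(x)
}

#' Render calcium fluorescence traces from a spike raster
#'
#' Frames are sampled at their start times `t_k = t0 + k * exposure`; a
#' spike at time `t` first contributes at the first frame with
#' `t_k >= t` (frame quantization happens only here).
#'
#' @param raster A [spike_raster()].
#' @param model A [calcium_model()].
#' @param exposure Frame exposure, seconds (defaults to the raster's).
#' @param seed Optional integer seed making noise and glial waves
#'   reproducible; `NULL` uses the current RNG stream.
#' @return A [trace_matrix()] of dimension `n_cells x n_frames` with
#'   `n_frames = ceiling(duration / exposure)`.
#' @examples
#' r <- spike_raster(list(1.0), duration = 4, exposure = 0.02)
#' tr <- render_calcium(r, calcium_model(noise_sd = 0))
#' max(tr$values)
#' @export
render_calcium <- function(raster, model = calcium_model(),
                           exposure = raster$exposure, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(model, "calcium_model"))
  assert_scalar_num(exposure, "exposure", 0, strict_lower = TRUE)
  n_frames <- ceiling(raster$duration / exposure)
  tk <- (seq_len(n_frames) - 1) * exposure
  g <- exp(-exposure / model$kernel_decay_tau)
  with_seed_(seed, {
    vals <- matrix(0, raster$n_cells, n_frames)
    for (i in seq_len(raster$n_cells)) {
      imp <- numeric(n_frames)
      for (t in raster$spikes[[i]]) {
        i0 <- ceiling(t / exposure - 1e-9) + 1
        if (i0 > n_frames) next
        # partial-frame decay between the spike and its first frame
        imp[i0] <- imp[i0] +
          model$amplitude * exp(-(tk[i0] - t) / model$kernel_decay_tau)
      }
      y <- as.numeric(stats::filter(imp, g, method = "recursive"))
      if (model$glial_wave_rate > 0) {
        nw <- stats::rpois(1, model$glial_wave_rate * raster$duration / 60)
        if (nw > 0) {
          ramp <- model$glial_rise_time / 0.8
          for (t0w in stats::runif(nw, 0, raster$duration)) {
            s <- tk - t0w
            w <- numeric(length(s))
            rising <- s >= 0 & s < ramp
            decaying <- s >= ramp
            w[rising] <- model$glial_amplitude * s[rising] / ramp
            w[decaying] <- model$glial_amplitude *
              exp(-(s[decaying] - ramp) / model$glial_decay_tau)
            y <- y + w
          }
        }
      }
      if (model$noise_sd > 0)
        y <- y + stats::rnorm(n_frames, 0, model$noise_sd)
      vals[i, ] <- y
    }
    trace_matrix(vals, exposure = exposure, t0 = 0)
  })
}

#' Write / read a trace matrix as wide CSV
#'
#' First column `cell_id`, remaining columns one per frame. Exposure is
#' not stored in the file and must be supplied on read.
#'
#' @param traces A [trace_matrix()].
#' @param path File path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a [trace_matrix()].
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_matrix"))
  df <- data.frame(cell_id = seq_len(traces$n_cells), traces$values)
  names(df) <- c("cell_id", sprintf("f%d", seq_len(traces$n_frames)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param exposure Frame exposure in seconds.
#' @param t0 Time of the first frame start.
#' @export
read_traces_csv <- function(path, exposure, t0 = 0) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "cell_id")
    stopf("trace CSV must have cell_id as its first column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  trace_matrix(vals, exposure = exposure, t0 = t0)
}
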